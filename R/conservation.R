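#' Residue frequencies of one alignment column
#'
#' Frequencies are fractions of *all* sequences in the alignment: a gapped
#' row counts in the denominator, so a residue absent from half the family
#' can be at most 50% frequent. This family-wide reading is what lets a
#' catalytic residue (e.g. Cys12 in the ArsC domain) show up as only ~54%
#' conserved when paralogs lacking it share the domain. The gap state is
#' reported as its own row (`residue == "-"`).
#'
#' @param aln Alignment tibble.
#' @param column 1-based column index.
#' @return Tibble with columns `residue`, `count`, `frequency`, sorted by
#'   decreasing frequency then residue.
#' @export
column_frequencies <- function(aln, column) {
  validate_alignment(aln)
  nc <- n_columns(aln)
  if (length(column) != 1 || column < 1 || column > nc) {
    abort(sprintf("`column` must be in 1..%d.", nc))
  }
  res <- substr(aln$seq, column, column)
  tab <- table(res)
  out <- tibble(
    residue = names(tab),
    count = as.integer(tab),
    frequency = as.integer(tab) / nrow(aln)
  )
  dplyr::arrange(out, dplyr::desc(.data$frequency), .data$residue)
}

#' Conservation profile of an alignment
#'
#' Per-column residue frequencies for the whole alignment (gaps counted in
#' the denominator, reported as residue `"-"`).
#'
#' @param aln Alignment tibble.
#' @param refmap Optional `reference_map`; adds a `ref_pos` column.
#' @return A `conservation_profile`: tibble with columns `column`,
#'   `ref_pos`, `residue`, `count`, `frequency`; attribute `n_sequences`.
#' @export
conservation_profile <- function(aln, refmap = NULL) {
  validate_alignment(aln)
  if (nrow(aln) == 0) abort("Cannot profile an empty alignment.")
  m <- aln_matrix(aln)
  n <- nrow(m)
  per_col <- lapply(seq_len(ncol(m)), function(j) {
    tab <- table(m[, j])
    tibble(
      column = j,
      residue = names(tab),
      count = as.integer(tab),
      frequency = as.integer(tab) / n
    )
  })
  out <- dplyr::bind_rows(per_col)
  out$ref_pos <- if (is.null(refmap)) NA_integer_ else col_to_ref(refmap, out$column)
  out <- out[, c("column", "ref_pos", "residue", "count", "frequency")]
  attr(out, "n_sequences") <- n
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Highly conserved positions
#'
#' Reports every column whose modal (non-gap) residue frequency strictly
#' exceeds `threshold`, in reference numbering when a map is supplied. The
#' default 0.80 is the conventional ">80%" cutoff for calling a family
#' position highly conserved; the inequality is strict, so a residue at
#' exactly 80% is not reported.
#'
#' @param aln Alignment tibble.
#' @param refmap Optional `reference_map` built on `aln`.
#' @param threshold Strict lower bound on the modal residue frequency.
#' @return Tibble with columns `ref_pos`, `column`, `residue`, `frequency`,
#'   sorted by reference position (then column for unmapped ones).
#' @export
conserved_positions <- function(aln, refmap = NULL, threshold = 0.80) {
  prof <- conservation_profile(aln, refmap)
  res <- prof[prof$residue != "-", , drop = FALSE]
  top <- res |>
    dplyr::group_by(.data$column) |>
    dplyr::slice_max(.data$frequency, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  hit <- top[top$frequency > threshold, , drop = FALSE]
  out <- hit[, c("ref_pos", "column", "residue", "frequency")]
  dplyr::arrange(out, .data$ref_pos, .data$column)
}

#' @method glance conservation_profile
#' @export
glance.conservation_profile <- function(x, threshold = 0.80, ...) {
  top <- x[x$residue != "-", ] |>
    dplyr::group_by(.data$column) |>
    dplyr::summarise(top = max(.data$frequency), .groups = "drop")
  tibble(
    n_sequences = attr(x, "n_sequences"),
    n_columns = dplyr::n_distinct(x$column),
    n_conserved = sum(top$top > threshold),
    threshold = threshold
  )
}
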