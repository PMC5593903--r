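#' Map alignment columns to reference residue numbering
#'
#' Positions in a domain family are conventionally reported in the native
#' numbering of a reference protein (e.g. "Arg60 of E. coli ArsC") rather
#' than as alignment columns. This builds the bidirectional correspondence
#' from the reference row of the alignment: every non-gap column of that row
#' is numbered consecutively from `first_residue_number`; columns where the
#' reference is gapped have no reference number.
#'
#' @param aln Alignment tibble.
#' @param reference_id Id of the reference record within `aln`.
#' @param first_residue_number Number of the first reference residue present
#'   in the alignment (1 for a full-length reference).
#' @return A `reference_map`: tibble with columns `column` (1-based
#'   alignment column) and `ref_pos`, plus attributes `reference_id` and
#'   `n_columns`.
#' @export
#' @examples
#' aln <- alignment(c("ref", "x"), c("M-KC", "MAKC"))
#' build_reference_map(aln, "ref")
build_reference_map <- function(aln, reference_id, first_residue_number = 1L) {
  validate_alignment(aln)
  i <- match(reference_id, aln$id)
  if (is.na(i)) {
    abort(sprintf("Reference id '%s' not found in the alignment.", reference_id))
  }
  res <- strsplit(aln$seq[[i]], "")[[1]]
  nongap <- which(res != "-")
  if (length(nongap) == 0) {
    warn(sprintf("Reference row '%s' is all gaps; empty map.", reference_id))
  }
  map <- tibble(
    column = nongap,
    ref_pos = seq_along(nongap) + first_residue_number - 1L
  )
  attr(map, "reference_id") <- reference_id
  attr(map, "n_columns") <- n_columns(aln)
  class(map) <- c("reference_map", class(map))
  map
}

#' Convert between alignment columns and reference positions
#'
#' @param refmap A `reference_map` from [build_reference_map()].
#' @param column,ref_pos Integer vectors to convert.
#' @return Integer vector of the same length; `NA` where unmapped (e.g. the
#'   reference is gapped in that column).
#' @export
col_to_ref <- function(refmap, column) {
  refmap$ref_pos[match(column, refmap$column)]
}

#' @rdname col_to_ref
#' @export
ref_to_col <- function(refmap, ref_pos) {
  refmap$column[match(ref_pos, refmap$ref_pos)]
}

#' Residue states of aligned sequences in reference numbering
#'
#' Expands an alignment into one row per (sequence, mapped reference
#' position) carrying a residue, the long form consumed by signature
#' classification and logo summaries.
#'
#' @param aln Alignment tibble.
#' @param refmap A `reference_map` built on `aln`.
#' @return Tibble with columns `id`, `ref_pos`, `residue`.
#' @export
alignment_states <- function(aln, refmap) {
  validate_alignment(aln)
  m <- aln_matrix(aln)
  sub <- m[, refmap$column, drop = FALSE]
  out <- tibble(
    id = rep(aln$id, times = length(refmap$ref_pos)),
    ref_pos = rep(refmap$ref_pos, each = nrow(aln)),
    residue = as.vector(sub)
  )
  out <- out[out$residue != "-", , drop = FALSE]
  dplyr::arrange(out, .data$id, .data$ref_pos)
}
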