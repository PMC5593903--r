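#' Catalogue residue events of an alignment
#'
#' A residue event is a (column, residue) pair; only events present in at
#' least `min_presence` of the sequences enter the coevolution analysis.
#' The 20% floor keeps the pair statistics out of the sparse regime where
#' association estimates are unstable. Gaps are never events.
#'
#' @param aln Alignment tibble.
#' @param min_presence Minimum event fraction (of all sequences), inclusive.
#' @param refmap Optional `reference_map`; adds `ref_pos`.
#' @return Tibble with columns `column`, `ref_pos`, `residue`, `count`,
#'   `fraction`, ordered by column then residue.
#' @export
event_catalog <- function(aln, min_presence = 0.20, refmap = NULL) {
  prof <- conservation_profile(aln, refmap)
  ev <- prof[prof$residue != "-" & prof$frequency >= min_presence, , drop = FALSE]
  out <- tibble(
    column = ev$column,
    ref_pos = ev$ref_pos,
    residue = ev$residue,
    count = ev$count,
    fraction = ev$frequency
  )
  dplyr::arrange(out, .data$column, .data$residue)
}

# one-sided Fisher exact (hypergeometric upper tail) for enrichment of
# co-occurrence: P(X >= k) with K successes, n draws out of N
hyper_tail_p <- function(k, count_a, count_b, n) {
  phyper(k - 1L, count_b, n - count_b, count_a, lower.tail = FALSE)
}

#' Association statistics for one pair of residue events
#'
#' For events a and b the conditional frequency f(b|a) is compared with the
#' background f(b); the relative increase f(b|a)/f(b) - 1 measures how much
#' the presence of a raises the frequency of b (and symmetrically for
#' b given a). Significance is a one-sided Fisher exact test (hypergeometric
#' upper tail) on the 2x2 presence table, in the enrichment direction.
#'
#' @param aln Alignment tibble.
#' @param a,b One-row data frames (or lists) with `column` and `residue`.
#' @return One-row tibble with counts, conditional frequencies, relative
#'   increases in both directions and `p_value`.
#' @export
pair_statistics <- function(aln, a, b) {
  validate_alignment(aln)
  a <- as.list(a)
  b <- as.list(b)
  if (a$column == b$column) {
    abort("Events in the same column cannot be paired (mutually exclusive).")
  }
  n <- nrow(aln)
  va <- substr(aln$seq, a$column, a$column) == a$residue
  vb <- substr(aln$seq, b$column, b$column) == b$residue
  ca <- sum(va)
  cb <- sum(vb)
  if (ca == 0 || cb == 0) {
    abort("Both events must occur at least once in the alignment.")
  }
  cab <- sum(va & vb)
  f_a <- ca / n
  f_b <- cb / n
  f_b_given_a <- cab / ca
  f_a_given_b <- cab / cb
  tibble(
    col_a = a$column, res_a = a$residue,
    col_b = b$column, res_b = b$residue,
    count_a = ca, count_b = cb, count_ab = cab,
    f_a = f_a, f_b = f_b,
    f_b_given_a = f_b_given_a, f_a_given_b = f_a_given_b,
    increase_ab = f_b_given_a / f_b - 1,
    increase_ba = f_a_given_b / f_a - 1,
    p_value = hyper_tail_p(cab, ca, cb, n)
  )
}

#' Detect correlated residue-event pairs
#'
#' Screens all pairs of catalogued events in distinct columns and reports
#' those satisfying, in at least one direction, the coevolution rule: the
#' presence of one event increases the frequency of the other by more than
#' `min_increase` (relative by default: f(b|a) > (1 + min_increase) f(b)),
#' with a one-sided Fisher exact p-value below `max_p`, both events being
#' present in at least `min_presence` of the sequences. Defaults are the
#' 20% / 80% / 1e-10 thresholds conventional for this analysis.
#'
#' `increase_mode = "absolute"` instead requires
#' f(b|a) - f(b) > min_increase; with the default thresholds that reading is
#' unsatisfiable for backgrounds above 0.2/1.8, which is why relative is the
#' default.
#'
#' @param aln Alignment tibble.
#' @param refmap Optional `reference_map` for reference numbering.
#' @param min_presence Event presence floor (inclusive).
#' @param min_increase Strict lower bound on the frequency increase.
#' @param max_p Strict upper bound on the Fisher p-value.
#' @param increase_mode `"relative"` or `"absolute"`.
#' @return Tibble of pairs (one row each, `col_a < col_b` or equal-column
#'   lexicographic residue order) with the statistics of
#'   [pair_statistics()], `ref_pos_a`/`ref_pos_b` and a `direction` column
#'   (`"a->b"`, `"b->a"` or `"both"` by which direction passed the increase
#'   rule), ordered by (col_a, res_a, col_b, res_b). Attribute
#'   `n_pairs_tested` records the size of the screen.
#' @export
detect_correlated_pairs <- function(aln, refmap = NULL, min_presence = 0.20,
                                    min_increase = 0.80, max_p = 1e-10,
                                    increase_mode = c("relative", "absolute")) {
  increase_mode <- match.arg(increase_mode)
  validate_alignment(aln)
  if (n_columns(aln) < 2) abort("Need an alignment with at least 2 columns.")
  ev <- event_catalog(aln, min_presence = min_presence, refmap = refmap)
  empty <- tibble(
    col_a = integer(), ref_pos_a = integer(), res_a = character(),
    col_b = integer(), ref_pos_b = integer(), res_b = character(),
    count_a = integer(), count_b = integer(), count_ab = integer(),
    f_a = numeric(), f_b = numeric(),
    f_b_given_a = numeric(), f_a_given_b = numeric(),
    increase_ab = numeric(), increase_ba = numeric(),
    p_value = numeric(), direction = character()
  )
  if (nrow(ev) < 2) {
    attr(empty, "n_pairs_tested") <- 0L
    return(empty)
  }
  m <- aln_matrix(aln)
  n <- nrow(m)
  # event membership matrix: sequences x events
  E <- vapply(
    seq_len(nrow(ev)),
    function(k) m[, ev$column[[k]]] == ev$residue[[k]],
    logical(n)
  )
  co <- crossprod(E) # co-occurrence counts
  idx <- which(upper.tri(co), arr.ind = TRUE)
  ia <- idx[, 1]
  ib <- idx[, 2]
  keep <- ev$column[ia] != ev$column[ib]
  ia <- ia[keep]
  ib <- ib[keep]
  n_tested <- length(ia)
  if (n_tested == 0) {
    attr(empty, "n_pairs_tested") <- 0L
    return(empty)
  }
  ca <- ev$count[ia]
  cb <- ev$count[ib]
  cab <- co[cbind(ia, ib)]
  f_a <- ca / n
  f_b <- cb / n
  f_b_given_a <- cab / ca
  f_a_given_b <- cab / cb
  if (increase_mode == "relative") {
    inc_ab <- f_b_given_a / f_b - 1
    inc_ba <- f_a_given_b / f_a - 1
  } else {
    inc_ab <- f_b_given_a - f_b
    inc_ba <- f_a_given_b - f_a
  }
  p <- phyper(cab - 1L, cb, n - cb, ca, lower.tail = FALSE)
  pass_ab <- inc_ab > min_increase
  pass_ba <- inc_ba > min_increase
  pass <- (pass_ab | pass_ba) & p < max_p
  out <- tibble(
    col_a = ev$column[ia], ref_pos_a = ev$ref_pos[ia], res_a = ev$residue[ia],
    col_b = ev$column[ib], ref_pos_b = ev$ref_pos[ib], res_b = ev$residue[ib],
    count_a = ca, count_b = cb, count_ab = cab,
    f_a = f_a, f_b = f_b,
    f_b_given_a = f_b_given_a, f_a_given_b = f_a_given_b,
    increase_ab = inc_ab,
    increase_ba = inc_ba,
    p_value = p,
    direction = dplyr::case_when(
      pass_ab & pass_ba ~ "both",
      pass_ab ~ "a->b",
      TRUE ~ "b->a"
    )
  )[pass, , drop = FALSE]
  out <- dplyr::arrange(out, .data$col_a, .data$res_a, .data$col_b, .data$res_b)
  attr(out, "n_pairs_tested") <- n_tested
  out
}

#' Assemble correlated pairs into coevolved sets
#'
#' Coevolved sets are the connected components (default) of the graph whose
#' nodes are residue events and whose edges are reported correlated pairs;
#' members of a set are reported jointly even when not every pairwise
#' support is individually significant. `mode = "clique"` instead returns
#' maximal cliques, requiring all pairwise supports (sets may then overlap).
#' Components of a single event are never emitted.
#'
#' @param pairs Tibble from [detect_correlated_pairs()].
#' @param mode `"component"` or `"clique"`.
#' @return A `coevolved_sets` tibble with columns `set`, `column`,
#'   `ref_pos`, `residue`, ordered by set then column; the supporting pairs
#'   are kept in attribute `pairs`.
#' @export
assemble_sets <- function(pairs, mode = c("component", "clique")) {
  mode <- match.arg(mode)
  empty <- tibble(
    set = integer(), column = integer(), ref_pos = integer(),
    residue = character()
  )
  if (nrow(pairs) == 0) {
    attr(empty, "pairs") <- pairs
    class(empty) <- c("coevolved_sets", class(empty))
    return(empty)
  }
  key_a <- paste0(pairs$col_a, ":", pairs$res_a)
  key_b <- paste0(pairs$col_b, ":", pairs$res_b)
  g <- igraph::graph_from_data_frame(
    data.frame(from = key_a, to = key_b), directed = FALSE
  )
  membership <- if (mode == "component") {
    comp <- igraph::components(g)$membership
    split(names(comp), comp)
  } else {
    cl <- igraph::max_cliques(g, min = 2)
    lapply(cl, igraph::as_ids)
  }
  lookup <- unique(tibble(
    key = c(key_a, key_b),
    column = c(pairs$col_a, pairs$col_b),
    ref_pos = c(pairs$ref_pos_a, pairs$ref_pos_b),
    residue = c(pairs$res_a, pairs$res_b)
  ))
  # order sets by their smallest column for reproducibility
  min_col <- vapply(
    membership,
    function(keys) min(lookup$column[match(keys, lookup$key)]), numeric(1)
  )
  membership <- membership[order(min_col)]
  out <- dplyr::bind_rows(lapply(seq_along(membership), function(s) {
    rows <- lookup[match(membership[[s]], lookup$key), , drop = FALSE]
    tibble(
      set = s, column = rows$column, ref_pos = rows$ref_pos,
      residue = rows$residue
    )
  }))
  out <- dplyr::arrange(out, .data$set, .data$column, .data$residue)
  attr(out, "pairs") <- pairs
  class(out) <- c("coevolved_sets", class(out))
  out
}

#' @method tidy coevolved_sets
#' @export
tidy.coevolved_sets <- function(x, ...) {
  tibble(
    set = x$set, column = x$column, ref_pos = x$ref_pos, residue = x$residue
  )
}

#' @method glance coevolved_sets
#' @export
glance.coevolved_sets <- function(x, ...) {
  pairs <- attr(x, "pairs")
  tibble(
    n_sets = dplyr::n_distinct(x$set),
    n_events = nrow(x),
    n_pairs = if (is.null(pairs)) NA_integer_ else nrow(pairs),
    n_pairs_tested = if (is.null(pairs)) {
      NA_integer_
    } else {
      attr(pairs, "n_pairs_tested") %||% NA_integer_
    }
  )
}
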