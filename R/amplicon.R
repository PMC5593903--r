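#' Translate a nucleotide sequence
#'
#' Standard genetic code. Codons containing `N` (or any non-ACGT symbol)
#' translate to `X`; a trailing partial codon is dropped. Stop codons are
#' handled per `stop_policy`: `"truncate"` ends the peptide at the first
#' stop, `"error"` raises an error naming the offending codon.
#'
#' @param nt Nucleotide string (alphabet ACGTN; U is accepted as T).
#' @param frame Reading-frame offset 0, 1 or 2.
#' @param stop_policy `"truncate"` or `"error"`.
#' @return Peptide string.
#' @export
#' @examples
#' translate_nt("ATGCGT") # "MR"
translate_nt <- function(nt, frame = 0L, stop_policy = c("truncate", "error")) {
  stop_policy <- match.arg(stop_policy)
  if (!frame %in% 0:2) abort("`frame` must be 0, 1 or 2.")
  nt <- toupper(chartr("U", "T", nt))
  if (nchar(nt) < frame + 3) {
    abort("Sequence too short to translate in this frame.")
  }
  body <- substr(nt, frame + 1L, nchar(nt))
  n_codons <- nchar(body) %/% 3L
  starts <- seq(1L, by = 3L, length.out = n_codons)
  codons <- substring(body, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X" # ambiguous (N-containing) codons
  stops <- which(aa == "*")
  if (length(stops) > 0) {
    if (stop_policy == "error") {
      abort(sprintf("Internal stop codon at codon %d.", stops[[1]]))
    }
    aa <- aa[seq_len(stops[[1]] - 1L)]
  }
  paste(aa, collapse = "")
}

#' Pick the reading frame best matching a reference peptide
#'
#' Translates `nt` in all three frames (truncating at stops) and scores
#' each translation against the reference peptide by semi-global alignment
#' (BLOSUM62, whole translation against a reference substring). Ties break
#' toward the lowest frame.
#'
#' @param nt Nucleotide string.
#' @param reference_peptide Reference peptide string.
#' @return One-row tibble with `frame`, `score` and the winning `peptide`.
#' @export
best_frame <- function(nt, reference_peptide) {
  if (nchar(nt) < 3) abort("Sequence shorter than one codon.")
  frames <- 0:2
  peps <- vapply(frames, function(f) {
    if (nchar(nt) < f + 3) "" else translate_nt(nt, f, "truncate")
  }, character(1))
  if (all(!nzchar(peps))) {
    abort("No frame yields any residues before a stop codon.")
  }
  scores <- vapply(seq_along(frames), function(i) {
    if (!nzchar(peps[[i]])) {
      return(-Inf)
    }
    Biostrings::score(Biostrings::pairwiseAlignment(
      peps[[i]], reference_peptide, type = "global-local",
      substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5
    ))
  }, numeric(1))
  i <- which.max(scores) # which.max takes the first maximum: frame 0 wins ties
  tibble(frame = frames[[i]], score = scores[[i]], peptide = peps[[i]])
}

#' Map a peptide onto reference residue numbering
#'
#' Aligns the peptide semi-globally against the reference (the whole
#' peptide against a substring of the reference, free reference end gaps —
#' the geometry of an amplicon sitting inside a full-length domain). Each
#' aligned peptide residue inherits the reference residue number; reference
#' positions deleted in the peptide stay unassigned, peptide insertions get
#' no number.
#'
#' @param peptide Peptide string.
#' @param reference_peptide Reference peptide string.
#' @param reference_numbering_start Number of the first reference residue
#'   (reference numbering is 1-based inclusive).
#' @param min_score Score floor below which the peptide is declared
#'   unmappable (warning; empty result with `NULL` span).
#' @return Tibble with columns `ref_pos`, `residue`; attributes `span`
#'   (c(ref_start, ref_end) or NULL) and `score`.
#' @export
map_peptide_to_reference <- function(peptide, reference_peptide,
                                     reference_numbering_start = 1L,
                                     min_score = 0) {
  if (!nzchar(peptide) || !nzchar(reference_peptide)) {
    abort("Peptide and reference must be non-empty.")
  }
  pa <- Biostrings::pairwiseAlignment(
    peptide, reference_peptide, type = "global-local",
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5
  )
  sc <- Biostrings::score(pa)
  empty <- tibble(ref_pos = integer(), residue = character())
  if (sc < min_score) {
    warn(sprintf("Peptide unmappable (score %.1f < %.1f).", sc, min_score))
    attr(empty, "span") <- NULL
    attr(empty, "score") <- sc
    return(empty)
  }
  p_chars <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  s_chars <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  ref_at <- Biostrings::start(Biostrings::subject(pa)) - 1L
  ref_pos <- integer(0)
  residue <- character(0)
  for (k in seq_along(s_chars)) {
    if (s_chars[[k]] != "-") ref_at <- ref_at + 1L
    if (s_chars[[k]] != "-" && p_chars[[k]] != "-") {
      ref_pos <- c(ref_pos, ref_at)
      residue <- c(residue, p_chars[[k]])
    }
  }
  out <- tibble(
    ref_pos = ref_pos + reference_numbering_start - 1L,
    residue = residue
  )
  attr(out, "span") <- if (nrow(out)) range(out$ref_pos) else NULL
  attr(out, "score") <- sc
  out
}

#' Translate and map a set of amplicons onto a reference
#'
#' For each nucleotide amplicon: choose the best reading frame against the
#' reference ([best_frame()], unless `frame` forces one), translate, and
#' map the peptide onto reference numbering. Records that fail to map
#' (score below `min_score`, e.g. frameshifted clones) are reported as
#' unmappable rather than repaired.
#'
#' @param amplicons Tibble with columns `id`, `seq` (nucleotides), or a
#'   named character vector, or a FASTA path.
#' @param reference_peptide Reference peptide string.
#' @param reference_numbering_start First reference residue number.
#' @param frame Optional forced frame (0/1/2), e.g. from primer design.
#' @param min_score Mapping score floor.
#' @return List with `states` (tibble `id`, `ref_pos`, `residue`) and
#'   `records` (tibble `id`, `frame`, `score`, `peptide`, `ref_start`,
#'   `ref_end`, `mapped`).
#' @export
map_amplicons <- function(amplicons, reference_peptide,
                          reference_numbering_start = 1L, frame = NULL,
                          min_score = 0) {
  if (is.character(amplicons) && length(amplicons) == 1 &&
      file.exists(amplicons)) {
    fa <- read_fasta(amplicons)
    amplicons <- tibble(id = fa$id, seq = fa$seq)
  }
  amplicons <- as_seq_tbl(amplicons)
  recs <- purrr::pmap(amplicons, function(id, seq) {
    fr <- if (is.null(frame)) {
      best_frame(seq, reference_peptide)
    } else {
      tibble(
        frame = frame, score = NA_real_,
        peptide = translate_nt(seq, frame, "truncate")
      )
    }
    mp <- map_peptide_to_reference(
      fr$peptide[[1]], reference_peptide,
      reference_numbering_start = reference_numbering_start,
      min_score = min_score
    )
    span <- attr(mp, "span")
    list(
      record = tibble(
        id = id, frame = fr$frame[[1]], score = attr(mp, "score"),
        peptide = fr$peptide[[1]],
        ref_start = if (is.null(span)) NA_integer_ else span[[1]],
        ref_end = if (is.null(span)) NA_integer_ else span[[2]],
        mapped = !is.null(span)
      ),
      states = if (nrow(mp)) dplyr::mutate(mp, id = id, .before = 1) else NULL
    )
  })
  list(
    states = dplyr::bind_rows(purrr::map(recs, "states")),
    records = dplyr::bind_rows(purrr::map(recs, "record"))
  )
}

#' Per-position residue distribution with Bayesian credible intervals
#'
#' The sequence-logo summary: at each requested reference position, residue
#' frequencies among the peptides covering that position, each with a
#' Bayesian credible interval from the Beta posterior of the per-residue
#' binomial proportion. The default Jeffreys prior, Beta(1/2, 1/2), gives
#' the conventional 95% "Bayesian confidence" error bars of sequence-logo
#' tools; interval ends are clamped to 0/1 when the count is 0/n so the
#' interval always contains the point estimate.
#'
#' @param states Long tibble (`id`, `ref_pos`, `residue`) from
#'   [map_amplicons()] or [alignment_states()].
#' @param positions Reference positions to report (default: all observed).
#' @param conf_level Credible level (default 0.95).
#' @param prior `"jeffreys"` (Beta(1/2,1/2)) or `"uniform"` (Beta(1,1)).
#' @return A `logo_matrix` tibble: `ref_pos`, `residue`, `count`, `n`,
#'   `frequency`, `ci_low`, `ci_high`. Positions covered by no peptide are
#'   emitted with `n = 0` and an `NA` residue.
#' @export
residue_distribution <- function(states, positions = NULL, conf_level = 0.95,
                                 prior = c("jeffreys", "uniform")) {
  prior <- match.arg(prior)
  ab <- if (prior == "jeffreys") 0.5 else 1
  if (nrow(states) == 0) abort("No residue states supplied.")
  positions <- positions %||% sort(unique(states$ref_pos))
  alpha <- (1 - conf_level) / 2
  per_pos <- lapply(positions, function(p) {
    here <- states[states$ref_pos == p, , drop = FALSE]
    n <- nrow(here)
    if (n == 0) {
      return(tibble(
        ref_pos = p, residue = NA_character_, count = 0L, n = 0L,
        frequency = NA_real_, ci_low = NA_real_, ci_high = NA_real_
      ))
    }
    tab <- table(here$residue)
    x <- as.integer(tab)
    tibble(
      ref_pos = p,
      residue = names(tab),
      count = x,
      n = n,
      frequency = x / n,
      ci_low = ifelse(x == 0, 0, qbeta(alpha, x + ab, n - x + ab)),
      ci_high = ifelse(x == n, 1, qbeta(1 - alpha, x + ab, n - x + ab))
    )
  })
  out <- dplyr::bind_rows(per_pos)
  out <- dplyr::arrange(
    out, .data$ref_pos, dplyr::desc(.data$frequency), .data$residue
  )
  attr(out, "conf_level") <- conf_level
  attr(out, "prior") <- prior
  class(out) <- c("logo_matrix", class(out))
  out
}
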