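AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Approximate residue frequencies of natural proteins (UniProt-like), for
# the skewed background preset.
AA_NATURAL_FREQ <- c(
  A = 0.083, C = 0.014, D = 0.055, E = 0.067, F = 0.039, G = 0.071,
  H = 0.023, I = 0.059, K = 0.058, L = 0.097, M = 0.024, N = 0.041,
  P = 0.047, Q = 0.039, R = 0.055, S = 0.066, T = 0.054, V = 0.069,
  W = 0.011, Y = 0.029
)

#' Specify a synthetic protein family
#'
#' Describes a family of `n_sequences` x `n_columns` aligned proteins drawn
#' column-wise from a background distribution, with three kinds of planted
#' structure: family-wide conserved columns hitting a target frequency,
#' subfamilies carrying deterministic residue-event sets on top of the
#' background (the mechanism that creates coevolving columns under
#' divergent evolution), and optional gap/fragment contamination.
#'
#' @param n_sequences,n_columns Alignment dimensions.
#' @param subfamilies Tibble with columns `label`, `proportion` and
#'   `events` (a list column; each element a list of event tibbles with
#'   columns `column`, `residue` — one tibble per planted set). See
#'   [subfamily()]. Proportions must sum to at most 1; the remainder is
#'   pure background.
#' @param conserved Tibble (`column`, `residue`, `frequency`) of planted
#'   conserved columns.
#' @param background `"uniform"` over the 20 amino acids (sharpest tests)
#'   or `"natural"` (skewed, UniProt-like frequencies).
#' @param gap_rate Per-cell probability of a gap in background cells.
#' @param fragment_rate Fraction of sequences truncated to a random
#'   contiguous window (30-50% of columns) to emulate fragment records.
#' @param noise Per-event probability that a planted event is *not*
#'   written (0 = deterministic subfamily sets).
#' @return A `family_spec` list, validated.
#' @export
family_spec <- function(n_sequences, n_columns, subfamilies = NULL,
                        conserved = NULL, background = c("uniform", "natural"),
                        gap_rate = 0, fragment_rate = 0, noise = 0) {
  background <- match.arg(background)
  spec <- list(
    n_sequences = as.integer(n_sequences),
    n_columns = as.integer(n_columns),
    subfamilies = subfamilies,
    conserved = conserved,
    background = background,
    gap_rate = gap_rate,
    fragment_rate = fragment_rate,
    noise = noise
  )
  if (spec$n_sequences < 1 || spec$n_columns < 1) {
    abort("Need at least one sequence and one column.")
  }
  if (!is.null(subfamilies)) {
    if (sum(subfamilies$proportion) > 1 + 1e-9) {
      abort("Subfamily proportions must sum to at most 1.")
    }
    for (i in seq_len(nrow(subfamilies))) {
      sets <- subfamilies$events[[i]]
      all_ev <- dplyr::bind_rows(sets)
      if (any(all_ev$column < 1 | all_ev$column > spec$n_columns)) {
        abort("Planted event column out of range.")
      }
      clash <- all_ev |>
        dplyr::distinct(.data$column, .data$residue) |>
        dplyr::count(.data$column) |>
        dplyr::filter(.data$n > 1)
      if (nrow(clash) > 0) {
        abort(sprintf(
          "Infeasible spec: subfamily '%s' plants two residues at column %d.",
          subfamilies$label[[i]], clash$column[[1]]
        ))
      }
    }
  }
  if (!is.null(conserved)) {
    if (any(conserved$column < 1 | conserved$column > spec$n_columns)) {
      abort("Conserved column out of range.")
    }
    if (any(conserved$frequency < 0 | conserved$frequency > 1)) {
      abort("Conserved target frequencies must be in [0, 1].")
    }
  }
  class(spec) <- "family_spec"
  spec
}

#' Describe one planted subfamily
#'
#' @param label Subfamily name.
#' @param proportion Fraction of the family belonging to this subfamily.
#' @param ... One or more planted event sets, each a tibble with columns
#'   `column`, `residue` (all members of the subfamily carry every event of
#'   every set, absent noise).
#' @return One-row tibble suitable for the `subfamilies` argument of
#'   [family_spec()].
#' @export
subfamily <- function(label, proportion, ...) {
  tibble(label = label, proportion = proportion, events = list(list(...)))
}

#' Generate a synthetic protein family with known truth
#'
#' Draws the alignment described by a [family_spec()]: background cells are
#' i.i.d. draws, conserved columns overwrite a Bernoulli(`frequency`)
#' subset of rows with the target residue, and each subfamily member
#' carries its planted events (deterministically at `noise = 0`). The
#' result is a pure function of `(spec, seed)`.
#'
#' @param spec A `family_spec`.
#' @param seed Integer seed.
#' @return List with `alignment` (tibble `id`, `seq`) and `truth` (list:
#'   `labels` tibble (`id`, `subfamily`, `is_fragment`), `sets` tibble
#'   (`subfamily`, `set`, `column`, `residue`), `conserved` tibble).
#' @export
generate_family <- function(spec, seed) {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(seed, {
    n <- spec$n_sequences
    nc <- spec$n_columns
    probs <- if (spec$background == "uniform") {
      setNames(rep(1 / 20, 20), AA20)
    } else {
      AA_NATURAL_FREQ / sum(AA_NATURAL_FREQ)
    }
    m <- matrix(
      sample(names(probs), n * nc, replace = TRUE, prob = probs),
      nrow = n, ncol = nc
    )
    # conserved columns
    if (!is.null(spec$conserved)) {
      for (i in seq_len(nrow(spec$conserved))) {
        hit <- rbinom(n, 1, spec$conserved$frequency[[i]]) == 1
        m[hit, spec$conserved$column[[i]]] <- spec$conserved$residue[[i]]
      }
    }
    # subfamily labels
    labels <- rep("background", n)
    sets_truth <- NULL
    if (!is.null(spec$subfamilies)) {
      props <- spec$subfamilies$proportion
      counts <- floor(props * n)
      remainder <- props * n - counts
      short <- round(sum(props) * n) - sum(counts)
      if (short > 0) {
        bump <- order(remainder, decreasing = TRUE)[seq_len(short)]
        counts[bump] <- counts[bump] + 1
      }
      pool <- sample.int(n) # random membership, fixed counts
      at <- 0
      for (i in seq_len(nrow(spec$subfamilies))) {
        rows <- pool[seq_len(counts[[i]]) + at]
        at <- at + counts[[i]]
        labels[rows] <- spec$subfamilies$label[[i]]
        sets <- spec$subfamilies$events[[i]]
        for (s in seq_along(sets)) {
          ev <- sets[[s]]
          sets_truth <- dplyr::bind_rows(sets_truth, tibble(
            subfamily = spec$subfamilies$label[[i]], set = s,
            column = ev$column, residue = ev$residue
          ))
          for (k in seq_len(nrow(ev))) {
            write_rows <- if (spec$noise > 0) {
              rows[runif(length(rows)) >= spec$noise]
            } else {
              rows
            }
            m[write_rows, ev$column[[k]]] <- ev$residue[[k]]
          }
        }
      }
    }
    # gap contamination
    if (spec$gap_rate > 0) {
      gap <- matrix(runif(n * nc) < spec$gap_rate, n, nc)
      m[gap] <- "-"
    }
    # fragments: keep a contiguous window, gap the rest
    is_fragment <- rep(FALSE, n)
    if (spec$fragment_rate > 0) {
      frag_rows <- which(runif(n) < spec$fragment_rate)
      is_fragment[frag_rows] <- TRUE
      for (r in frag_rows) {
        w <- max(1L, floor(nc * runif(1, 0.3, 0.5)))
        start <- sample.int(nc - w + 1L, 1)
        keep <- seq(start, start + w - 1L)
        m[r, -keep] <- "-"
      }
    }
    ids <- sprintf("seq%04d", seq_len(n))
    aln <- alignment(ids, apply(m, 1, paste, collapse = ""), "protein")
    truth <- list(
      labels = tibble(id = ids, subfamily = labels, is_fragment = is_fragment),
      sets = sets_truth,
      conserved = spec$conserved
    )
    list(alignment = aln, truth = truth)
  })
}

# codons per amino acid, standard code
codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc_tab <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc_tab), unname(gc_tab))
    }
    cache
  }
})

#' Reverse-translate a peptide with random synonymous codons
#'
#' @param peptide Peptide string (standard residues).
#' @return Nucleotide string; codons are drawn uniformly from each
#'   residue's synonymous codons, so translation round-trips exactly.
#'   Randomness comes from the caller's RNG state.
#' @export
reverse_translate <- function(peptide) {
  tab <- codon_table()
  aa <- strsplit(peptide, "")[[1]]
  unknown <- setdiff(aa, names(tab))
  if (length(unknown) > 0) {
    abort(sprintf(
      "Cannot reverse-translate symbol(s): %s",
      paste(unknown, collapse = ", ")
    ))
  }
  paste(vapply(
    aa,
    function(a) {
      cods <- tab[[a]]
      cods[[sample.int(length(cods), 1)]]
    },
    character(1)
  ), collapse = "")
}

#' Generate synthetic amplicons covering a reference region
#'
#' Emulates clone-library amplicons: the reference peptide region is
#' reverse-translated per clone with random synonymous codons, nucleotide
#' substitutions are applied at `substitution_rate`, and random flanking
#' bases are prepended/appended (a 5' flank of f bases shifts the correct
#' reading frame to `f %% 3`).
#'
#' @param reference_peptide Reference peptide string.
#' @param region `c(start, end)` residue numbers (1-based inclusive, in
#'   reference numbering starting at `reference_numbering_start`).
#' @param n Number of amplicons.
#' @param substitution_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param flank5,flank3 Number of random flanking bases on each side.
#' @param reference_numbering_start Number of the reference's first residue.
#' @return List with `amplicons` (tibble `id`, `seq`) and `truth` (tibble
#'   `id`, `ref_start`, `ref_end`, `frame`).
#' @export
generate_amplicons <- function(reference_peptide, region, n,
                               substitution_rate = 0, seed = 1L,
                               flank5 = 0L, flank3 = 0L,
                               reference_numbering_start = 1L) {
  len <- nchar(reference_peptide)
  start_i <- region[[1]] - reference_numbering_start + 1L
  end_i <- region[[2]] - reference_numbering_start + 1L
  if (start_i < 1 || end_i > len || start_i > end_i) {
    abort(sprintf(
      "Region %d-%d outside the reference (residues %d-%d).",
      region[[1]], region[[2]], reference_numbering_start,
      reference_numbering_start + len - 1L
    ))
  }
  pep <- substr(reference_peptide, start_i, end_i)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      nt <- strsplit(reverse_translate(pep), "")[[1]]
      sub <- runif(length(nt)) < substitution_rate
      if (any(sub)) {
        nt[sub] <- vapply(
          nt[sub],
          function(b) sample(setdiff(bases, b), 1), character(1)
        )
      }
      paste0(
        paste(sample(bases, flank5, replace = TRUE), collapse = ""),
        paste(nt, collapse = ""),
        paste(sample(bases, flank3, replace = TRUE), collapse = "")
      )
    }, character(1))
    ids <- sprintf("amp%04d", seq_len(n))
    list(
      amplicons = tibble(id = ids, seq = seqs),
      truth = tibble(
        id = ids, ref_start = region[[1]], ref_end = region[[2]],
        frame = flank5 %% 3L
      )
    )
  })
}

#' Generate a synthetic clone library with known OTU structure
#'
#' Builds one centroid per OTU (centroids mutually ~`between_otu_distance`
#' apart) and mutates each member from its centroid so that within-OTU
#' pairwise distances stay around `within_otu_distance`. Substitution
#' counts are exact (`round(rate * length)` positions), making the planted
#' distances sharp.
#'
#' @param otu_abundances Integer vector: sequences per OTU.
#' @param within_otu_distance Target within-OTU pairwise distance (members
#'   are mutated at half this rate from the centroid).
#' @param between_otu_distance Target between-centroid distance.
#' @param seed Integer seed.
#' @param seq_length Sequence length in bases.
#' @return List with `library` (tibble `id`, `seq`) and `truth` (tibble
#'   `id`, `otu`).
#' @export
generate_clone_library <- function(otu_abundances, within_otu_distance = 0.01,
                                   between_otu_distance = 0.10, seed = 1L,
                                   seq_length = 500L) {
  if (between_otu_distance <= within_otu_distance) {
    abort("`between_otu_distance` must exceed `within_otu_distance`.")
  }
  if (any(otu_abundances < 1)) abort("OTU abundances must be >= 1.")
  bases <- c("A", "C", "G", "T")
  mutate_at <- function(x, k) {
    if (k == 0) {
      return(x)
    }
    pos <- sample.int(length(x), k)
    x[pos] <- vapply(x[pos], function(b) sample(setdiff(bases, b), 1), character(1))
    x
  }
  withr::with_seed(seed, {
    master <- sample(bases, seq_length, replace = TRUE)
    k_between <- round(between_otu_distance / 2 * seq_length)
    k_within <- round(within_otu_distance / 2 * seq_length)
    rows <- list()
    for (o in seq_along(otu_abundances)) {
      centroid <- mutate_at(master, k_between)
      for (s in seq_len(otu_abundances[[o]])) {
        rows[[length(rows) + 1]] <- tibble(
          id = sprintf("otu%02d_seq%03d", o, s),
          seq = paste(mutate_at(centroid, k_within), collapse = ""),
          otu = o
        )
      }
    }
    lib <- dplyr::bind_rows(rows)
    list(
      library = lib[, c("id", "seq")],
      truth = lib[, c("id", "otu")]
    )
  })
}
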