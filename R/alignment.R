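#' Construct an alignment tibble
#'
#' An alignment is an ordinary tibble with columns `id` (unique sequence
#' identifiers) and `seq` (gapped sequences, all the same length). Gap
#' characters `.` are normalised to `-` and residues are uppercased, the
#' dialect used by Pfam exports.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of gapped sequences, equal lengths.
#' @param alphabet `"protein"` or `"nucleotide"`; stored as an attribute and
#'   guessed from the residues when `NULL`.
#' @return A tibble with columns `id`, `seq` and attribute `alphabet`.
#' @export
#' @examples
#' alignment(c("a", "b"), c("AC-D", "ACED"))
alignment <- function(id, seq, alphabet = NULL) {
  if (length(id) != length(seq)) {
    abort("`id` and `seq` must have the same length.")
  }
  seq <- toupper(gsub(".", "-", seq, fixed = TRUE))
  aln <- tibble(id = as.character(id), seq = seq)
  attr(aln, "alphabet") <- alphabet %||% guess_alphabet(seq)
  validate_alignment(aln)
  aln
}

guess_alphabet <- function(seq) {
  chars <- unique(strsplit(paste(seq, collapse = ""), "")[[1]])
  chars <- setdiff(chars, c("-", "N", "X"))
  if (length(chars) > 0 && all(chars %in% c("A", "C", "G", "T", "U"))) {
    "nucleotide"
  } else {
    "protein"
  }
}

validate_alignment <- function(aln) {
  if (!is.data.frame(aln) || !all(c("id", "seq") %in% names(aln))) {
    abort("An alignment must be a data frame with columns `id` and `seq`.")
  }
  if (nrow(aln) == 0) {
    return(invisible(aln))
  }
  widths <- nchar(aln$seq)
  if (length(unique(widths)) != 1) {
    abort(sprintf(
      "All aligned sequences must have equal length (saw lengths %s).",
      paste(unique(widths), collapse = ", ")
    ))
  }
  if (anyDuplicated(aln$id)) {
    abort(sprintf(
      "Sequence ids must be unique; duplicated: %s",
      paste(unique(aln$id[duplicated(aln$id)]), collapse = ", ")
    ))
  }
  invisible(aln)
}

#' Number of alignment columns
#' @param aln Alignment tibble.
#' @return Integer number of columns (0 for an empty alignment).
#' @export
n_columns <- function(aln) {
  validate_alignment(aln)
  if (nrow(aln) == 0) 0L else nchar(aln$seq[[1]])
}

# residues as a character matrix, rows = sequences
aln_matrix <- function(aln) {
  validate_alignment(aln)
  m <- matrix(
    unlist(strsplit(aln$seq, "")),
    nrow = nrow(aln), byrow = TRUE
  )
  rownames(m) <- aln$id
  m
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or Stockholm (Pfam export) files into an alignment
#' tibble. Stockholm annotation lines (`#=GF`, `#=GC`, ...) are skipped;
#' only sequence rows are kept. `.` gaps are normalised to `-` and residues
#' uppercased.
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (sniff the first non-blank line), `"fasta"` or
#'   `"stockholm"`.
#' @param alphabet Optional `"protein"`/`"nucleotide"` override.
#' @return An alignment tibble.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm"),
                           alphabet = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    if (length(first) == 0) abort(sprintf("Empty alignment file: %s", path))
    format <- if (startsWith(first[[1]], "# STOCKHOLM") ||
                  any(startsWith(first, "#=GF"))) "stockholm" else "fasta"
  }
  parsed <- switch(format,
    fasta = read_fasta(path),
    stockholm = read_stockholm(path)
  )
  alignment(parsed$id, parsed$seq, alphabet = alphabet)
}

# minimal FASTA reader; keeps gaps, reports the line of the first defect
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  header <- startsWith(lines, ">")
  if (any(keep & !header) && !header[which(keep)[1]]) {
    abort(sprintf(
      "Malformed FASTA in %s: line %d holds sequence before any '>' header.",
      path, which(keep)[1]
    ))
  }
  if (!any(header)) {
    abort(sprintf("Malformed FASTA in %s: no '>' header found.", path))
  }
  grp <- cumsum(header)
  ids <- sub("^>\\s*", "", lines[header])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(
    split(lines[keep & !header], grp[keep & !header]),
    function(x) paste(gsub("\\s", "", x), collapse = ""),
    character(1)
  )
  if (length(seqs) != length(ids)) {
    empty <- setdiff(seq_along(ids), as.integer(names(seqs)))
    abort(sprintf(
      "Malformed FASTA in %s: record '%s' has no sequence.",
      path, ids[empty[1]]
    ))
  }
  list(id = ids, seq = unname(seqs))
}

# Stockholm: sequence rows are "<name> <aligned seq>"; '#' lines and the
# '//' terminator are annotation. Multi-block files concatenate per name.
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqs <- list()
  order_seen <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(line, "#") ||
        startsWith(trimws(line), "//")) {
      next
    }
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) != 2) {
      abort(sprintf(
        "Malformed Stockholm in %s: line %d is not '<name> <sequence>'.",
        path, i
      ))
    }
    nm <- parts[[1]]
    if (is.null(seqs[[nm]])) {
      seqs[[nm]] <- parts[[2]]
      order_seen <- c(order_seen, nm)
    } else {
      seqs[[nm]] <- paste0(seqs[[nm]], parts[[2]])
    }
  }
  if (length(seqs) == 0) {
    abort(sprintf("No sequence rows found in Stockholm file %s.", path))
  }
  list(id = order_seen, seq = unlist(seqs[order_seen], use.names = FALSE))
}

#' Write an alignment as aligned FASTA
#'
#' @param aln Alignment tibble.
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 60L) {
  validate_alignment(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", aln$id[[i]]), con)
    s <- aln$seq[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Pairwise identity between two gapped sequences
#'
#' Identity is the number of identical residues divided by the number of
#' columns where *both* sequences carry a residue. The co-occupancy
#' denominator makes the measure robust to fragments, which is the point of
#' the redundancy filter it feeds. Returns 0 when no column is co-occupied.
#'
#' @param a,b Gapped sequences of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("ACDE", "ACDF") # 0.75
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("`a` and `b` must be aligned to the same length.")
  }
  va <- strsplit(toupper(chartr(".", "-", a)), "")[[1]]
  vb <- strsplit(toupper(chartr(".", "-", b)), "")[[1]]
  both <- va != "-" & vb != "-"
  if (!any(both)) {
    return(0)
  }
  sum(va[both] == vb[both]) / sum(both)
}

#' All-pairs identity matrix of an alignment
#'
#' @param aln Alignment tibble.
#' @return Symmetric numeric matrix with unit diagonal, dimnames = ids.
#' @export
identity_matrix <- function(aln) {
  validate_alignment(aln)
  m <- aln_matrix(aln)
  n <- nrow(m)
  occ <- m != "-"
  out <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        both <- occ[i, ] & occ[j, ]
        out[i, j] <- out[j, i] <-
          if (any(both)) sum(m[i, both] == m[j, both]) / sum(both) else 0
      }
    }
  }
  dimnames(out) <- list(aln$id, aln$id)
  out
}

#' Remove fragment sequences from an alignment
#'
#' A fragment is a record occupying fewer than `min_occupancy` of the
#' alignment columns with residues. Record order is preserved.
#'
#' @param aln Alignment tibble.
#' @param min_occupancy Minimum fraction of non-gap columns to keep a record.
#' @return Filtered alignment, with attribute `filter_report`: a tibble of
#'   (`id`, `kept`, `occupancy`).
#' @export
remove_fragments <- function(aln, min_occupancy = 0.5) {
  validate_alignment(aln)
  if (nrow(aln) == 0) abort("Cannot filter an empty alignment.")
  nc <- n_columns(aln)
  occ <- vapply(
    strsplit(aln$seq, ""),
    function(x) sum(x != "-") / nc, numeric(1)
  )
  kept <- occ >= min_occupancy
  if (!any(kept)) {
    warn("All records removed as fragments; returning an empty alignment.")
  }
  out <- aln[kept, , drop = FALSE]
  attr(out, "alphabet") <- attr(aln, "alphabet")
  attr(out, "filter_report") <- tibble(
    id = aln$id, kept = kept, occupancy = occ
  )
  out
}

#' Remove highly similar sequences from an alignment
#'
#' Greedy scan in input order: a record is kept iff its identity to every
#' already-kept record is at most `max_identity`. The output therefore has
#' all pairwise identities `<= max_identity`, and re-filtering is a no-op.
#' The default 0.70 reproduces the ">70% identity" redundancy filter used
#' when preparing domain families for conservation/coevolution analysis.
#'
#' @param aln Alignment tibble.
#' @param max_identity Maximum tolerated pairwise identity.
#' @return Filtered alignment with a `filter_report` attribute
#'   (`id`, `kept`, `max_identity_to_kept`).
#' @export
remove_redundant <- function(aln, max_identity = 0.70) {
  validate_alignment(aln)
  if (nrow(aln) == 0) abort("Cannot filter an empty alignment.")
  m <- aln_matrix(aln)
  occ <- m != "-"
  n <- nrow(m)
  kept_idx <- integer(0)
  best <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ok <- TRUE
    besti <- if (length(kept_idx)) 0 else NA_real_
    for (j in kept_idx) {
      both <- occ[i, ] & occ[j, ]
      idij <- if (any(both)) sum(m[i, both] == m[j, both]) / sum(both) else 0
      besti <- max(besti, idij)
      if (idij > max_identity) {
        ok <- FALSE
        break
      }
    }
    best[i] <- besti
    if (ok) kept_idx <- c(kept_idx, i)
  }
  kept <- seq_len(n) %in% kept_idx
  out <- aln[kept, , drop = FALSE]
  attr(out, "alphabet") <- attr(aln, "alphabet")
  attr(out, "filter_report") <- tibble(
    id = aln$id, kept = kept, max_identity_to_kept = best
  )
  out
}

#' Reduce redundancy of unaligned sequences
#'
#' Greedy keep-scan over unaligned sequences mirroring the classic
#' decrease-redundancy preparation for phylogenetics: a sequence is dropped
#' when its best semi-global identity to an already-kept sequence exceeds
#' `max_similarity` (near-duplicate) or when its best identity to every kept
#' sequence falls below `min_similarity` (unrelated outlier). The first
#' sequence is always kept; the result is deterministic in input order.
#'
#' Identity is matches over aligned columns of an overlap (free end gap)
#' pairwise alignment.
#'
#' @param seqs Tibble with columns `id`, `seq` (unaligned), or a character
#'   vector (names used as ids).
#' @param max_similarity Drop sequences more similar than this to a kept one.
#' @param min_similarity Drop sequences less similar than this to all kept.
#' @return Tibble of kept sequences with a `filter_report` attribute
#'   (`id`, `kept`, `best_identity`, `reason`).
#' @export
decrease_redundancy <- function(seqs, max_similarity = 0.99,
                                min_similarity = 0.30) {
  seqs <- as_seq_tbl(seqs)
  if (nrow(seqs) == 0) abort("Need at least one sequence.")
  n <- nrow(seqs)
  kept_idx <- integer(0)
  best <- rep(NA_real_, n)
  reason <- rep("kept", n)
  for (i in seq_len(n)) {
    if (length(kept_idx) == 0) {
      kept_idx <- i
      next
    }
    ids <- vapply(
      kept_idx,
      function(j) unaligned_identity(seqs$seq[[i]], seqs$seq[[j]]),
      numeric(1)
    )
    best[i] <- max(ids)
    if (any(ids > max_similarity)) {
      reason[i] <- "too_similar"
    } else if (best[i] < min_similarity) {
      reason[i] <- "outlier"
    } else {
      kept_idx <- c(kept_idx, i)
    }
  }
  kept <- seq_len(n) %in% kept_idx
  out <- seqs[kept, , drop = FALSE]
  attr(out, "filter_report") <- tibble(
    id = seqs$id, kept = kept, best_identity = best, reason = reason
  )
  out
}

as_seq_tbl <- function(seqs) {
  if (is.character(seqs)) {
    ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
    seqs <- tibble(id = ids, seq = unname(seqs))
  }
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    abort("`seqs` must be a tibble with columns `id` and `seq`.")
  }
  if (any(!nzchar(seqs$seq))) abort("Empty sequences are not allowed.")
  as_tibble(seqs[, c("id", "seq")])
}

# identity of two unaligned sequences: matched residues of an overlap
# (free end gap) alignment divided by the shorter sequence length. The
# length-normalised denominator keeps short spurious overlaps from scoring
# as high identity, so unrelated sequences land near the ~25% random floor
# while near-duplicates stay near 1.
unaligned_identity <- function(a, b) {
  alphabet <- guess_alphabet(c(a, b))
  if (alphabet == "nucleotide") {
    sm <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1, baseOnly = FALSE
    )
    pa <- Biostrings::pairwiseAlignment(
      a, b, type = "overlap", substitutionMatrix = sm,
      gapOpening = 10, gapExtension = 4
    )
  } else {
    pa <- Biostrings::pairwiseAlignment(
      a, b, type = "overlap", substitutionMatrix = blosum62(),
      gapOpening = 10, gapExtension = 0.5
    )
  }
  Biostrings::nmatch(pa) / min(nchar(a), nchar(b))
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
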