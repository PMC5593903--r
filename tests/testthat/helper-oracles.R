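# Independent oracles and fixture builders shared across the suite.

AA_POOL <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# brute-force per-column residue counting, independent of the package's
# vectorised profile code
oracle_column_freq <- function(aln, column) {
  counts <- list()
  for (i in seq_len(nrow(aln))) {
    ch <- substr(aln$seq[[i]], column, column)
    counts[[ch]] <- (counts[[ch]] %||% 0) + 1
  }
  out <- tibble::tibble(
    residue = names(counts),
    count = as.integer(unlist(counts)),
    frequency = as.integer(unlist(counts)) / nrow(aln)
  )
  out[order(-out$frequency, out$residue), ]
}

# hypergeometric upper tail P(X >= k) by direct log-factorial summation
oracle_hyper_tail <- function(k, count_a, count_b, n) {
  jmax <- min(count_a, count_b)
  if (k > jmax) {
    return(0)
  }
  j <- seq(k, jmax)
  terms <- lchoose(count_b, j) + lchoose(n - count_b, count_a - j) -
    lchoose(n, count_a)
  sum(exp(terms))
}

# naive agglomerative clustering straight from the definition: repeatedly
# merge the closest pair of clusters (linkage-defined) while the merge
# distance stays within the cutoff
oracle_cluster <- function(d, cutoff, linkage) {
  clusters <- as.list(rownames(d))
  link <- switch(linkage, furthest = max, average = mean, nearest = min)
  repeat {
    n <- length(clusters)
    if (n == 1) break
    bestd <- Inf
    best <- c(NA, NA)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        dd <- link(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd) {
          bestd <- dd
          best <- c(i, j)
        }
      }
    }
    if (bestd > cutoff) break
    clusters[[best[[1]]]] <- c(clusters[[best[[1]]]], clusters[[best[[2]]]])
    clusters[[best[[2]]]] <- NULL
  }
  clusters
}

# canonical form of a partition for label-free comparison
canonical_partition <- function(groups) {
  sorted <- unname(lapply(groups, function(g) sort(unname(unlist(g)))))
  sorted[order(vapply(sorted, `[[`, character(1), 1))]
}

partition_from_clusters <- function(clusters_tbl) {
  canonical_partition(split(clusters_tbl$id, clusters_tbl$otu))
}

# random gapped alignment fixture
rand_aln <- function(n, nc, seed, gap_rate = 0.1, pool = AA_POOL) {
  withr::with_seed(seed, {
    m <- matrix(sample(pool, n * nc, replace = TRUE), n, nc)
    if (gap_rate > 0) m[matrix(runif(n * nc) < gap_rate, n, nc)] <- "-"
    alignment(sprintf("s%03d", seq_len(n)), apply(m, 1, paste, collapse = ""))
  })
}

# two-column alignment with a perfectly associated residue pair in the
# first half of the rows; remaining rows spread over low-frequency residues
# so only the planted events clear the 20% presence floor
perfect_pair_aln <- function(n_total) {
  half <- n_total / 2
  filler <- rep(c("D", "E", "F", "G"), length.out = half)
  col1 <- c(rep("A", half), filler)
  col2 <- c(rep("W", half), rev(filler))
  alignment(
    sprintf("s%03d", seq_len(n_total)),
    paste0(col1, col2)
  )
}

# random unaligned nucleotide sequences
rand_nt <- function(len, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
}

# mutate exactly k positions of a nucleotide string
mutate_nt <- function(s, k, seed) {
  withr::with_seed(seed, {
    x <- strsplit(s, "")[[1]]
    pos <- sample.int(length(x), k)
    x[pos] <- vapply(
      x[pos],
      function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
      character(1)
    )
    paste(x, collapse = "")
  })
}

# synthetic reference peptide used by the amplicon/signature fixtures:
# random background with the ArsC-like signature residues planted at their
# reference positions
synthetic_reference <- function(len = 141, seed = 99,
                                planted = c(
                                  `12` = "C", `22` = "I", `60` = "R",
                                  `94` = "R", `95` = "P", `106` = "C",
                                  `107` = "R", `108` = "P"
                                )) {
  withr::with_seed(seed, {
    aa <- sample(AA_POOL, len, replace = TRUE)
    aa[as.integer(names(planted))] <- planted
    paste(aa, collapse = "")
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
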