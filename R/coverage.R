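#' Pairwise distance matrix of unaligned sequences
#'
#' d(i, j) = 1 - identity from a semi-global (free end gap) pairwise
#' alignment, the distance fed to OTU clustering of clone libraries.
#'
#' @param seqs Tibble (`id`, `seq`) or named character vector of unaligned
#'   nucleotide (or peptide) sequences.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
distance_matrix <- function(seqs) {
  seqs <- as_seq_tbl(seqs)
  if (nrow(seqs) < 2) abort("Need at least two sequences for distances.")
  n <- nrow(seqs)
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- 1 - unaligned_identity(seqs$seq[[i]], seqs$seq[[j]])
    }
  }
  d
}

#' Cluster sequences into OTUs at an identity cutoff
#'
#' Hierarchical agglomerative clustering of the pairwise distance matrix,
#' cut at `cutoff` (so a 0.03 cutoff groups sequences within 97% identity).
#' The default furthest-neighbour (complete) linkage is the historical
#' DOTUR convention; `"average"` and `"nearest"` are also available.
#' Sequences are processed in lexicographic id order so ties resolve
#' deterministically; OTUs are numbered by their lexicographically first
#' member.
#'
#' @param seqs Tibble (`id`, `seq`) or named character vector; or a
#'   precomputed distance matrix from [distance_matrix()].
#' @param cutoff Distance cutoff (1 - identity), default 0.03.
#' @param linkage `"furthest"`, `"average"` or `"nearest"`.
#' @return An `otu_clustering` object: list with `clusters` (tibble `id`,
#'   `otu`), `sizes` (tibble `otu`, `size`), and scalars `cutoff`,
#'   `linkage`, `N`, `n_otus`, `n_singletons`.
#' @export
cluster_otus <- function(seqs, cutoff = 0.03,
                         linkage = c("furthest", "average", "nearest")) {
  linkage <- match.arg(linkage)
  if (is.matrix(seqs)) {
    d <- seqs
  } else {
    seqs <- as_seq_tbl(seqs)
    if (nrow(seqs) == 0) abort("Need at least one sequence.")
    if (nrow(seqs) == 1) {
      return(new_otu_clustering(
        tibble(id = seqs$id, otu = 1L), cutoff, linkage
      ))
    }
    d <- distance_matrix(seqs)
  }
  ord <- order(rownames(d))
  d <- d[ord, ord]
  method <- c(furthest = "complete", average = "average", nearest = "single")[[linkage]]
  hc <- hclust(as.dist(d), method = method)
  membership <- cutree(hc, h = cutoff)
  # renumber OTUs by first (lexicographic) member
  first_member <- tapply(names(membership), membership, min)
  renum <- setNames(rank(first_member, ties.method = "first"), names(first_member))
  clusters <- tibble(
    id = names(membership),
    otu = as.integer(renum[as.character(membership)])
  )
  new_otu_clustering(dplyr::arrange(clusters, .data$otu, .data$id), cutoff, linkage)
}

new_otu_clustering <- function(clusters, cutoff, linkage) {
  sizes <- clusters |>
    dplyr::count(.data$otu, name = "size") |>
    dplyr::arrange(.data$otu)
  out <- list(
    clusters = clusters,
    sizes = sizes,
    cutoff = cutoff,
    linkage = linkage,
    N = nrow(clusters),
    n_otus = nrow(sizes),
    n_singletons = sum(sizes$size == 1)
  )
  class(out) <- "otu_clustering"
  out
}

#' @method tidy otu_clustering
#' @export
tidy.otu_clustering <- function(x, ...) x$clusters

#' @method glance otu_clustering
#' @export
glance.otu_clustering <- function(x, ...) {
  tibble(
    N = x$N, n_otus = x$n_otus, n_singletons = x$n_singletons,
    cutoff = x$cutoff, linkage = x$linkage
  )
}

#' @export
print.otu_clustering <- function(x, ...) {
  cat(sprintf(
    "OTU clustering: %d sequences -> %d OTUs (%d singletons) at cutoff %.3g (%s linkage)\n",
    x$N, x$n_otus, x$n_singletons, x$cutoff, x$linkage
  ))
  invisible(x)
}

#' Good's coverage of a clone library
#'
#' C = (1 - n/N) x 100, the estimated percentage of the library's diversity
#' captured: N is the number of sequences and n, under the default Good's
#' (1953) reading, the number of singleton OTUs. `n_definition =
#' "distinct_otus"` instead uses the total OTU count, a literal
#' "unique OTUs" reading kept for fidelity comparisons.
#'
#' @param table An `otu_clustering` from [cluster_otus()].
#' @param n_definition `"singleton_otus"` (default) or `"distinct_otus"`.
#' @return One-row tibble with `C` (percent), `n`, `N`, `n_definition`.
#' @export
#' @examples
#' lib <- tibble::tibble(
#'   id = c("a", "b", "c", "d"),
#'   seq = c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC", "ACGTACGTTT")
#' )
#' goods_coverage(cluster_otus(lib, cutoff = 0.03))
goods_coverage <- function(table,
                           n_definition = c("singleton_otus", "distinct_otus")) {
  n_definition <- match.arg(n_definition)
  if (!inherits(table, "otu_clustering")) {
    abort("`table` must be an `otu_clustering` from cluster_otus().")
  }
  if (table$N < 1) abort("Good's coverage needs at least one sequence.")
  n <- switch(n_definition,
    singleton_otus = table$n_singletons,
    distinct_otus = table$n_otus
  )
  tibble(
    C = (1 - n / table$N) * 100,
    n = n,
    N = table$N,
    n_definition = n_definition
  )
}
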