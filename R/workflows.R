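#' Run the protein-family analysis workflow
#'
#' The full pipeline on one domain-family alignment: read, remove fragment
#' records, remove redundant (>70% identity) records, build the reference
#' numbering map, profile conservation, detect coevolved residue sets, and
#' classify the retained sequences against residue signatures. All reports
#' are written as TSV/JSON under `output_dir` together with a run manifest
#' (inputs, parameters, package version, stage record counts); reruns with
#' identical inputs produce byte-identical outputs.
#'
#' @param input Alignment tibble, or path to an aligned FASTA/Stockholm file.
#' @param reference_id Id of the reference record (for residue numbering).
#' @param output_dir Directory for reports (created if missing).
#' @param first_residue_number Number of the reference's first residue.
#' @param min_occupancy Fragment filter threshold.
#' @param max_identity Redundancy filter threshold.
#' @param conservation_threshold Strict conservation call threshold.
#' @param min_presence,min_increase,max_p Coevolution rule thresholds.
#' @param signatures Optional `signature_set` (e.g.
#'   `builtin_signatures("arsC")`); `NULL` skips classification.
#' @return Invisibly, a list with `alignment` (filtered), `refmap`,
#'   `conserved`, `pairs`, `sets`, `classification` (or NULL) and
#'   `manifest`.
#' @export
run_family_workflow <- function(input, reference_id, output_dir,
                                first_residue_number = 1L,
                                min_occupancy = 0.5, max_identity = 0.70,
                                conservation_threshold = 0.80,
                                min_presence = 0.20, min_increase = 0.80,
                                max_p = 1e-10, signatures = NULL) {
  written <- character(0)
  on_fail <- function(stage) {
    function(e) {
      unlink(written) # no partial report bundles
      abort(sprintf("Family workflow failed at stage '%s': %s",
                    stage, conditionMessage(e)))
    }
  }
  emit <- function(x, name) {
    path <- file.path(output_dir, name)
    readr::write_tsv(x, path)
    written <<- c(written, path)
    path
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  aln <- tryCatch(
    {
      a <- if (is.character(input)) read_alignment(input) else input
      validate_alignment(a)
      if (nrow(a) == 0) abort("Input alignment is empty.")
      a
    },
    error = on_fail("read")
  )
  n_input <- nrow(aln)

  aln_f <- tryCatch(remove_fragments(aln, min_occupancy), error = on_fail("fragments"))
  emit(attr(aln_f, "filter_report"), "fragment_filter.tsv")
  aln_r <- tryCatch(remove_redundant(aln_f, max_identity), error = on_fail("redundancy"))
  emit(attr(aln_r, "filter_report"), "redundancy_filter.tsv")
  if (nrow(aln_r) == 0) {
    unlink(written)
    abort("Family workflow failed at stage 'redundancy': no sequences survive filtering.")
  }
  write_alignment(aln_r, file.path(output_dir, "filtered_alignment.fasta"))
  written <- c(written, file.path(output_dir, "filtered_alignment.fasta"))

  refmap <- tryCatch(
    build_reference_map(aln_r, reference_id, first_residue_number),
    error = on_fail("reference_map")
  )
  conserved <- tryCatch(
    conserved_positions(aln_r, refmap, conservation_threshold),
    error = on_fail("conservation")
  )
  emit(conserved, "conserved_positions.tsv")

  pairs <- tryCatch(
    detect_correlated_pairs(
      aln_r, refmap,
      min_presence = min_presence,
      min_increase = min_increase, max_p = max_p
    ),
    error = on_fail("coevolution")
  )
  emit(pairs, "correlated_pairs.tsv")
  sets <- assemble_sets(pairs)
  jsonlite::write_json(
    split(
      tidy(sets)[, c("column", "ref_pos", "residue")],
      tidy(sets)$set
    ),
    file.path(output_dir, "coevolved_sets.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  written <- c(written, file.path(output_dir, "coevolved_sets.json"))

  classification <- NULL
  if (!is.null(signatures)) {
    classification <- tryCatch(
      classify(alignment_states(aln_r, refmap), signatures),
      error = on_fail("classification")
    )
    emit(classification$calls, "classification_calls.tsv")
    emit(classification$aggregate, "classification_summary.tsv")
  }

  manifest <- list(
    workflow = "family",
    package_version = as.character(utils::packageVersion("famsig")),
    input = if (is.character(input)) input else "<in-memory alignment>",
    reference_id = reference_id,
    parameters = list(
      first_residue_number = first_residue_number,
      min_occupancy = min_occupancy, max_identity = max_identity,
      conservation_threshold = conservation_threshold,
      min_presence = min_presence, min_increase = min_increase,
      max_p = max_p,
      signatures = if (is.null(signatures)) NULL else unique(signatures$signature)
    ),
    stages = list(
      read = list(records = n_input),
      fragments = list(kept = nrow(aln_f), removed = n_input - nrow(aln_f)),
      redundancy = list(kept = nrow(aln_r), removed = nrow(aln_f) - nrow(aln_r)),
      conservation = list(conserved_positions = nrow(conserved)),
      coevolution = list(
        pairs_tested = attr(pairs, "n_pairs_tested"),
        pairs_reported = nrow(pairs),
        sets = if (nrow(sets)) max(sets$set) else 0L
      ),
      classification = if (is.null(classification)) {
        NULL
      } else {
        list(sequences = dplyr::n_distinct(classification$calls$id))
      }
    )
  )
  jsonlite::write_json(
    manifest, file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    alignment = aln_r, refmap = refmap, conserved = conserved,
    pairs = pairs, sets = sets, classification = classification,
    manifest = manifest
  ))
}

#' Run the clone-library coverage workflow
#'
#' Distance matrix, OTU clustering at the identity cutoff (default 97%
#' identity, i.e. distance 0.03) and Good's coverage, with TSV reports and
#' a manifest under `output_dir`.
#'
#' @param input Tibble (`id`, `seq`), named character vector, or FASTA path.
#' @param output_dir Directory for reports.
#' @param cutoff Distance cutoff for OTUs.
#' @param linkage Clustering linkage (`"furthest"`, `"average"`, `"nearest"`).
#' @param n_definition Good's `n`: `"singleton_otus"` or `"distinct_otus"`.
#' @return Invisibly, a list with `otus`, `coverage`, `manifest`.
#' @export
run_coverage_workflow <- function(input, output_dir, cutoff = 0.03,
                                  linkage = "furthest",
                                  n_definition = "singleton_otus") {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(stage) {
    function(e) {
      unlink(written)
      abort(sprintf("Coverage workflow failed at stage '%s': %s",
                    stage, conditionMessage(e)))
    }
  }
  seqs <- tryCatch(
    {
      if (is.character(input) && length(input) == 1 && file.exists(input)) {
        fa <- read_fasta(input)
        tibble(id = fa$id, seq = fa$seq)
      } else {
        as_seq_tbl(input)
      }
    },
    error = on_fail("read")
  )
  otus <- tryCatch(
    cluster_otus(seqs, cutoff = cutoff, linkage = linkage),
    error = on_fail("cluster")
  )
  cov <- tryCatch(
    goods_coverage(otus, n_definition = n_definition),
    error = on_fail("coverage")
  )
  readr::write_tsv(otus$clusters, file.path(output_dir, "otu_membership.tsv"))
  written <- c(written, file.path(output_dir, "otu_membership.tsv"))
  readr::write_tsv(cov, file.path(output_dir, "goods_coverage.tsv"))
  written <- c(written, file.path(output_dir, "goods_coverage.tsv"))
  manifest <- list(
    workflow = "coverage",
    package_version = as.character(utils::packageVersion("famsig")),
    input = if (is.character(input) && length(input) == 1) input else "<in-memory sequences>",
    parameters = list(
      cutoff = cutoff, linkage = linkage, n_definition = n_definition
    ),
    stages = list(
      read = list(records = nrow(seqs)),
      cluster = list(otus = otus$n_otus, singletons = otus$n_singletons),
      coverage = list(C = cov$C)
    )
  )
  jsonlite::write_json(
    manifest, file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(otus = otus, coverage = cov, manifest = manifest))
}
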