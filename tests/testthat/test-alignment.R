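test_that("aligned FASTA parses into an alignment tibble", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-D", ">b", "aced"), path)
  aln <- read_alignment(path)
  expect_equal(aln$id, c("a", "b"))
  expect_equal(aln$seq, c("AC-D", "ACED")) # uppercased on read
  expect_equal(n_columns(aln), 4L)
  expect_equal(attr(aln, "alphabet"), "protein")
})

test_that("Stockholm annotation lines are skipped, '.' gaps normalised", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-D", ">b", "ACED"), fa)
  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c(
    "# STOCKHOLM 1.0",
    "#=GF ID  demo",
    "a  AC.D",
    "b  ACED",
    "#=GC seq_cons  ACxD",
    "//"
  ), sto)
  expect_equal(
    read_alignment(sto)[, c("id", "seq")],
    read_alignment(fa)[, c("id", "seq")]
  )
})

test_that("malformed inputs raise informative parse/invariant errors", {
  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD", ">b", "ACED"), ragged)
  expect_error(read_alignment(ragged), "equal length")

  headerless <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACD", "ACE"), headerless)
  expect_error(read_alignment(headerless), "line 1")

  bad_sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "a AC D E"), bad_sto)
  expect_error(read_alignment(bad_sto, format = "stockholm"), "line 2")

  expect_error(alignment(c("a", "a"), c("AC", "AC")), "unique")
})

test_that("alignments round-trip through FASTA writing", {
  aln <- rand_aln(6, 25, seed = 11)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, path, width = 10)
  back <- read_alignment(path)
  expect_equal(back$id, aln$id)
  expect_equal(back$seq, aln$seq)
})

test_that("pairwise identity counts matches over co-occupied columns", {
  expect_equal(pairwise_identity("ACDE", "ACDF"), 0.75)
  expect_equal(pairwise_identity("AC-E", "AC-E"), 1.0)
  expect_equal(pairwise_identity("A---", "-CDE"), 0.0)
  expect_error(pairwise_identity("AC", "ACD"), "length")
})

test_that("pairwise identity is symmetric and gap-column-insertion invariant", {
  for (seed in 1:5) {
    aln <- rand_aln(2, 30, seed = seed, gap_rate = 0.2)
    a <- aln$seq[[1]]
    b <- aln$seq[[2]]
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    # insert a column gapped in both at position 10
    a2 <- paste0(substr(a, 1, 9), "-", substr(a, 10, nchar(a)))
    b2 <- paste0(substr(b, 1, 9), "-", substr(b, 10, nchar(b)))
    expect_equal(pairwise_identity(a2, b2), pairwise_identity(a, b))
  }
})

test_that("reference maps number non-gap reference columns consecutively", {
  aln <- alignment(c("ref", "x"), c("M-KC", "MAKC"))
  rm_ <- build_reference_map(aln, "ref")
  expect_equal(rm_$column, c(1L, 3L, 4L))
  expect_equal(rm_$ref_pos, c(1L, 2L, 3L))
  expect_equal(col_to_ref(rm_, c(1, 2, 3)), c(1L, NA, 2L))
  expect_equal(ref_to_col(rm_, 3), 4L)

  # ungapped reference with offset start: column i -> i + start - 1
  aln2 <- alignment("r", paste(rep("A", 10), collapse = ""))
  rm2 <- build_reference_map(aln2, "r", first_residue_number = 5)
  expect_equal(rm2$ref_pos, rm2$column + 4L)

  expect_error(build_reference_map(aln, "absent"), "not found")
  expect_warning(
    rm3 <- build_reference_map(alignment(c("g", "x"), c("----", "ACDE")), "g"),
    "all gaps"
  )
  expect_equal(nrow(rm3), 0)
})

test_that("inserting all-gap columns shifts map columns but not numbering", {
  aln <- alignment(c("ref", "x"), c("MKCDE", "MKCDE"))
  rm1 <- build_reference_map(aln, "ref")
  aln2 <- alignment(c("ref", "x"), c("MK--CDE", "MK--CDE"))
  rm2 <- build_reference_map(aln2, "ref")
  expect_equal(rm1$ref_pos, rm2$ref_pos)
  expect_false(identical(rm1$column, rm2$column))
})

test_that("fragment filter drops low-occupancy records and is idempotent", {
  aln <- alignment(
    c("full", "frag", "half"),
    c("ACDEFGHIKL", "A---------", "ACDEF-----")
  )
  out <- remove_fragments(aln)
  expect_equal(out$id, c("full", "half")) # 50% occupancy kept (>=)
  expect_equal(remove_fragments(out)$id, out$id)
  expect_equal(remove_fragments(aln, min_occupancy = 0)$id, aln$id)
  rep_ <- attr(out, "filter_report")
  expect_equal(rep_$occupancy, c(1, 0.1, 0.5))
})

test_that("redundancy filter enforces the pairwise identity ceiling", {
  dup <- alignment(c("a", "b"), c("ACDEF", "ACDEF"))
  expect_equal(remove_redundant(dup)$id, "a")

  # mutual identity 0.4 < 0.7: all kept
  tri <- alignment(c("a", "b", "c"), c("ACDEF", "ACGHI", "AKGEW"))
  expect_equal(remove_redundant(tri)$id, c("a", "b", "c"))

  # property fixture: families of near-duplicates force removals
  base <- rand_aln(12, 40, seed = 21, gap_rate = 0)
  kids <- dplyr::bind_rows(lapply(1:4, function(k) {
    dplyr::mutate(base,
      id = paste0(id, "_v", k),
      seq = vapply(seq, function(s) {
        x <- strsplit(s, "")[[1]]
        pos <- withr::with_seed(k * 100 + 7, sample.int(40, 6))
        x[pos] <- "A"
        paste(x, collapse = "")
      }, character(1))
    )
  }))
  fam <- dplyr::bind_rows(base, kids)
  out <- remove_redundant(fam, max_identity = 0.70)
  expect_lt(nrow(out), nrow(fam))
  im <- identity_matrix(out)
  expect_lte(max(im[upper.tri(im)]), 0.70)
  again <- remove_redundant(out, max_identity = 0.70)
  expect_equal(again$id, out$id) # fixed point
})

test_that("decrease_redundancy drops near-duplicates and outliers", {
  core <- rand_nt(120, seed = 31)
  homologs <- c(
    h1 = core,
    h2 = mutate_nt(core, 10, seed = 32),
    h3 = mutate_nt(core, 20, seed = 33)
  )
  # exact duplicate -> one survivor
  out <- decrease_redundancy(c(homologs, dup = core))
  expect_equal(out$id, c("h1", "h2", "h3"))
  expect_equal(
    attr(out, "filter_report")$reason[[4]], "too_similar"
  )
  # unrelated random sequence -> dropped as an outlier
  out2 <- decrease_redundancy(c(homologs, junk = rand_nt(120, seed = 99)))
  expect_false("junk" %in% out2$id)
  expect_equal(
    attr(out2, "filter_report")$reason[attr(out2, "filter_report")$id == "junk"],
    "outlier"
  )
  # identity thresholds wide open -> input unchanged
  out3 <- decrease_redundancy(homologs, max_similarity = 1, min_similarity = 0)
  expect_equal(out3$id, names(homologs))
})
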