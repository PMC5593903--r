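test_that("family generation is a pure function of spec and seed", {
  spec <- family_spec(
    30, 20,
    subfamilies = subfamily(
      "s1", 0.5, tibble::tibble(column = c(5, 9), residue = c("A", "W"))
    ),
    conserved = tibble::tibble(column = 3, residue = "R", frequency = 1.0),
    gap_rate = 0.05
  )
  f1 <- generate_family(spec, seed = 1)
  f2 <- generate_family(spec, seed = 1)
  expect_identical(f1, f2)
  f3 <- generate_family(spec, seed = 2)
  expect_false(identical(f1$alignment$seq, f3$alignment$seq))
  # generation does not disturb the caller's RNG stream
  withr::with_seed(7, {
    before <- runif(1)
  })
  withr::with_seed(7, {
    generate_family(spec, seed = 3)
    expect_equal(runif(1), before)
  })
})

test_that("planted structure is written exactly at zero noise", {
  spec <- family_spec(
    40, 12,
    subfamilies = subfamily(
      "s1", 0.5, tibble::tibble(column = c(5, 9), residue = c("A", "W"))
    ),
    conserved = tibble::tibble(column = 2, residue = "P", frequency = 1.0)
  )
  fam <- generate_family(spec, seed = 11)
  m <- famsig:::aln_matrix(fam$alignment)
  members <- fam$truth$labels$id[fam$truth$labels$subfamily == "s1"]
  expect_equal(length(members), 20)
  expect_true(all(m[members, 5] == "A"))
  expect_true(all(m[members, 9] == "W"))
  # conserved column at target 1.0 reaches frequency 1.0 exactly
  expect_equal(
    column_frequencies(fam$alignment, 2)$frequency[1], 1.0
  )
})

test_that("generator rejects infeasible specs", {
  expect_error(
    family_spec(
      10, 5,
      subfamilies = subfamily(
        "s1", 0.5,
        tibble::tibble(column = c(3, 3), residue = c("A", "W"))
      )
    ),
    "two residues at column 3"
  )
  expect_error(
    family_spec(10, 5, conserved = tibble::tibble(
      column = 9, residue = "R", frequency = 0.9
    )),
    "out of range"
  )
  expect_error(
    family_spec(
      10, 5,
      subfamilies = dplyr::bind_rows(
        subfamily("a", 0.7), subfamily("b", 0.6)
      )
    ),
    "at most 1"
  )
})

test_that("fragment and gap contamination are labelled in the truth", {
  spec <- family_spec(60, 40, fragment_rate = 0.3, gap_rate = 0.05)
  fam <- generate_family(spec, seed = 21)
  frags <- fam$truth$labels$id[fam$truth$labels$is_fragment]
  expect_gt(length(frags), 0)
  occ <- vapply(
    strsplit(fam$alignment$seq, ""),
    function(x) mean(x != "-"), numeric(1)
  )
  names(occ) <- fam$alignment$id
  expect_true(all(occ[frags] <= 0.5))
  # the fragment filter removes exactly the heavily gapped records
  kept <- remove_fragments(fam$alignment)$id
  expect_true(all(setdiff(fam$alignment$id, kept) %in% c(frags)))
})

test_that("planted coevolution is recovered from generated families", {
  # N = 80 and a 40% subfamily keep the planted pair clear of both rules:
  # at 50% the background-inflated f(b) ~ 0.55 caps the relative increase
  # at 1/f(b) - 1 < 0.8, and at N = 40 chance collisions push p past 1e-10
  spec <- family_spec(
    80, 12,
    subfamilies = subfamily(
      "s1", 0.4, tibble::tibble(column = c(5, 9), residue = c("A", "W"))
    )
  )
  fam <- generate_family(spec, seed = 31)
  pairs <- detect_correlated_pairs(fam$alignment)
  expect_equal(nrow(pairs), 1)
  expect_equal(c(pairs$col_a, pairs$col_b), c(5, 9))
  sets <- assemble_sets(pairs)
  expect_equal(
    dplyr::arrange(tidy(sets), column)[, c("column", "residue")],
    tibble::tibble(column = c(5L, 9L), residue = c("A", "W"))
  )
})

test_that("amplicon generation round-trips and reports its truth", {
  ref <- synthetic_reference()
  amp <- generate_amplicons(ref, c(27, 116), n = 10, seed = 41)
  expect_identical(
    amp, generate_amplicons(ref, c(27, 116), n = 10, seed = 41)
  )
  expect_equal(unique(amp$truth$frame), 0L)
  res <- map_amplicons(amp$amplicons, ref)
  expect_true(all(res$records$ref_start == 27 & res$records$ref_end == 116))
  expect_error(generate_amplicons(ref, c(100, 200), n = 1), "outside")
})

test_that("higher substitution rates degrade mappability monotonically", {
  ref <- synthetic_reference()
  frac_mapped <- vapply(c(0, 0.25, 0.6), function(rate) {
    amp <- generate_amplicons(
      ref, c(27, 116),
      n = 20, substitution_rate = rate, seed = 43
    )
    # unmappable records each warn; here only the mapped fraction matters
    res <- suppressWarnings(map_amplicons(amp$amplicons, ref, min_score = 150))
    mean(res$records$mapped)
  }, numeric(1))
  expect_equal(frac_mapped[[1]], 1)
  expect_true(all(diff(frac_mapped) <= 0))
  expect_lt(frac_mapped[[3]], 1)
})

test_that("clone libraries reproduce the planted OTU structure", {
  lib <- generate_clone_library(
    c(5, 3, 1, 1),
    within_otu_distance = 0.01, between_otu_distance = 0.10, seed = 51
  )
  expect_identical(
    lib, generate_clone_library(
      c(5, 3, 1, 1),
      within_otu_distance = 0.01, between_otu_distance = 0.10, seed = 51
    )
  )
  ot <- cluster_otus(lib$library, cutoff = 0.03)
  expect_equal(ot$n_otus, 4)
  expect_equal(ot$n_singletons, 2)
  expect_equal(goods_coverage(ot)$C, 80)
  # recovered clusters equal the planted labels as a partition
  expect_equal(
    partition_from_clusters(ot$clusters),
    canonical_partition(split(lib$truth$id, lib$truth$otu))
  )
  expect_error(
    generate_clone_library(c(2, 2), 0.1, 0.05),
    "must exceed"
  )
})
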