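test_that("event catalog applies the presence floor, excluding gaps", {
  # 40 rows, col1: 50% A / 10% W / 40% spread; col2: invariant C
  col1 <- c(rep("A", 20), rep("W", 4), rep(c("D", "E", "F", "G"), 4))
  aln <- alignment(sprintf("s%03d", 1:40), paste0(col1, "C"))
  ev <- event_catalog(aln)
  expect_equal(nrow(ev), 2)
  a <- ev[ev$column == 1, ]
  expect_equal(a$residue, "A")
  expect_equal(a$count, 20L)
  expect_equal(a$fraction, 0.5)
  expect_equal(ev[ev$column == 2, ]$fraction, 1.0) # invariant column is an event
  # gap-heavy column: gap never an event
  gappy <- alignment(c("a", "b", "c"), c("-C", "-C", "AC"))
  expect_false("-" %in% event_catalog(gappy)$residue)
})

test_that("pair statistics reproduce the exact hypergeometric boundary case", {
  aln <- perfect_pair_aln(40)
  st <- pair_statistics(
    aln, list(column = 1, residue = "A"), list(column = 2, residue = "W")
  )
  expect_equal(st$f_b, 0.5)
  expect_equal(st$f_b_given_a, 1.0)
  expect_equal(st$increase_ab, 1.0)
  expect_equal(st$p_value, 1 / choose(40, 20), tolerance = 1e-12)

  # both events in all rows: no association possible
  allrows <- alignment(c("a", "b"), c("AW", "AW"))
  st2 <- pair_statistics(
    allrows, list(column = 1, residue = "A"), list(column = 2, residue = "W")
  )
  expect_equal(st2$increase_ab, 0)
  expect_equal(st2$p_value, 1.0)

  expect_error(
    pair_statistics(
      aln, list(column = 1, residue = "A"), list(column = 1, residue = "D")
    ),
    "same column"
  )
})

test_that("independent events at matched marginals show no frequency increase", {
  # b hits half of a's rows and half of the rest: f(b|a) == f(b) exactly
  col1 <- c(rep("A", 20), rep("D", 20))
  col2 <- c(rep("W", 10), rep("Y", 10), rep("W", 10), rep("Y", 10))
  aln <- alignment(sprintf("s%03d", 1:40), paste0(col1, col2))
  st <- pair_statistics(
    aln, list(column = 1, residue = "A"), list(column = 2, residue = "W")
  )
  expect_equal(st$increase_ab, 0)
  expect_equal(st$increase_ba, 0)
})

test_that("Fisher p-values match the factorial oracle and fisher.test", {
  cases <- withr::with_seed(5, {
    lapply(1:25, function(i) {
      n <- sample(5:60, 1)
      ca <- sample(1:n, 1)
      cb <- sample(1:n, 1)
      k <- sample(max(0, ca + cb - n):min(ca, cb), 1)
      list(n = n, ca = ca, cb = cb, k = k)
    })
  })
  for (cs in cases) {
    p_pkg <- phyper(cs$k - 1, cs$cb, cs$n - cs$cb, cs$ca, lower.tail = FALSE)
    p_oracle <- oracle_hyper_tail(cs$k, cs$ca, cs$cb, cs$n)
    expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
    tab <- matrix(c(
      cs$k, cs$ca - cs$k,
      cs$cb - cs$k, cs$n - cs$ca - cs$cb + cs$k
    ), 2, byrow = TRUE)
    expect_equal(
      p_pkg, stats::fisher.test(tab, alternative = "greater")$p.value,
      tolerance = 1e-9
    )
  }
})

test_that("pair detection honours every rule of the screen", {
  # perfect association at N=40: p = 1/C(40,20) ~ 7.25e-12 < 1e-10: reported
  hits <- detect_correlated_pairs(perfect_pair_aln(40))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$direction, "both")
  expect_equal(hits$p_value, 1 / choose(40, 20), tolerance = 1e-12)

  # same construction at N=30: p = 1/C(30,15) ~ 6.4e-9 > 1e-10: not reported
  miss <- detect_correlated_pairs(perfect_pair_aln(30))
  expect_equal(nrow(miss), 0)
  expect_gt(attr(miss, "n_pairs_tested"), 0)

  # i.i.d. random alignment: no pair survives the default thresholds
  noise <- rand_aln(100, 50, seed = 13, gap_rate = 0)
  expect_equal(nrow(detect_correlated_pairs(noise)), 0)

  # unsatisfiable increase threshold
  expect_equal(
    nrow(detect_correlated_pairs(perfect_pair_aln(40), min_increase = Inf)), 0
  )
})

test_that("detection is invariant to row and column permutation", {
  spec <- family_spec(
    120, 12,
    subfamilies = subfamily(
      "s1", 0.5, tibble::tibble(column = c(3, 8), residue = c("A", "W"))
    )
  )
  aln <- generate_family(spec, seed = 17)$alignment
  base <- detect_correlated_pairs(aln)
  # rows
  aln_r <- withr::with_seed(1, aln[sample.int(nrow(aln)), ])
  expect_equal(detect_correlated_pairs(aln_r), base, ignore_attr = TRUE)
  # columns (relabelled): reverse column order
  nc <- n_columns(aln)
  rev_seq <- vapply(
    strsplit(aln$seq, ""),
    function(x) paste(rev(x), collapse = ""), character(1)
  )
  aln_c <- alignment(aln$id, rev_seq)
  got <- detect_correlated_pairs(aln_c)
  remapped <- sort(c(nc + 1 - base$col_a, nc + 1 - base$col_b))
  expect_equal(sort(c(got$col_a, got$col_b)), remapped)
  expect_equal(got$p_value, base$p_value)
})

test_that("tightening any threshold never adds pairs", {
  spec <- family_spec(
    300, 20,
    subfamilies = subfamily(
      "s1", 0.4,
      tibble::tibble(column = c(2, 7, 15), residue = c("A", "W", "C"))
    )
  )
  aln <- generate_family(spec, seed = 23)$alignment
  key <- function(p) paste(p$col_a, p$res_a, p$col_b, p$res_b)
  loose <- detect_correlated_pairs(
    aln,
    min_presence = 0.10, min_increase = 0.40, max_p = 1e-6
  )
  for (args in list(
    list(min_presence = 0.30, min_increase = 0.40, max_p = 1e-6),
    list(min_presence = 0.10, min_increase = 0.90, max_p = 1e-6),
    list(min_presence = 0.10, min_increase = 0.40, max_p = 1e-20)
  )) {
    tight <- do.call(
      detect_correlated_pairs,
      c(list(aln), args)
    )
    expect_true(all(key(tight) %in% key(loose)))
  }
})

test_that("coevolved sets are connected components, never singletons", {
  pair_row <- function(ca, ra, cb, rb) {
    tibble::tibble(
      col_a = ca, ref_pos_a = NA_integer_, res_a = ra,
      col_b = cb, ref_pos_b = NA_integer_, res_b = rb,
      count_a = 10L, count_b = 10L, count_ab = 10L,
      f_a = 0.5, f_b = 0.5, f_b_given_a = 1, f_a_given_b = 1,
      increase_ab = 1, increase_ba = 1, p_value = 1e-12, direction = "both"
    )
  }
  # transitive chain -> one set of 3
  chain <- dplyr::bind_rows(pair_row(1, "A", 2, "W"), pair_row(2, "W", 3, "C"))
  sets <- assemble_sets(chain)
  expect_equal(max(sets$set), 1)
  expect_equal(nrow(sets), 3)
  # no pairs -> no sets
  expect_equal(nrow(assemble_sets(chain[0, ])), 0)
  # two disjoint pairs -> two sets of 2
  two <- dplyr::bind_rows(pair_row(1, "A", 2, "W"), pair_row(5, "D", 9, "Y"))
  s2 <- assemble_sets(two)
  expect_equal(max(s2$set), 2)
  expect_equal(as.integer(table(s2$set)), c(2L, 2L))
  # clique mode on the chain: two overlapping cliques of size 2
  cl <- assemble_sets(chain, mode = "clique")
  expect_equal(max(cl$set), 2)
  expect_true(all(table(cl$set) == 2))
})
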