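test_that("PSSM column averages match an independent mean", {
  expect_equal(unname(pssm_average_scores(toy_pssm(matrix(3, 4, 20)))),
               rep(3, 20))
  two <- toy_pssm(rbind(rep(0, 20), rep(2, 20)))
  expect_equal(unname(pssm_average_scores(two)), rep(1, 20))

  set.seed(5)
  m <- matrix(sample(-9:13, 100, replace = TRUE), nrow = 5)
  brute <- vapply(1:20, function(j) sum(m[, j]) / 5, numeric(1))
  expect_equal(unname(pssm_average_scores(toy_pssm(m))), brute)
})

test_that("consensus residues follow the background-weighted argmax", {
  row_a <- rep(0, 20); row_a[1] <- 5
  expect_equal(consensus_sequence(toy_pssm(rbind(row_a))), "A")
  # all-zero row: tie broken alphabetically
  expect_equal(consensus_sequence(toy_pssm(rbind(rep(0, 20)))), "A")
  # doubling the background weight of W wins the tie
  bg <- rep(1, 20); names(bg) <- AA; bg["W"] <- 2; bg <- bg / sum(bg)
  expect_equal(consensus_sequence(toy_pssm(rbind(rep(0, 20))), bg), "W")
  # consensus length equals profile length
  set.seed(8)
  m <- matrix(sample(-5:8, 7 * 20, replace = TRUE), nrow = 7)
  expect_equal(nchar(consensus_sequence(toy_pssm(m, residues = "AAAAAAA"))), 7)
})

test_that("consensus n-gram features are weighted and sum to one", {
  v <- consensus_ngram_features("AA")
  expect_length(v, 420)
  expect_equal(unname(v["A"]), 20 / 420)
  expect_equal(unname(v["AA"]), 400 / 420)
  expect_equal(sum(v), 1)
  expect_error(consensus_ngram_features("A"), "length >= 2")

  set.seed(9)
  for (i in 1:10) {
    expect_equal(sum(consensus_ngram_features(rand_seq(sample(2:30, 1)))), 1)
  }
})

test_that("secondary-structure sequence features match hand segmentation", {
  expect_equal(unname(ss_sequence_features("CCCC")), c(0, 0, 1, 0, 0, 0))
  expect_equal(unname(ss_sequence_features("HHHH")), c(1, 0, 0, 1, 0, 0))
  # runs of EEHHEE are E,H,E: one strand-helix-strand window
  expect_equal(unname(ss_sequence_features("EEHHEE")),
               c(2 / 6, 4 / 6, 0, 2 / 6, 2 / 6, 1))
  # coil separators keep the runs distinct
  expect_equal(unname(ss_sequence_features("ECHCE"))[6], 1)
  expect_equal(unname(ss_sequence_features("HCH"))[6], 0)
})

test_that("global probability features are the column means", {
  const <- toy_ss2(matrix(rep(c(0.2, 0.3, 0.5), each = 6), nrow = 6))
  expect_equal(unname(ss_global_features(const)), c(0.2, 0.3, 0.5))
  set.seed(9)
  g <- matrix(rgamma(18, 2), nrow = 6)
  p <- g / rowSums(g)
  glob <- ss_global_features(toy_ss2(p))
  expect_equal(unname(glob), c(mean(p[, 1]), mean(p[, 2]), mean(p[, 3])))
  expect_equal(sum(glob), 1, tolerance = 1e-12)
  expect_error(ss_global_features(const, n = 2), "n = 1")
})

test_that("local features split rows remainder-to-front", {
  expect_equal(dbpmix:::segment_sizes(10, 8), c(2, 2, 1, 1, 1, 1, 1, 1))
  expect_equal(dbpmix:::segment_sizes(16, 8), rep(2, 8))

  const <- toy_ss2(matrix(rep(c(0.2, 0.3, 0.5), each = 8), nrow = 8))
  loc <- ss_local_features(const, lambda = 8)
  expect_length(loc, 24)
  expect_equal(unname(loc), rep(c(0.2, 0.3, 0.5), 8))

  set.seed(91)
  g <- matrix(rgamma(36, 2), nrow = 12)
  p <- g / rowSums(g)
  ssp <- toy_ss2(p)
  expect_equal(unname(ss_local_features(ssp, lambda = 1)),
               unname(ss_global_features(ssp)))
  # each segment's three features sum to 1 when rows are stochastic
  loc <- ss_local_features(ssp, lambda = 4)
  expect_equal(unname(tapply(loc, rep(1:4, each = 3), sum)), rep(1, 4),
               ignore_attr = TRUE)
  expect_error(ss_local_features(ssp, lambda = 13), "rows")
})

test_that("the full SSF encoding has the 473-dimensional block layout", {
  set.seed(10)
  L <- 30
  m <- matrix(sample(-9:13, L * 20, replace = TRUE), nrow = L)
  res <- rand_seq(L)
  pssm <- toy_pssm(m, residues = res, id = "s1")
  g <- matrix(rgamma(L * 3, 2), nrow = L)
  ssp <- toy_ss2(g / rowSums(g), id = "s1")

  fm <- encode_ssf(pssm, ssp)
  fn <- setdiff(names(fm), "sample_id")
  expect_length(fn, 473)
  expect_equal(sum(startsWith(fn, "ssf.pssm_avg.")), 20)
  expect_equal(sum(startsWith(fn, "ssf.consensus.")), 420)
  expect_equal(sum(startsWith(fn, "ssf.ss_seq.")), 6)
  expect_equal(sum(startsWith(fn, "ssf.ss_glob.")), 3)
  expect_equal(sum(startsWith(fn, "ssf.ss_loc.")), 24)
  # PSI-BLAST sub-block 440, PSI-PRED sub-block 33 = 8 * 3 + 3 + 6
  expect_equal(sum(startsWith(fn, "ssf.pssm_avg.") |
                     startsWith(fn, "ssf.consensus.")), 440)
  expect_equal(473 - 440, 33)

  expect_error(encode_ssf(pssm, toy_ss2(matrix(1 / 3, 10, 3))), "differ")
  expect_error(encode_ssf(pssm, ssp, n = 2), "n = 1")
})

test_that("SSF output width follows 446 + 3^n + lambda * 3^n", {
  set.seed(14)
  L <- 24
  m <- matrix(sample(-5:5, L * 20, replace = TRUE), nrow = L)
  pssm <- toy_pssm(m, residues = rand_seq(L))
  g <- matrix(rgamma(L * 3, 2), nrow = L)
  ssp <- toy_ss2(g / rowSums(g))
  for (lambda in c(1, 4, 8, 12)) {
    fm <- encode_ssf(pssm, ssp, lambda = lambda)
    expect_length(setdiff(names(fm), "sample_id"), 446 + 3 + 3 * lambda)
  }
})
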