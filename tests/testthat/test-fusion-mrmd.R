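encode_blocks <- function(n = 4, seed = 40) {
  set.seed(seed)
  seqs <- tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    residues = vapply(seq_len(n), function(i) rand_seq(25), character(1)))
  list(it = encode_information_theory(seqs),
       ksng = encode_k_skip_n_grams(seqs))
}

test_that("fusing blocks concatenates columns and keeps prefixes", {
  b <- encode_blocks()
  both <- concat_features(b$it, b$ksng)
  expect_length(setdiff(names(both), "sample_id"), 403)
  single <- concat_features(b$it)
  expect_equal(single, b$it)

  wrong <- b$ksng
  wrong$sample_id[1] <- "other"
  expect_error(concat_features(b$it, wrong), "other")
})

test_that("the full three-block fusion is 876 features wide", {
  set.seed(41)
  L <- 20
  seqs <- tibble::tibble(sample_id = "s1", residues = rand_seq(L))
  pssm <- toy_pssm(matrix(sample(-5:5, L * 20, TRUE), nrow = L),
                   residues = seqs$residues, id = "s1")
  g <- matrix(rgamma(L * 3, 2), nrow = L)
  ssp <- toy_ss2(g / rowSums(g), id = "s1")
  fm <- encode_features(seqs, pssms = list(pssm), ss2s = list(ssp),
                        features = c("ssf", "it", "ksng"))
  expect_length(setdiff(names(fm), "sample_id"), 876)
  expect_error(encode_features(seqs, features = "ssf"), "profiles")
})

test_that("MRMD ranks a label-copy feature first among noise", {
  ds <- label_copy_dataset(n = 60, n_noise = 9, seed = 21)
  rk <- mrmd_rank(ds)
  expect_equal(rk$feature[1], "y_copy")
  expect_equal(rk$relevance[1], 1)
  expect_equal(rk$rank, 1:10)
})

test_that("relevance conventions: constant and duplicated features", {
  ds <- label_copy_dataset(seed = 22)
  ds$flat <- 5
  ds$noise1_dup <- ds$noise1
  rk <- mrmd_rank(ds)
  expect_equal(rk$relevance[rk$feature == "flat"], 0)
  expect_equal(rk$relevance[rk$feature == "noise1"],
               rk$relevance[rk$feature == "noise1_dup"])
  expect_error(mrmd_rank(dplyr::mutate(ds, label = 1L)), "both classes")
})

test_that("ranking is invariant to positive affine feature rescaling", {
  ds <- label_copy_dataset(seed = 23)
  scaled <- dplyr::mutate(ds, noise2 = 100 * noise2 + 7,
                          noise5 = 0.001 * noise5 - 3)
  expect_equal(mrmd_rank(scaled)$feature, mrmd_rank(ds)$feature)
})

test_that("combined scores are monotone in relevance at fixed distance", {
  ds <- label_copy_dataset(seed = 24)
  rk <- mrmd_rank(ds)
  # between any two features, larger relevance with distance held equal
  # (within tolerance) must not rank lower
  for (i in seq_len(nrow(rk) - 1)) {
    expect_gte(rk$combined[i], rk$combined[i + 1])
  }
  rk2 <- mrmd_rank(ds, relevance_weight = 2, distance_weight = 1)
  expect_equal(rk2$combined,
               2 * rk2$relevance + rk2$distance, tolerance = 1e-12)
})

test_that("selection keeps top-ranked features deterministically", {
  ds <- label_copy_dataset(seed = 21)
  rk <- mrmd_rank(ds)
  all_kept <- mrmd_select(ds, rk, m = 10)
  expect_setequal(setdiff(names(all_kept), c("sample_id", "label")),
                  setdiff(names(ds), c("sample_id", "label")))
  expect_equal(setdiff(names(all_kept), c("sample_id", "label")), rk$feature)

  one <- mrmd_select(ds, rk, m = 1)
  expect_equal(setdiff(names(one), c("sample_id", "label")), "y_copy")
  expect_error(mrmd_select(ds, rk, m = 99), "m must be")

  auto <- mrmd_select(ds, rk, m = "auto", seed = 5)
  expect_lte(attr(auto, "mrmd_m"), 5)
  sweep <- attr(auto, "mrmd_sweep")
  expect_gte(max(sweep$cv_accuracy), 0.95)
  auto2 <- mrmd_select(ds, rk, m = "auto", seed = 5)
  expect_identical(names(auto), names(auto2))
})
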