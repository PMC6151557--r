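# Shared helpers: tiny in-code fixtures and independent brute-force
# oracles used across the test files.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(len) {
  paste0(sample(AA, len, replace = TRUE), collapse = "")
}

# PSSM profile with explicit scores (canonical column order).
toy_pssm <- function(scores, residues = NULL, id = "toy") {
  scores <- as.matrix(scores)
  colnames(scores) <- AA
  residues <- residues %||% paste0(rep("A", nrow(scores)), collapse = "")
  pssm_profile(id, residues, scores)
}

# ss2 profile from a probability matrix (columns C, H, E); states default
# to the per-row argmax.
toy_ss2 <- function(probs, states = NULL, id = "toy") {
  probs <- as.matrix(probs)
  if (is.null(states)) {
    states <- paste0(c("C", "H", "E")[apply(probs, 1, which.max)],
                     collapse = "")
  }
  ss2_profile(id, states, probs)
}

# Independent skip-gram oracle: enumerate every ordered index pair with at
# most k positions skipped in between, by explicit double loop.
brute_force_skip_bigrams <- function(residues, k) {
  ch <- strsplit(residues, "")[[1]]
  L <- length(ch)
  out <- character(0)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j > i && (j - i - 1) <= min(k, L - 2)) {
        out <- c(out, paste0(ch[i], ch[j]))
      }
    }
  }
  out
}

# Separable two-feature toy set: class 1 centred at (+2, +2), class 0 at
# (-2, -2), small noise.
separable_toy <- function(n_per_class = 10, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c(1L, 0L), each = n_per_class)
  mu <- ifelse(lab == 1, 2, -2)
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    label = lab,
    x1 = mu + rnorm(n, sd = 0.3),
    x2 = mu + rnorm(n, sd = 0.3))
}

# Labelled dataset where feature y_copy equals the 0/1 label and the rest
# are independent standard-normal noise.
label_copy_dataset <- function(n = 60, n_noise = 9, seed = 21) {
  set.seed(seed)
  lab <- rep(c(1L, 0L), length.out = n)
  noise <- matrix(rnorm(n * n_noise), nrow = n,
                  dimnames = list(NULL, paste0("noise", seq_len(n_noise))))
  dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("s", seq_len(n)), label = lab,
                   y_copy = as.numeric(lab)),
    tibble::as_tibble(noise))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
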