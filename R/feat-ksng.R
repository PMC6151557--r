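# K-skip-n-gram gapped composition. An n-gram with skip distance d picks
# n residues separated by d skipped positions; pooling d = 0..k and
# normalising the counts gives a 20^n-dimensional frequency vector (400
# features for the default dipeptide case n = 2).

#' Enumerate the skip-gram multiset of a sequence
#'
#' For gram size `n = 2`, returns every ordered residue pair at positions
#' `(i, i + d + 1)` for each skip distance `d = 0..min(k, L - 2)`;
#' `d = 0` is the contiguous dipeptide case. The union over skip distances
#' is a multiset: duplicate grams are kept, so frequencies later reflect
#' multiplicity. `k` is capped per sequence at `L - n` so at least one gram
#' exists.
#'
#' @param residues A single residue string of length at least `n`.
#' @param k Maximum number of skipped residues between selected positions
#'   (non-negative).
#' @param n Gram size; 1, 2 or 3 supported (default 2).
#' @return Character vector of grams, with multiplicity.
#' @export
#' @examples
#' enumerate_skip_grams("ACA", k = 0)   # "AC" "CA"
#' enumerate_skip_grams("ACD", k = 1)   # "AC" "CD" "AD"
enumerate_skip_grams <- function(residues, k, n = 2) {
  if (n < 1 || n > 3) abort("gram size n must be 1, 2 or 3")
  if (k < 0) abort("skip distance k must be non-negative")
  L <- nchar(residues)
  if (L < n) {
    abort(sprintf("sequence length (%d) is shorter than the gram size (%d)",
                  L, n))
  }
  ch <- strsplit(residues, "")[[1]]
  if (n == 1) return(ch)
  k_eff <- min(k, L - n)
  grams <- character(0)
  for (d in 0:k_eff) {
    step <- d + 1
    last_start <- L - (n - 1) * step
    if (last_start < 1) next
    i <- seq_len(last_start)
    g <- ch[i]
    for (j in seq_len(n - 1)) g <- paste0(g, ch[i + j * step])
    grams <- c(grams, g)
  }
  grams
}

all_grams <- function(n) {
  g <- AA20
  for (j in seq_len(n - 1)) {
    g <- as.vector(t(outer(g, AA20, paste0)))
  }
  sort(g)
}

#' Encode sequences with k-skip-n-gram composition
#'
#' Counts the skip-gram multiset of each sequence (see
#' [enumerate_skip_grams()]) and normalises by the total gram count,
#' yielding a frequency over all `20^n` grams in lexicographic order (400
#' features for the default `n = 2`). Features are named `ksng.<gram>`.
#'
#' @param sequences Tibble with columns `sample_id` and `residues`.
#' @param k Maximum skip distance (default 3), capped per sequence at
#'   `L - n`.
#' @param n Gram size (default 2).
#' @return A feature-table tibble of width `20^n + 1`.
#' @export
encode_k_skip_n_grams <- function(sequences, k = 3, n = 2) {
  lev <- all_grams(n)
  m <- t(vapply(sequences$residues, function(s) {
    g <- enumerate_skip_grams(s, k = k, n = n)
    cnt <- table(factor(g, levels = lev))
    as.numeric(cnt) / length(g)
  }, numeric(length(lev))))
  colnames(m) <- paste0("ksng.", lev)
  dplyr::bind_cols(tibble(sample_id = sequences$sample_id), as_tibble(m))
}
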