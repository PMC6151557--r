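# Sequential-and-structural features (SSF): 473 features per sequence at
# the default settings, concatenating
#   20  per-amino-acid PSSM column averages
#   420 weighted consensus-sequence 1-gram + 2-gram frequencies
#   6   secondary-structure sequence features (state fractions, longest
#       H/E runs, strand-helix-strand motif frequency)
#   3   global state-probability means (3^n, n = 1)
#   24  local state-probability means over lambda = 8 row segments

#' Uniform amino-acid background frequencies
#'
#' Default background for the consensus-sequence transform. A user-supplied
#' vector (e.g. frequencies observed in the Protein Data Bank) may be used
#' instead; it must be positive, named by the 20 amino acids, and sum to 1.
#'
#' @return Named length-20 numeric vector, each entry 1/20.
#' @export
uniform_background <- function() {
  setNames(rep(1 / 20, 20), AA20)
}

assert_background <- function(bg) {
  if (length(bg) != 20 || is.null(names(bg)) || !setequal(names(bg), AA20)) {
    abort("background frequencies must be a named length-20 vector over the amino-acid alphabet")
  }
  bg <- bg[AA20]
  if (any(bg <= 0) || abs(sum(bg) - 1) > 1e-6) {
    abort("background frequencies must be positive and sum to 1")
  }
  bg
}

#' Average PSSM score per amino acid
#'
#' Column means of the L x 20 position-specific score matrix: component j
#' is the average score of mutating to amino acid j over all positions.
#'
#' @param pssm A [pssm_profile()] object.
#' @return Named length-20 numeric vector in canonical order.
#' @export
pssm_average_scores <- function(pssm) {
  if (nrow(pssm$scores) == 0) abort("PSSM profile has no rows")
  colMeans(pssm$scores)
}

#' Consensus sequence of a PSSM
#'
#' Exponentiates each score against the background
#' (\eqn{S'_{ij} = 2^{S_{ij}} p_j}) and takes, at every position, the amino
#' acid with the largest weighted score. Ties are broken alphabetically.
#'
#' @param pssm A [pssm_profile()] object.
#' @param background Named length-20 background frequency vector; defaults
#'   to uniform.
#' @return Consensus residue string of the same length as the profile.
#' @export
consensus_sequence <- function(pssm, background = uniform_background()) {
  bg <- assert_background(background)
  if (nrow(pssm$scores) == 0) abort("PSSM profile has no rows")
  w <- sweep(2^pssm$scores, 2, bg, `*`)
  paste0(AA20[apply(w, 1, which.max)], collapse = "")
}

#' Weighted n-gram features of a consensus sequence
#'
#' Concatenates the 1-gram frequencies weighted by 20/420 and the
#' contiguous 2-gram frequencies weighted by 400/420, so the 420-vector
#' always sums to 1.
#'
#' @param consensus Consensus residue string (length at least 2, so the
#'   2-gram block is defined).
#' @return Named length-420 numeric vector (20 monogram + 400 dipeptide
#'   components in lexicographic order).
#' @export
consensus_ngram_features <- function(consensus) {
  L <- nchar(consensus)
  if (L < 2) {
    abort("consensus sequence must have length >= 2 for the 2-gram block")
  }
  ch <- strsplit(consensus, "")[[1]]
  f1 <- as.numeric(table(factor(ch, levels = AA20))) / L
  bi <- paste0(ch[-L], ch[-1])
  f2 <- as.numeric(table(factor(bi, levels = all_grams(2)))) / (L - 1)
  setNames(c(20 / 420 * f1, 400 / 420 * f2), c(AA20, all_grams(2)))
}

#' Secondary-structure sequence features
#'
#' Six features from the H/E/C state string: the three state fractions,
#' the longest H run and longest E run normalised by sequence length, and
#' the frequency of the strand-helix-strand (E-H-E) motif among the runs
#' of the coil-free segment sequence (number of E,H,E run triplets divided
#' by the number of length-3 run windows, floored at 1).
#'
#' @param ssp An [ss2_profile()] object, or a state string.
#' @return Named length-6 numeric vector:
#'   `f_H, f_E, f_C, maxrun_H, maxrun_E, ehe`.
#' @export
ss_sequence_features <- function(ssp) {
  states <- if (inherits(ssp, "ss2_profile")) ssp$states else ssp
  ch <- strsplit(states, "")[[1]]
  L <- length(ch)
  if (L == 0) abort("empty secondary-structure state string")
  fr <- as.numeric(table(factor(ch, levels = SS3))) / L  # C, H, E
  r <- rle(ch)
  maxrun <- function(s) {
    len <- r$lengths[r$values == s]
    if (length(len) == 0) 0 else max(len)
  }
  seg <- r$values[r$values != "C"]  # ordered H/E runs (Sseg)
  n_win <- max(1, length(seg) - 2)
  ehe <- if (length(seg) >= 3) {
    sum(seg[seq_len(length(seg) - 2)] == "E" &
          seg[seq_len(length(seg) - 2) + 1] == "H" &
          seg[seq_len(length(seg) - 2) + 2] == "E")
  } else 0
  c(f_H = fr[2], f_E = fr[3], f_C = fr[1],
    maxrun_H = maxrun("H") / L, maxrun_E = maxrun("E") / L,
    ehe = ehe / n_win)
}

#' Global secondary-structure probability features
#'
#' For order `n = 1`, the mean of each state-probability column over all
#' positions (3 values, order C, H, E). Higher orders are not supported.
#'
#' @param ssp An [ss2_profile()] object.
#' @param n Feature order; only 1 is implemented.
#' @return Named length-3 numeric vector (`C`, `H`, `E`).
#' @export
ss_global_features <- function(ssp, n = 1) {
  if (n != 1) abort("only order n = 1 is supported for structural features")
  if (nrow(ssp$probabilities) == 0) abort("empty probability matrix")
  colMeans(ssp$probabilities)
}

# Contiguous row segments with sizes differing by at most one; the
# remainder goes to the earliest segments.
segment_sizes <- function(L, lambda) {
  base <- L %/% lambda
  base + as.integer(seq_len(lambda) <= L %% lambda)
}

#' Local secondary-structure probability features
#'
#' Splits the probability matrix rows into `lambda` contiguous segments
#' (sizes differing by at most one, remainder assigned front-first) and
#' returns each segment's per-state column means, concatenated in segment
#' order: `lambda * 3^n` values for `n = 1`.
#'
#' @param ssp An [ss2_profile()] object.
#' @param lambda Number of segments (default 8); the profile must have at
#'   least `lambda` rows.
#' @param n Feature order; only 1 is implemented.
#' @return Named numeric vector of length `3 * lambda`
#'   (`s1.C, s1.H, s1.E, s2.C, ...`).
#' @export
ss_local_features <- function(ssp, lambda = 8, n = 1) {
  if (n != 1) abort("only order n = 1 is supported for structural features")
  L <- nrow(ssp$probabilities)
  if (L < lambda) {
    abort(sprintf("profile has %d rows but lambda = %d segments requested",
                  L, lambda))
  }
  sizes <- segment_sizes(L, lambda)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  out <- unlist(lapply(seq_len(lambda), function(m) {
    colMeans(ssp$probabilities[starts[m]:ends[m], , drop = FALSE])
  }))
  names(out) <- paste0("s", rep(seq_len(lambda), each = 3), ".",
                       rep(SS3, lambda))
  out
}

ssf_vector <- function(pssm, ssp, lambda = 8, n = 1,
                       background = uniform_background()) {
  if (nrow(pssm$scores) != nchar(ssp$states)) {
    abort(sprintf(
      "PSSM length (%d) and secondary-structure length (%d) differ for '%s'",
      nrow(pssm$scores), nchar(ssp$states), pssm$sequence_id))
  }
  cons <- consensus_sequence(pssm, background)
  v <- c(pssm_average_scores(pssm),
         consensus_ngram_features(cons),
         ss_sequence_features(ssp),
         ss_global_features(ssp, n),
         ss_local_features(ssp, lambda, n))
  names(v) <- c(paste0("ssf.pssm_avg.", AA20),
                paste0("ssf.consensus.", c(AA20, all_grams(2))),
                paste0("ssf.ss_seq.",
                       c("f_H", "f_E", "f_C", "maxrun_H", "maxrun_E", "ehe")),
                paste0("ssf.ss_glob.", SS3),
                paste0("ssf.ss_loc.s", rep(seq_len(lambda), each = 3), ".",
                       rep(SS3, lambda)))
  v
}

#' Encode sequences with sequential-and-structural features
#'
#' Combines the PSSM-derived blocks (20 column averages + 420 weighted
#' consensus n-grams) with the secondary-structure blocks (6 state-sequence
#' features + `3^n` global + `lambda * 3^n` local probability means) into a
#' single vector per sequence: 473 features at the defaults
#' `lambda = 8`, `n = 1`.
#'
#' @param pssms List of [pssm_profile()] objects.
#' @param ss2s List of [ss2_profile()] objects, matched to `pssms` by
#'   position; each pair must describe sequences of equal length.
#' @param lambda Number of local segments (default 8).
#' @param n Structural feature order; only 1 is implemented.
#' @param background Amino-acid background for the consensus transform;
#'   defaults to uniform.
#' @return A feature-table tibble of width `20 + 420 + 6 + 3^n +
#'   lambda * 3^n + 1`.
#' @export
encode_ssf <- function(pssms, ss2s, lambda = 8, n = 1,
                       background = uniform_background()) {
  if (inherits(pssms, "pssm_profile")) pssms <- list(pssms)
  if (inherits(ss2s, "ss2_profile")) ss2s <- list(ss2s)
  if (length(pssms) != length(ss2s)) {
    abort("pssms and ss2s must have the same length")
  }
  rows <- lapply(seq_along(pssms), function(i) {
    ssf_vector(pssms[[i]], ss2s[[i]], lambda = lambda, n = n,
               background = background)
  })
  m <- do.call(rbind, rows)
  ids <- vapply(pssms, `[[`, character(1), "sequence_id")
  dplyr::bind_cols(tibble(sample_id = ids), as_tibble(m))
}
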