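# Synthetic fixture generator: balanced sets of protein sequences with
# matching PSSM and secondary-structure profiles and a controllable class
# signal, so the whole pipeline can be exercised without databases or
# external profile tools. The sequences and profiles are synthetic test
# material, not biological ground truth.

# PSI-BLAST's own column order, used when writing fixture PSSM files so
# the reader's column remapping is exercised.
PSIBLAST_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Residues whose enrichment marks the synthetic positive class; chosen as
# a plausible DNA-binding-like composition bias (basic + small residues).
POSITIVE_BIAS_RESIDUES <- c("K", "R", "G", "S")

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha
  g / sum(g)
}

fixture_sequence <- function(len, signal_strength) {
  p <- rep(1 / 20, 20)
  names(p) <- AA20
  bias <- setNames(rep(0, 20), AA20)
  bias[POSITIVE_BIAS_RESIDUES] <- 1 / length(POSITIVE_BIAS_RESIDUES)
  p <- (1 - signal_strength) * p + signal_strength * bias
  paste0(sample(AA20, len, replace = TRUE, prob = p), collapse = "")
}

fixture_pssm <- function(sequence_id, residues) {
  ch <- strsplit(residues, "")[[1]]
  scores <- matrix(round(stats::rnorm(length(ch) * 20, mean = -2, sd = 2)),
                   nrow = length(ch))
  colnames(scores) <- AA20
  for (i in seq_along(ch)) {
    scores[i, ch[i]] <- round(stats::rnorm(1, mean = 6, sd = 2))
  }
  scores[] <- pmin(pmax(scores, -9), 13)
  pssm_profile(sequence_id, residues, scores)
}

fixture_ss2 <- function(sequence_id, len, ss_bias, positive) {
  alpha <- c(C = 2, H = 2, E = 2)
  if (positive) alpha["H"] <- 2 + 8 * ss_bias
  probs <- t(vapply(seq_len(len), function(i) rdirichlet1(alpha), numeric(3)))
  probs <- round(probs, 3)
  states <- SS3[apply(probs, 1, which.max)]
  ss2_profile(sequence_id, paste0(states, collapse = ""), probs)
}

write_pssm_file <- function(pssm, path) {
  scores <- pssm$scores[, PSIBLAST_ORDER, drop = FALSE]
  ch <- strsplit(pssm$residues, "")[[1]]
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weight ratio 1.0",
    paste0("    ", paste(sprintf("%3s", PSIBLAST_ORDER), collapse = " ")),
    vapply(seq_along(ch), function(i) {
      paste0(sprintf("%5d %s ", i, ch[i]),
             paste(sprintf("%3d", scores[i, ]), collapse = " "))
    }, character(1)),
    "")
  writeLines(lines, path)
}

write_ss2_file <- function(ssp, path) {
  st <- strsplit(ssp$states, "")[[1]]
  lines <- c(
    "# PSIPRED VFORMAT (synthetic fixture)",
    "",
    vapply(seq_along(st), function(i) {
      sprintf("%4d X %s  %6.3f %6.3f %6.3f", i, st[i],
              ssp$probabilities[i, 1], ssp$probabilities[i, 2],
              ssp$probabilities[i, 3])
    }, character(1)))
  writeLines(lines, path)
}

#' Generate a synthetic labelled fixture dataset
#'
#' Draws a balanced-by-design set of protein sequences with per-sequence
#' PSSM and secondary-structure profiles. Positive-class sequences have
#' their residue composition shifted toward `{K, R, G, S}` by
#' `signal_strength` (0 = indistinguishable from negatives, 1 = drawn
#' entirely from the biased subset) and their helix probability enriched
#' by `ss_bias`; negatives are uniform. PSSM scores are integers in
#' `[-9, 13]` with the emitted residue's score elevated, mirroring real
#' PSI-BLAST output ranges. Everything is deterministic given `seed`.
#'
#' @param n_positive,n_negative Class sizes (at least 1 each).
#' @param length_range Integer pair: sequence lengths are drawn uniformly
#'   from this range (minimum length 10).
#' @param seed Integer seed.
#' @param signal_strength Composition bias of positives, in `[0, 1]`.
#' @param ss_bias Helix-state enrichment of positives, in `[0, 1]`.
#' @param dir Optional directory: if given, writes `sequences.fasta`,
#'   `<id>.pssm`, `<id>.ss2` and `labels.csv` there.
#' @return A list with `sequences` (tibble `sample_id`, `residues`),
#'   `pssms` and `ss2s` (profile lists in the same order), and `labels`
#'   (tibble `sample_id`, `label` with 1 = binding).
#' @export
generate_fixture_dataset <- function(n_positive, n_negative,
                                     length_range = c(50, 80), seed = 7,
                                     signal_strength = 0.5, ss_bias = 0.3,
                                     dir = NULL) {
  if (n_positive < 1 || n_negative < 1) abort("class counts must be >= 1")
  if (length(length_range) != 2 || length_range[1] < 10 ||
      length_range[2] < length_range[1]) {
    abort("length_range must be an increasing pair with minimum >= 10")
  }
  if (signal_strength < 0 || signal_strength > 1 ||
      ss_bias < 0 || ss_bias > 1) {
    abort("signal_strength and ss_bias must lie in [0, 1]")
  }
  set.seed(seed)
  ids <- c(sprintf("pos%03d", seq_len(n_positive)),
           sprintf("neg%03d", seq_len(n_negative)))
  labels <- c(rep(1L, n_positive), rep(0L, n_negative))
  lens <- sample(seq(length_range[1], length_range[2]),
                 length(ids), replace = TRUE)
  residues <- vapply(seq_along(ids), function(i) {
    fixture_sequence(lens[i], if (labels[i] == 1) signal_strength else 0)
  }, character(1))
  pssms <- lapply(seq_along(ids), function(i) {
    fixture_pssm(ids[i], residues[i])
  })
  ss2s <- lapply(seq_along(ids), function(i) {
    fixture_ss2(ids[i], lens[i], ss_bias, labels[i] == 1)
  })
  out <- list(
    sequences = tibble(sample_id = ids, residues = residues),
    pssms = pssms, ss2s = ss2s,
    labels = tibble(sample_id = ids, label = labels))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeLines(
      unlist(purrr::map2(ids, residues, ~ c(paste0(">", .x), .y))),
      file.path(dir, "sequences.fasta"))
    purrr::walk(pssms, function(p) {
      write_pssm_file(p, file.path(dir, paste0(p$sequence_id, ".pssm")))
    })
    purrr::walk(ss2s, function(s) {
      write_ss2_file(s, file.path(dir, paste0(s$sequence_id, ".ss2")))
    })
    readr::write_csv(out$labels, file.path(dir, "labels.csv"))
  }
  out
}

#' Attach fixture labels to a feature table
#'
#' @param fm Feature table.
#' @param labels Tibble with `sample_id` and `label` columns.
#' @return The feature table with a `label` column after `sample_id`.
#' @export
add_labels <- function(fm, labels) {
  if (!all(fm$sample_id %in% labels$sample_id)) {
    abort("labels are missing for some samples")
  }
  lab <- labels$label[match(fm$sample_id, labels$sample_id)]
  dplyr::mutate(fm, label = as.integer(lab), .after = "sample_id")
}
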