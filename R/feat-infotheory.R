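# Information-theoretic composition features: Shannon entropy of the
# amino-acid composition, relative Shannon entropy (Kullback-Leibler
# divergence from the uniform composition), and their difference, the
# information gain score.

#' Amino-acid composition of a sequence
#'
#' @param residues Character vector of residue strings over the standard
#'   alphabet.
#' @return For a single string, a named length-20 numeric vector of
#'   frequencies in canonical order; for a vector, a matrix with one row
#'   per sequence. Frequencies sum to 1 for non-empty sequences.
#' @export
aa_composition <- function(residues) {
  comp1 <- function(s) {
    if (!nzchar(s)) abort("cannot compute composition of an empty sequence")
    ch <- strsplit(s, "")[[1]]
    if (!all(ch %in% AA20)) {
      abort("sequence contains residues outside the 20-letter alphabet")
    }
    tab <- table(factor(ch, levels = AA20))
    as.numeric(tab) / length(ch)
  }
  m <- t(vapply(residues, comp1, numeric(20)))
  colnames(m) <- AA20
  if (length(residues) == 1) m[1, ] else m
}

#' Shannon entropy of the amino-acid composition
#'
#' \eqn{SEn = -\sum_i p_i \log_2 p_i} over the 20 amino acids, with the
#' convention \eqn{0 \log 0 = 0}. Bounded by \eqn{[0, \log_2 20]} bits.
#'
#' @param residues Character vector of residue strings.
#' @return Numeric vector of entropies in bits.
#' @export
#' @examples
#' shannon_entropy("AAAAA")                  # 0
#' shannon_entropy("ACDEFGHIKLMNPQRSTVWY")   # log2(20)
shannon_entropy <- function(residues) {
  p <- rbind(aa_composition(residues))
  apply(p, 1, function(pi) {
    pi <- pi[pi > 0]
    -sum(pi * log2(pi))
  })
}

#' Relative Shannon entropy of the composition
#'
#' \eqn{RSEn = \sum_i p_i \log_2(p_i / p_0)} with \eqn{p_0 = 1/20}: the
#' Kullback-Leibler divergence of the sequence composition from the uniform
#' amino-acid distribution. Always non-negative; zero exactly when the
#' composition is uniform over all 20 residues.
#'
#' @inheritParams shannon_entropy
#' @return Numeric vector of relative entropies in bits.
#' @export
relative_shannon_entropy <- function(residues) {
  p <- rbind(aa_composition(residues))
  apply(p, 1, function(pi) {
    pi <- pi[pi > 0]
    sum(pi * log2(pi * 20))
  })
}

#' Information gain score
#'
#' The difference `shannon_entropy - relative_shannon_entropy`.
#'
#' @inheritParams shannon_entropy
#' @return Numeric vector in bits.
#' @export
information_gain_score <- function(residues) {
  shannon_entropy(residues) - relative_shannon_entropy(residues)
}

#' Encode sequences with the information-theory features
#'
#' Produces the three composition-level features per sequence: Shannon
#' entropy (`it.SEn`), relative Shannon entropy (`it.RSEn`) and information
#' gain score (`it.IGS`).
#'
#' @param sequences Tibble with columns `sample_id` and `residues`, as
#'   returned by [read_fasta()].
#' @return A feature-table tibble with columns `sample_id`, `it.SEn`,
#'   `it.RSEn`, `it.IGS`.
#' @export
encode_information_theory <- function(sequences) {
  sen <- shannon_entropy(sequences$residues)
  rsen <- relative_shannon_entropy(sequences$residues)
  tibble(sample_id = sequences$sample_id,
         it.SEn = unname(sen),
         it.RSEn = unname(rsen),
         it.IGS = unname(sen - rsen))
}
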