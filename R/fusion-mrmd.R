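# Feature fusion and max-relevance-max-distance (MRMD) dimension
# reduction. MRMD scores each feature by (i) relevance: the absolute
# Pearson correlation with the binary class label, and (ii) distance: how
# far the (standardized) feature column lies, on average, from all other
# feature columns. A weighted sum of the two ranks the features; selection
# keeps the top m, or chooses m by internal cross-validation.

#' Concatenate feature blocks column-wise
#'
#' Joins several feature tables for the same samples into one mixed
#' feature set, preserving block-prefixed names. All blocks must carry
#' identical `sample_id` vectors in identical order.
#'
#' @param ... Feature-table tibbles, or a single list of them.
#' @return A feature-table tibble whose width is the sum of the block
#'   widths. A `label` column, if present in any block, is kept once
#'   (blocks carrying conflicting labels are an error).
#' @export
concat_features <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1 && is.list(blocks[[1]]) &&
      !is.data.frame(blocks[[1]])) {
    blocks <- blocks[[1]]
  }
  if (length(blocks) == 0) abort("no feature blocks given")
  ids <- blocks[[1]]$sample_id
  for (b in blocks[-1]) {
    if (!identical(b$sample_id, ids)) {
      off <- union(setdiff(b$sample_id, ids), setdiff(ids, b$sample_id))
      if (length(off) == 0) off <- "(same ids, different order)"
      abort(paste0("sample_id mismatch across feature blocks: ",
                   paste(head(off, 5), collapse = ", ")))
    }
  }
  labs <- purrr::compact(lapply(blocks, function(b) b[["label"]]))
  if (length(labs) > 1 &&
      !all(vapply(labs[-1], identical, logical(1), labs[[1]]))) {
    abort("feature blocks carry conflicting label columns")
  }
  stripped <- lapply(blocks, function(b) b[, feature_names(b), drop = FALSE])
  all_names <- unlist(lapply(stripped, names))
  if (anyDuplicated(all_names)) {
    abort(paste0("duplicate feature names across blocks: ",
                 paste(head(unique(all_names[duplicated(all_names)]), 5),
                       collapse = ", ")))
  }
  out <- dplyr::bind_cols(c(list(tibble(sample_id = ids)), stripped))
  if (length(labs) > 0) {
    out <- dplyr::mutate(out, label = labs[[1]], .after = "sample_id")
  }
  assert_feature_table(out)
}

#' Encode sequences with one or more feature blocks
#'
#' Convenience wrapper running the requested encoders and fusing their
#' blocks with [concat_features()]. The seven single and mixed feature
#' sets arise from the subsets of `features`.
#'
#' @param sequences Tibble with `sample_id` and `residues` columns.
#' @param pssms,ss2s Profile lists matched to `sequences` by position;
#'   required when `"ssf"` is requested.
#' @param features Character subset of `c("it", "ksng", "ssf")`, encoded
#'   and concatenated in the given order.
#' @param k,n_gram K-skip-n-gram parameters (see
#'   [encode_k_skip_n_grams()]).
#' @param lambda,background SSF parameters (see [encode_ssf()]).
#' @return A fused feature-table tibble.
#' @export
encode_features <- function(sequences, pssms = NULL, ss2s = NULL,
                            features = c("it", "ksng", "ssf"),
                            k = 3, n_gram = 2, lambda = 8,
                            background = uniform_background()) {
  features <- match.arg(features, several.ok = TRUE)
  blocks <- lapply(features, function(f) {
    switch(f,
      it = encode_information_theory(sequences),
      ksng = encode_k_skip_n_grams(sequences, k = k, n = n_gram),
      ssf = {
        if (is.null(pssms) || is.null(ss2s)) {
          abort(paste0("the 'ssf' encoder needs PSSM and .ss2 profiles; ",
                       "pass them via pssms= and ss2s= (see read_pssm(), ",
                       "read_ss2())"))
        }
        encode_ssf(pssms, ss2s, lambda = lambda, background = background)
      })
  })
  concat_features(blocks)
}

std_columns <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  z <- sweep(m, 2, mu, `-`)
  ok <- s > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2, s[ok], `/`)
  z[, !ok] <- 0
  z
}

assert_labeled <- function(data) {
  assert_feature_table(data)
  if (!"label" %in% names(data)) {
    abort("a labelled feature table (with a 0/1 'label' column) is required")
  }
  if (length(unique(data$label)) < 2) {
    abort("both classes must be present")
  }
  invisible(data)
}

#' Rank features by max-relevance-max-distance
#'
#' Scores every feature column by `relevance_weight * relevance +
#' distance_weight * distance`, where relevance is the absolute Pearson
#' correlation between the feature and the 0/1 class label (0 for constant
#' features) and distance is the mean Euclidean distance between the
#' standardized feature column and all other columns, rescaled to
#' `[0, 1]`. Features are ranked by the combined score, descending, ties
#' broken by original column position.
#'
#' @param data Labelled feature table (`sample_id`, `label`, features).
#' @param relevance_weight,distance_weight Non-negative weights of the two
#'   components (both default 1).
#' @return An `mrmd_ranking` tibble with columns `feature`, `relevance`,
#'   `distance`, `combined`, `rank`, ordered by rank.
#' @export
mrmd_rank <- function(data, relevance_weight = 1, distance_weight = 1) {
  assert_labeled(data)
  if (nrow(data) < 2) abort("at least 2 samples are required")
  m <- feature_matrix(data)
  y <- as.numeric(data$label > 0)
  rel <- apply(m, 2, function(x) {
    if (sd(x) == 0) 0 else abs(cor(x, y))
  })
  z <- std_columns(m)
  d <- as.matrix(stats::dist(t(z)))
  dist_raw <- rowSums(d) / (ncol(m) - 1)
  if (ncol(m) == 1) dist_raw <- 0
  rng <- range(dist_raw)
  dist01 <- if (diff(rng) > 0) (dist_raw - rng[1]) / diff(rng) else
    rep(0, length(dist_raw))
  combined <- relevance_weight * rel + distance_weight * dist01
  ord <- order(-combined, seq_along(combined))
  out <- tibble(feature = colnames(m)[ord],
                relevance = unname(rel[ord]),
                distance = unname(dist01[ord]),
                combined = unname(combined[ord]),
                rank = seq_along(ord))
  class(out) <- c("mrmd_ranking", class(out))
  out
}

#' Select the top MRMD-ranked features
#'
#' Keeps the `m` highest-ranked features. With `m = "auto"` the number is
#' chosen by sweeping a geometric grid (1, 2, 5, 10, 20, 50, 100, 200,
#' all, clipped to the feature count) and keeping the smallest `m` that
#' maximises `folds`-fold cross-validated accuracy of the configured
#' classifier; ties go to the smaller m.
#'
#' @param data Labelled feature table.
#' @param ranking An [mrmd_rank()] result; computed from `data` if `NULL`.
#' @param m Number of features to keep, or `"auto"`.
#' @param classifier,folds,seed Internal cross-validation settings used
#'   only for `m = "auto"`.
#' @param ... Passed on to [train_classifier()] during the auto sweep.
#' @return The feature table restricted to the selected features, columns
#'   ordered by rank; the chosen size is in `attr(, "mrmd_m")` and the
#'   sweep table (for auto) in `attr(, "mrmd_sweep")`.
#' @export
mrmd_select <- function(data, ranking = NULL, m = "auto",
                        classifier = "svm", folds = 5, seed = 1, ...) {
  assert_labeled(data)
  ranking <- ranking %||% mrmd_rank(data)
  p <- length(feature_names(data))
  keep_cols <- function(mm) {
    data[, c("sample_id", "label", ranking$feature[seq_len(mm)])]
  }
  sweep_tbl <- NULL
  if (identical(m, "auto")) {
    grid <- unique(pmin(c(1, 2, 5, 10, 20, 50, 100, 200, p), p))
    accs <- vapply(grid, function(mm) {
      k_fold_cv(keep_cols(mm), k = folds, classifier = classifier,
                seed = seed, ...)$mean_accuracy
    }, numeric(1))
    sweep_tbl <- tibble(m = grid, cv_accuracy = accs)
    m <- grid[which.max(accs)]  # which.max takes the first (smallest) tie
  }
  if (!is.numeric(m) || m < 1 || m > p) {
    abort(sprintf("m must be in 1..%d or 'auto'", p))
  }
  out <- keep_cols(as.integer(m))
  attr(out, "mrmd_m") <- as.integer(m)
  attr(out, "mrmd_sweep") <- sweep_tbl
  out
}
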