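# Readers and writers for the external formats the pipeline consumes:
# multi-record FASTA, PSI-BLAST ASCII PSSM profiles, PSI-PRED .ss2
# secondary-structure profiles, and CSV / LIBSVM feature tables.

#' Sanitize protein residues to the 20-letter alphabet
#'
#' Upper-cases the sequence, strips whitespace and digits, and resolves
#' non-standard residue codes (B, J, O, U, X, Z and anything else outside
#' the standard alphabet) according to `policy`:
#'
#' * `"drop"` (default): non-standard residues are removed.
#' * `"map"`: ambiguity codes with a natural nearest standard residue are
#'   substituted (B to D, Z to E, U to C); the rest are dropped.
#'
#' @param x Character vector of raw residue strings.
#' @param policy `"drop"` or `"map"`.
#' @return Character vector of cleaned residue strings over the standard
#'   alphabet `ACDEFGHIKLMNPQRSTVWY`.
#' @export
#' @examples
#' sanitize_residues("ac de")          # "ACDE"
#' sanitize_residues("ACXE")           # "ACE"
#' sanitize_residues("ABZ", "map")     # "ADE"
sanitize_residues <- function(x, policy = c("drop", "map")) {
  policy <- match.arg(policy)
  x <- toupper(gsub("[[:space:][:digit:]*-]", "", x))
  if (policy == "map") {
    x <- chartr("BZU", "DEC", x)
  }
  vapply(strsplit(x, ""), function(ch) {
    paste0(ch[ch %in% AA20], collapse = "")
  }, character(1))
}

#' Read protein sequences from a FASTA file
#'
#' Parses a multi-record FASTA file into a tibble of protein sequences,
#' sanitizing residues to the 20-letter alphabet. The first whitespace-
#' delimited token of each header is used as the sequence identifier.
#'
#' @param path Path to a FASTA file.
#' @param residue_policy How to treat non-standard residues; see
#'   [sanitize_residues()].
#' @return A tibble with columns `sample_id` and `residues`, one row per
#'   record in file order.
#' @export
read_fasta <- function(path, residue_policy = c("drop", "map")) {
  residue_policy <- match.arg(residue_policy)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  res <- sanitize_residues(as.character(set), policy = residue_policy)
  empty <- !nzchar(res)
  if (any(empty)) {
    abort(paste0("FASTA record with empty sequence after sanitization: ",
                 paste(ids[empty], collapse = ", ")))
  }
  tibble(sample_id = unname(ids), residues = unname(res))
}

#' Construct a PSSM profile object
#'
#' A PSSM profile holds the L x 20 position-specific score matrix produced
#' by an iterative profile search (PSI-BLAST), aligned to a residue string.
#' Columns are stored in the canonical alphabetical amino-acid order.
#'
#' @param sequence_id Identifier of the underlying sequence.
#' @param residues L-character residue string.
#' @param scores L x 20 numeric matrix; column names must be a permutation
#'   of the 20 standard amino acids (columns are reordered canonically).
#' @return An object of class `pssm_profile`.
#' @export
pssm_profile <- function(sequence_id, residues, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20) {
    abort("PSSM score matrix must have exactly 20 columns")
  }
  if (is.null(colnames(scores)) || !setequal(colnames(scores), AA20)) {
    abort("PSSM score columns must be named by the 20 standard amino acids")
  }
  scores <- scores[, AA20, drop = FALSE]
  if (nrow(scores) != nchar(residues)) {
    abort(sprintf(
      "PSSM row count (%d) does not match sequence length (%d) for '%s'",
      nrow(scores), nchar(residues), sequence_id))
  }
  if (!all(is.finite(scores))) {
    abort("PSSM scores must be finite")
  }
  structure(
    list(sequence_id = sequence_id, residues = residues, scores = scores),
    class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile '%s': %d positions x 20 amino acids>\n",
              x$sequence_id, nrow(x$scores)))
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the first (log-odds) 20-column block of a PSI-BLAST
#' `-out_ascii_pssm` file. The amino-acid column order is taken from the
#' header line and remapped to the canonical alphabetical order; the
#' percentage block and trailing statistics are ignored.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence_id Identifier to attach; defaults to the file name
#'   without extension.
#' @return A [pssm_profile()] object.
#' @export
read_pssm <- function(path, sequence_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("PSSM file not found: ", path))
  }
  sequence_id <- sequence_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  toks <- lapply(strsplit(trimws(lines), "\\s+"), function(t) t[nzchar(t)])

  header_at <- which(vapply(toks, function(t) {
    length(t) >= 20 && all(t %in% AA20) && setequal(t[1:20], AA20)
  }, logical(1)))
  if (length(header_at) == 0) {
    abort(paste0("no amino-acid header line found in PSSM file: ", path))
  }
  col_order <- toks[[header_at[1]]][1:20]

  rows <- list()
  residues <- character()
  for (i in seq(header_at[1] + 1, length(toks))) {
    t <- toks[[i]]
    if (length(t) == 0) break
    if (is.na(suppressWarnings(as.integer(t[1])))) break
    if (length(t) < 22) {
      abort(sprintf("truncated PSSM row at line %d of %s", i, path))
    }
    vals <- suppressWarnings(as.numeric(t[3:22]))
    if (anyNA(vals)) {
      abort(sprintf("non-numeric PSSM scores at line %d of %s", i, path))
    }
    residues <- c(residues, t[2])
    rows[[length(rows) + 1]] <- vals
  }
  if (length(rows) == 0) {
    abort(paste0("no score rows found in PSSM file: ", path))
  }
  scores <- do.call(rbind, rows)
  colnames(scores) <- col_order
  pssm_profile(sequence_id, paste0(residues, collapse = ""), scores)
}

#' Construct a secondary-structure profile object
#'
#' Holds a per-residue three-state secondary-structure assignment (H =
#' helix, E = strand, C = coil) together with the L x 3 state-probability
#' matrix, columns ordered (C, H, E) as in the PSI-PRED .ss2 format.
#'
#' @param sequence_id Identifier of the underlying sequence.
#' @param states L-character string over `{H, E, C}`.
#' @param probabilities L x 3 numeric matrix with columns C, H, E; each
#'   entry in `[0, 1]` and each row summing to 1 within 0.05 (predictor
#'   outputs are rounded).
#' @return An object of class `ss2_profile`.
#' @export
ss2_profile <- function(sequence_id, states, probabilities) {
  probabilities <- as.matrix(probabilities)
  if (ncol(probabilities) != 3) {
    abort("secondary-structure probability matrix must have 3 columns")
  }
  colnames(probabilities) <- SS3
  st <- strsplit(states, "")[[1]]
  if (!all(st %in% SS3)) {
    abort(paste0("unknown secondary-structure state letter(s): ",
                 paste(unique(st[!st %in% SS3]), collapse = ", ")))
  }
  if (length(st) != nrow(probabilities)) {
    abort("states length must equal probability row count")
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    abort("secondary-structure probabilities must lie in [0, 1]")
  }
  if (any(abs(rowSums(probabilities) - 1) > 0.05)) {
    abort("secondary-structure probability rows must sum to 1 (within 0.05)")
  }
  structure(
    list(sequence_id = sequence_id, states = states,
         probabilities = probabilities),
    class = "ss2_profile")
}

#' @export
print.ss2_profile <- function(x, ...) {
  cat(sprintf("<ss2_profile '%s': %d positions, states H/E/C>\n",
              x$sequence_id, nchar(x$states)))
  invisible(x)
}

#' Read a PSI-PRED .ss2 secondary-structure file
#'
#' Parses the PSI-PRED VFORMAT: a comment line, then one row per residue
#' with position index, residue, predicted state and the three state
#' probabilities in (C, H, E) order.
#'
#' @param path Path to the .ss2 file.
#' @param sequence_id Identifier to attach; defaults to the file name
#'   without extension.
#' @return An [ss2_profile()] object.
#' @export
read_ss2 <- function(path, sequence_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0(".ss2 file not found: ", path))
  }
  sequence_id <- sequence_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("no residue rows found in .ss2 file: ", path))
  }
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(toks) < 6)
  if (length(bad) > 0) {
    abort(sprintf("malformed .ss2 row (expected 6 fields): %s line %d",
                  path, bad[1]))
  }
  states <- vapply(toks, `[`, character(1), 3)
  probs <- t(vapply(toks, function(t) {
    v <- suppressWarnings(as.numeric(t[4:6]))
    if (anyNA(v)) abort(paste0("non-numeric probability in .ss2 file: ", path))
    v
  }, numeric(3)))
  ss2_profile(sequence_id, paste0(states, collapse = ""), probs)
}

# -- feature tables ----------------------------------------------------------

# A feature table is a tibble whose first column is `sample_id`, optionally
# followed by a `label` column (1 = binding, 0 = non-binding), and whose
# remaining columns are numeric, uniquely named, block-prefixed features.

feature_names <- function(fm) {
  setdiff(names(fm), c("sample_id", "label"))
}

feature_matrix <- function(fm) {
  m <- as.matrix(fm[, feature_names(fm), drop = FALSE])
  rownames(m) <- fm$sample_id
  storage.mode(m) <- "double"
  m
}

assert_feature_table <- function(fm) {
  if (!is.data.frame(fm) || !"sample_id" %in% names(fm)) {
    abort("feature table must be a data frame with a 'sample_id' column")
  }
  fn <- feature_names(fm)
  if (anyDuplicated(fn)) {
    abort(paste0("duplicate feature names: ",
                 paste(unique(fn[duplicated(fn)]), collapse = ", ")))
  }
  m <- feature_matrix(fm)
  if (length(m) > 0 && !all(is.finite(m))) {
    abort("feature values must be finite")
  }
  invisible(fm)
}

#' Write a feature table to disk
#'
#' @param fm Feature table: a tibble with `sample_id`, optionally `label`,
#'   and numeric feature columns.
#' @param path Output file path.
#' @param format `"csv"` (header row of feature names) or `"libsvm"`
#'   (labels written as +1/-1, dense 1-based `index:value` pairs).
#' @return `fm`, invisibly.
#' @export
write_feature_table <- function(fm, path, format = c("csv", "libsvm")) {
  format <- match.arg(format)
  assert_feature_table(fm)
  if (format == "csv") {
    readr::write_csv(fm, path)
  } else {
    m <- feature_matrix(fm)
    lab <- if ("label" %in% names(fm)) ifelse(fm$label > 0, 1L, -1L) else
      rep(1L, nrow(fm))
    lines <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(sprintf("%+d", lab[i]),
              sprintf("%d:%.12g", seq_len(ncol(m)), m[i, ])),
            collapse = " ")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(fm)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Input file path.
#' @param format `"csv"` or `"libsvm"`.
#' @return A feature-table tibble. LIBSVM input yields features named
#'   `f1 ... fp` and a 0/1 `label` column (feature names are not stored in
#'   that format).
#' @export
read_feature_table <- function(path, format = c("csv", "libsvm")) {
  format <- match.arg(format)
  if (format == "csv") {
    fm <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    assert_feature_table(fm)
    return(fm)
  }
  toks <- strsplit(trimws(readLines(path)), "\\s+")
  labs <- vapply(toks, function(t) as.integer(t[1]), integer(1))
  vals <- lapply(toks, function(t) {
    kv <- do.call(rbind, strsplit(t[-1], ":", fixed = TRUE))
    setNames(as.numeric(kv[, 2]), as.integer(kv[, 1]))
  })
  p <- max(vapply(vals, function(v) max(as.integer(names(v))), integer(1)))
  m <- matrix(0, nrow = length(vals), ncol = p)
  for (i in seq_along(vals)) {
    m[i, as.integer(names(vals[[i]]))] <- vals[[i]]
  }
  colnames(m) <- paste0("f", seq_len(p))
  out <- as_tibble(m)
  out <- dplyr::bind_cols(
    tibble(sample_id = paste0("s", seq_len(nrow(m))),
           label = as.integer(labs > 0)),
    out)
  out
}
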