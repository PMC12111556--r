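#' Three-component z-scale descriptors of the 20 standard amino acids
#'
#' The classical principal-property z-scales (z1 ~ hydrophilicity,
#' z2 ~ steric bulk, z3 ~ polarity/electronic effects) used to embed
#' residues before the auto/cross-covariance transform.
#'
#' @format numeric matrix, 20 rows (one-letter residue codes) x 3 columns
#'   (`z1`, `z2`, `z3`).
#' @export
zscales <- local({
  m <- matrix(c(
    0.24, -2.32,  0.60,   # A
    3.52,  2.50, -3.50,   # R
    3.05,  1.62,  1.04,   # N
    3.98,  0.93,  1.93,   # D
    0.84, -1.67,  3.71,   # C
    1.75,  0.50, -1.44,   # Q
    3.11,  0.26, -0.11,   # E
    2.05, -4.06,  0.36,   # G
    2.47,  1.95,  0.26,   # H
   -3.89, -1.73, -1.71,   # I
   -4.28, -1.30, -1.49,   # L
    2.29,  0.89, -2.49,   # K
   -2.85, -0.22,  0.47,   # M
   -4.22,  1.94,  1.06,   # F
   -1.66,  0.27,  1.84,   # P
    2.39, -1.07,  1.15,   # S
    0.75, -2.18, -1.12,   # T
   -4.36,  3.94,  0.59,   # W
   -2.54,  2.44,  0.43,   # Y
   -2.59, -2.64, -1.54),  # V
    ncol = 3, byrow = TRUE,
    dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                    c("z1", "z2", "z3")))
  m
})

zscale_version <- "zscale-3d-v1"

#' Read protein records from a FASTA file
#'
#' Headers are parsed to the first whitespace; multi-line sequences are
#' joined. Records are validated against the 20-residue alphabet:
#' ambiguous `X` residues are rejected or stripped per `on_x`, any other
#' non-standard residue is an error naming the record and position.
#'
#' @param path FASTA file.
#' @param on_x `"reject"` (default) or `"strip"` for ambiguous X residues.
#' @return tibble with `id` and `sequence`.
#' @export
read_fasta <- function(path, on_x = c("reject", "strip")) {
  on_x <- match.arg(on_x)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop_input("read_fasta: no records in %s", path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop_input("read_fasta: duplicate record id '%s'",
               ids[duplicated(ids)][1])
  seqs <- unname(toupper(as.character(aa)))
  if (on_x == "strip") {
    stripped <- grepl("X", seqs, fixed = TRUE)
    if (any(stripped))
      message("stripped X residues from ", sum(stripped), " record(s)")
    seqs <- gsub("X", "", seqs, fixed = TRUE)
  }
  ok <- paste(rownames(zscales), collapse = "")
  bad <- regexpr(sprintf("[^%s]", ok), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop_input("read_fasta: invalid residue '%s' in record '%s' at position %d",
               substr(seqs[i], bad[i], bad[i]), ids[i], bad[i])
  }
  tibble(id = ids, sequence = seqs)
}

#' Write protein records to a FASTA file
#' @param records tibble with `id` and `sequence`.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Auto/cross-covariance (ACC) transform of a protein sequence
#'
#' Each residue is embedded by its three z-scale descriptors; for each
#' descriptor pair (j, k) and each lag l in 1..`lag`, the component is
#' `sum_i (z_j(i) - zbar_j) (z_k(i + l) - zbar_k) / (n - l)` with the sum
#' over i = 1..n-l, `zbar` the per-sequence descriptor means when
#' `center = TRUE` (so a homopolymer maps to the zero vector).
#' Components are ordered lexicographically in (j, k, l).
#'
#' @param sequence a single protein sequence (20-residue alphabet).
#' @param lag maximal lag; the sequence must be longer than `lag`.
#' @param center subtract per-sequence descriptor means.
#' @param scales residue-by-descriptor numeric matrix (default [zscales]).
#' @return named numeric vector of length `ncol(scales)^2 * lag`.
#' @export
acc_transform <- function(sequence, lag = 8L, center = TRUE,
                          scales = zscales) {
  if (lag < 1) stop_input("acc_transform: lag must be >= 1")
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n <= lag)
    stop_input("acc_transform: sequence length %d must exceed lag %d", n, lag)
  if (!all(res %in% rownames(scales)))
    stop_input("acc_transform: invalid residue '%s'",
               setdiff(res, rownames(scales))[1])
  z <- scales[res, , drop = FALSE]
  if (center) z <- sweep(z, 2, colMeans(z), `-`)
  nd <- ncol(scales)
  out <- numeric(nd * nd * lag)
  nm <- character(length(out))
  pos <- 1L
  for (j in seq_len(nd)) {
    for (k in seq_len(nd)) {
      for (l in seq_len(lag)) {
        i <- seq_len(n - l)
        out[pos] <- sum(z[i, j] * z[i + l, k]) / (n - l)
        nm[pos] <- sprintf("%s_%s_lag%d", colnames(scales)[j],
                           colnames(scales)[k], l)
        pos <- pos + 1L
      }
    }
  }
  setNames(out, nm)
}

#' ACC feature matrix for a set of protein records
#'
#' @param records tibble with `id` and `sequence`.
#' @inheritParams acc_transform
#' @return numeric matrix, one row per record (rownames = ids).
#' @export
acc_features <- function(records, lag = 8L, center = TRUE, scales = zscales) {
  feats <- t(vapply(records$sequence, acc_transform,
                    numeric(ncol(scales)^2 * lag),
                    lag = lag, center = center, scales = scales,
                    USE.NAMES = FALSE))
  rownames(feats) <- records$id
  feats
}

#' Train a linear antigenicity head on ACC features
#'
#' Ridge-regularized logistic regression (via glmnet, alpha = 0, fixed
#' penalty) mapping ACC descriptors to the probability of the antigenic
#' class. Deterministic for fixed inputs.
#'
#' @param features numeric ACC feature matrix (rows = sequences).
#' @param labels logical/0-1 vector, `TRUE` = antigenic; both classes must
#'   be present.
#' @param lambda ridge penalty.
#' @param lag,scale_version metadata recorded in the head.
#' @return an `antigen_head` list: `weights`, `intercept`, `lag`,
#'   `scale_version`, `lambda`.
#' @export
train_head <- function(features, labels, lambda = 0.01, lag = 8L,
                       scale_version = zscale_version) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2)
    stop_input("train_head: both classes must be present")
  fit <- glmnet::glmnet(features, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  structure(list(weights = setNames(as.numeric(fit$beta),
                                    rownames(fit$beta)),
                 intercept = as.numeric(fit$a0),
                 lag = as.integer(lag), scale_version = scale_version,
                 lambda = lambda),
            class = "antigen_head")
}

#' Serialize / load a linear head as JSON
#' @param head an `antigen_head`.
#' @param path JSON file path.
#' @export
write_head_json <- function(head, path) {
  obj <- unclass(head)
  obj$weights <- as.list(obj$weights)  # keep feature names in the JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_head_json
#' @export
read_head_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$weights <- unlist(x$weights)
  structure(x, class = "antigen_head")
}

#' Score protein sequences for antigenicity
#'
#' Applies the head's logistic score to each record's ACC features and
#' thresholds it.
#'
#' @param records tibble with `id` and `sequence`.
#' @param head an `antigen_head` from [train_head()].
#' @param threshold score cutoff; `antigenic = score >= threshold`.
#' @return tibble `id`, `score`, `antigenic`.
#' @export
score_sequences <- function(records, head, threshold = 0.5) {
  feats <- acc_features(records, lag = head$lag)
  eta <- as.numeric(feats %*% head$weights) + head$intercept
  score <- 1 / (1 + exp(-eta))
  tibble(id = records$id, score = score, antigenic = score >= threshold)
}
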