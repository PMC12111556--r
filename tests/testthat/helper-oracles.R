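# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as plain loops over the definitions and
# share no code with the package internals.

# expressed-and-variable selection by direct per-gene loops
brute_overmean <- function(m, ref_var = c("mean_gene_var", "total_var")) {
  ref_var <- match.arg(ref_var)
  grand <- mean(as.vector(m))
  means <- numeric(nrow(m))
  vars <- numeric(nrow(m))
  for (g in seq_len(nrow(m))) {
    means[g] <- mean(m[g, ])
    vars[g] <- var(m[g, ])
  }
  rv <- if (ref_var == "mean_gene_var") mean(vars) else var(as.vector(m))
  rownames(m)[means > grand & vars > rv]
}

# step-up BH by explicit sort / multiply / right-to-left cummin
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * n / seq_len(n)
  for (i in rev(seq_len(n - 1)))
    adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# classical pooled-variance two-sample t per gene
brute_pooled_t <- function(m, grp) {
  t(vapply(seq_len(nrow(m)), function(g) {
    x <- m[g, grp == "BT"]; y <- m[g, grp == "BNT"]
    n1 <- length(x); n2 <- length(y)
    s2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    tt <- (mean(x) - mean(y)) / sqrt(s2 * (1 / n1 + 1 / n2))
    c(t = tt, p = 2 * pt(-abs(tt), n1 + n2 - 2))
  }, c(t = 0, p = 0)))
}

# ACC by the definition: explicit double loop over positions and lags
brute_acc <- function(sequence, lag, center = TRUE, scales = ctcmarkers::zscales) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  z <- scales[res, , drop = FALSE]
  if (center) for (j in seq_len(ncol(z))) z[, j] <- z[, j] - mean(z[, j])
  out <- c()
  for (j in seq_len(ncol(z))) for (k in seq_len(ncol(z))) for (l in seq_len(lag)) {
    s <- 0
    for (i in seq_len(n - l)) s <- s + z[i, j] * z[i + l, k]
    out <- c(out, s / (n - l))
  }
  out
}

# four-criterion atypicality by direct truth-table evaluation
brute_atypical <- function(cd45_intensity, cd45_homogeneous, diameter,
                           leuko_mean, nuclear_irregular, nc_ratio,
                           nc_min = 0.75) {
  c1 <- !(cd45_intensity == "intense" && cd45_homogeneous)
  c2 <- diameter > leuko_mean
  c3 <- nuclear_irregular
  c4 <- nc_ratio > nc_min
  c1 && c2 && c3 && c4
}

# CTC label by explicit enumeration over the panel stains
brute_ctc_label <- function(atypical, stains, panel_mode = "any",
                            positive_levels = c("low", "high")) {
  if (!atypical) return("leukocyte")
  pos <- vapply(stains, function(s) s %in% positive_levels, TRUE)
  hit <- if (panel_mode == "any") any(pos) else all(pos)
  if (hit) "CTC" else "potential_CTC"
}

# deterministic annotation fixture realizing the published in-silico-sort
# split: 26 both-database + 4 one-database membrane genes (30 kept), 11 of
# them immune-flagged (19 kept), 7 of those failing the IHC criterion
# (12 kept)
papercounts_annotation <- function() {
  genes <- sprintf("PC%02d", 1:50)
  membrane_db1 <- rep(FALSE, 50)
  membrane_db2 <- rep(FALSE, 50)
  membrane_db1[1:26] <- TRUE
  membrane_db2[1:26] <- TRUE
  membrane_db1[27:28] <- TRUE   # one-database genes: two per database
  membrane_db2[29:30] <- TRUE
  immune <- rep(FALSE, 50)
  immune[20:30] <- TRUE         # removes 11 of the 30 membrane genes
  ihc <- rep(list(rep("not_detected", 10)), 50)
  for (i in 1:12) ihc[[i]] <- rep(c("high", "medium"), 5)  # 12 survivors
  for (i in 13:19) ihc[[i]] <- c(rep("medium", 4), rep("low", 6))  # 40% < 50%
  tibble::tibble(gene_id = genes,
                 membrane_db1 = membrane_db1, membrane_db2 = membrane_db2,
                 immune_db1 = immune, immune_db2 = immune,
                 go_plasma_membrane = membrane_db1 | membrane_db2,
                 ihc_levels = ihc)
}

# cell populations realizing the printed spiked-cell staining table:
# per column, low/high counts are the printed percentages x100 out of
# 10000 cells (negatives take the remainder)
table2_fixture_cells <- function() {
  ref <- ctcmarkers::marker_positivity_reference
  fixtures <- list()
  for (i in seq_len(nrow(ref))) {
    n_low <- round(100 * ref$pct_low[i])
    n_high <- round(100 * ref$pct_high[i])
    n_neg <- 10000 - n_low - n_high
    fixtures[[ref$marker[i]]] <- tibble::tibble(
      cell_id = sprintf("%s_%05d", ref$marker[i], 1:10000),
      stain_M = rep(c("negative", "low", "high"), c(n_neg, n_low, n_high)))
  }
  fixtures
}
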