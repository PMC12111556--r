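#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjusted p-values: sort descending, multiply by n/rank, take the
#' running minimum from the smallest rank upward, clip at 1, and return in
#' the input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order and length as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop_input("bh_adjust: p-values must lie in [0, 1]")
  n <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * pvalues[o]))[ro]
  adj
}

# Newton solve of trigamma(y) = x (for the moment estimator of the prior df)
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

# moment estimation of (prior df d0, prior variance s0^2) from per-gene
# residual variances s2 on d df, via the distribution of log s2
estimate_prior <- function(s2, d) {
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  if (n < 2) return(list(d0 = 0, s0_2 = exp(emean)))
  evar <- mean((e - emean)^2) * n / (n - 1) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated two-group differential expression
#'
#' Per-gene two-group linear model on a log2-scale matrix: the effect is the
#' BT minus BNT mean difference; the residual variance (pooled within-group,
#' d = n - 2 df) is shrunk toward a prior by empirical Bayes,
#' `s2_post = (d0 s0^2 + d s2) / (d0 + d)`, with the prior `(d0, s0^2)`
#' estimated by the method of moments on `log s2`. The moderated t is the
#' mean difference over its shrunken standard error, with two-sided
#' p-values on `d0 + d` df (normal in the infinite-df limit), and BH-FDR
#' adjustment across genes.
#'
#' Genes with zero residual variance have `s2` replaced by the smallest
#' positive `s2` before moment estimation (keeping `log s2` finite); if no
#' gene has positive variance the function falls back to the ordinary t
#' with a warning.
#'
#' @param matrix an `expr_matrix` (platform `bulk_log`).
#' @param design tibble/data.frame with `sample_id` and `group` (`BT`/`BNT`)
#'   covering every matrix column exactly once; both groups need >= 2
#'   samples.
#' @param fdr_threshold FDR level used for the `upregulated` flag.
#' @param prior_df override of the prior df `d0`; `NULL` estimates it, `0`
#'   switches shrinkage off (ordinary pooled t).
#' @return tibble (one row per gene): `gene_id`, `log2fc`, `t_mod`,
#'   `df_total`, `p`, `fdr`, `upregulated`.
#' @export
moderated_t <- function(matrix, design, fdr_threshold = 0.05,
                        prior_df = NULL) {
  if (!setequal(design$sample_id, colnames(matrix)) ||
      anyDuplicated(design$sample_id))
    stop_input("design must cover every matrix sample exactly once")
  grp <- design$group[match(colnames(matrix), design$sample_id)]
  if (!all(grp %in% c("BT", "BNT")))
    stop_input("design groups must be BT or BNT")
  n1 <- sum(grp == "BT"); n2 <- sum(grp == "BNT")
  if (n1 < 2 || n2 < 2)
    stop_input("each group needs >= 2 samples for variance estimation")
  m <- unclass(matrix)
  m1 <- rowMeans(m[, grp == "BT", drop = FALSE])
  m2 <- rowMeans(m[, grp == "BNT", drop = FALSE])
  log2fc <- m1 - m2
  d <- n1 + n2 - 2
  ss1 <- rowSums((m[, grp == "BT", drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, grp == "BNT", drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / d
  s2_mom <- s2
  if (any(s2 == 0)) {
    if (all(s2 == 0)) {
      warning("all genes have zero residual variance; ",
              "falling back to the ordinary t")
      prior_df <- 0
    } else {
      s2_mom[s2 == 0] <- min(s2[s2 > 0])
      message(sum(s2 == 0),
              " gene(s) with zero residual variance floored for ",
              "prior estimation")
    }
  }
  if (is.null(prior_df)) {
    prior <- estimate_prior(s2_mom, d)
    d0 <- prior$d0; s0_2 <- prior$s0_2
  } else {
    d0 <- prior_df
    s0_2 <- if (d0 > 0) estimate_prior(s2_mom, d)$s0_2 else 0
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, log2fc / se, ifelse(log2fc == 0, 0, Inf * sign(log2fc)))
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t_mod)) else
    2 * pt(-abs(t_mod), df = df_total)
  fdr <- bh_adjust(p)
  tibble(gene_id = rownames(m), log2fc = unname(log2fc),
         t_mod = unname(t_mod), df_total = df_total, p = unname(p),
         fdr = unname(fdr),
         upregulated = unname(log2fc > 0 & fdr < fdr_threshold))
}

#' Select upregulated genes at an FDR threshold
#'
#' @param deg a DEG table from [moderated_t()].
#' @param fdr_threshold FDR cutoff (positive direction required).
#' @return character vector of upregulated gene ids.
#' @export
select_upregulated <- function(deg, fdr_threshold = 0.05) {
  deg$gene_id[deg$log2fc > 0 & deg$fdr < fdr_threshold]
}

#' Write a DEG table as TSV
#' @param deg tibble from [moderated_t()].
#' @param path file path.
#' @export
write_deg_tsv <- function(deg, path) {
  write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
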