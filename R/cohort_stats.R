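#' Printed marker-positivity reference table (spiked-cell experiments)
#'
#' Published positivity percentages for 20 MCF7 cells spiked into healthy
#' blood: per marker or cocktail, the percentage of evaluated cells scored
#' negative / low / high, and the positive row (low + high). Used as a
#' regression reference for the positivity arithmetic.
#'
#' @format tibble with columns `marker`, `pct_negative`, `pct_low`,
#'   `pct_high`, `pct_positive`.
#' @export
marker_positivity_reference <- tibble::tibble(
  marker = c("CK", "EpCAM", "CK+EpCAM", "SLC9A3R1", "MARCKSL1", "RHOD",
             "ScreenCell_cocktail"),
  pct_negative = c(34.40, 69.70, 30.80, 11.50, 40.00, 5.12, 0.00),
  pct_low      = c(16.40, 22.70, 25.00, 37.70, 13.30, 41.00, 1.90),
  pct_high     = c(49.20,  7.60, 44.20, 50.10, 46.60, 53.80, 98.10),
  pct_positive = c(65.60, 30.30, 69.20, 87.80, 59.90, 94.80, 100.00))

#' Published cohort staining efficiencies
#'
#' Patient-cohort mean percentages of atypical cells labeled by each panel
#' (reference values for the complement identities: percent unlabeled and
#' the cocktail's efficiency gain).
#'
#' @format named numeric vector (`conventional`, `cocktail`).
#' @export
cohort_staining_reference <- c(conventional = 65.82, cocktail = 99.59)

#' Percent of cells left unlabeled by a panel
#' @param pct_positive positivity percentage (0-100).
#' @return `100 - pct_positive`.
#' @export
pct_unlabeled <- function(pct_positive) 100 - pct_positive

#' Efficiency gap between two panels, percentage points
#' @param pct_a,pct_b positivity percentages (0-100).
#' @return `pct_a - pct_b`.
#' @export
efficiency_gap <- function(pct_a, pct_b) pct_a - pct_b

cocktail_category <- function(stains, panel_mode = "any") {
  # stains: character matrix cells x members; high > low > negative precedence
  if (panel_mode == "any") {
    ifelse(rowSums(stains == "high") > 0, "high",
           ifelse(rowSums(stains == "low") > 0, "low", "negative"))
  } else {
    npos <- rowSums(stains == "high" | stains == "low")
    ifelse(npos < ncol(stains), "negative",
           ifelse(rowSums(stains == "high") == ncol(stains), "high", "low"))
  }
}

#' Marker / cocktail positivity table
#'
#' For each requested single marker, the percentage of evaluated cells
#' scoring negative / low / high; for each cocktail, a cell's category is
#' high if any member is high, else low if any member is low, else
#' negative (precedence high > low > negative, `panel_mode = "any"`).
#' `pct_positive = pct_low + pct_high` by construction, and the three
#' category percentages sum to 100.
#'
#' @param cells cell-record tibble with `stain_<marker>` columns; every
#'   evaluated cell must carry non-NA stains for the requested markers.
#' @param markers character vector of single markers to tabulate.
#' @param cocktails named list of marker vectors.
#' @param panel_mode cocktail aggregation rule, `"any"` or `"all"`.
#' @return tibble `marker`, `n_cells`, `pct_negative`, `pct_low`,
#'   `pct_high`, `pct_positive`.
#' @export
positivity_table <- function(cells, markers = character(),
                             cocktails = list(), panel_mode = "any") {
  if (nrow(cells) == 0) stop_input("positivity_table: empty cell set")
  one <- function(name, member_markers) {
    cols <- paste0("stain_", member_markers)
    missing_col <- setdiff(cols, names(cells))
    if (length(missing_col) > 0)
      stop_input("positivity_table: no stains for marker '%s'",
                 sub("^stain_", "", missing_col[1]))
    stains <- as.matrix(cells[, cols, drop = FALSE])
    if (any(is.na(stains)))
      stop_input("positivity_table: NA stain for '%s' (cell '%s')", name,
                 cells$cell_id[which(rowSums(is.na(stains)) > 0)[1]])
    cat_ <- cocktail_category(stains, panel_mode)
    n <- length(cat_)
    pl <- 100 * sum(cat_ == "low") / n
    ph <- 100 * sum(cat_ == "high") / n
    tibble(marker = name, n_cells = n,
           pct_negative = 100 * sum(cat_ == "negative") / n,
           pct_low = pl, pct_high = ph, pct_positive = pl + ph)
  }
  rows <- c(lapply(markers, function(m) one(m, m)),
            lapply(names(cocktails), function(nm) one(nm, cocktails[[nm]])))
  bind_rows(rows)
}

#' Per-cohort summaries of AC/CTC counts and staining percentages
#'
#' Per cohort and panel: mean, SEM (sd / sqrt(n)), median and n of the
#' per-subject atypical-cell counts, CTC counts and percent-stained values.
#' Subjects with zero atypical cells are excluded from the percent-stained
#' aggregation (their percentage is undefined) and counted in
#' `n_excluded_pct`. With a single subject the SEM is reported as 0 and
#' flagged.
#'
#' @param subjects per-subject tibble from [call_cohort()] (`subject_id`,
#'   `cohort`, `panel`, `n_ac`, `n_ctc`, `pct_stained`).
#' @return tibble, one row per cohort x panel x statistic.
#' @export
cohort_summary <- function(subjects) {
  groups <- split(subjects, interaction(subjects$cohort, subjects$panel,
                                        drop = TRUE))
  rows <- lapply(groups, function(g) {
    mk <- function(quantity, x) {
      x2 <- x[!is.na(x)]
      n <- length(x2)
      tibble(cohort = g$cohort[1], panel = g$panel[1], quantity = quantity,
             mean = if (n > 0) mean(x2) else NA_real_,
             sem = if (n > 1) sd(x2) / sqrt(n) else 0,
             sem_degenerate = n <= 1,
             median = if (n > 0) median(x2) else NA_real_,
             n = n, n_excluded = length(x) - n)
    }
    bind_rows(mk("n_ac", g$n_ac), mk("n_ctc", g$n_ctc),
              mk("pct_stained", g$pct_stained))
  })
  out <- bind_rows(rows)
  excl <- out$quantity == "pct_stained" & out$n_excluded > 0
  if (any(excl))
    message(sum(out$n_excluded[excl]), " subject(s) with zero atypical ",
            "cells excluded from percent-stained averaging")
  out
}

t_result <- function(statistic, df, p, paired, degenerate = FALSE) {
  structure(list(statistic = statistic, df = df, p = p, paired = paired,
                 degenerate = degenerate), class = "t_result")
}

#' @export
print.t_result <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4f, df = %s, p = %.4g%s\n",
              if (x$paired) "paired" else "unpaired (pooled)",
              x$statistic, format(x$df), x$p,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Paired Student t-test
#'
#' Classical paired t on the differences, two-sided. Zero variance of the
#' differences is degenerate: p = 1 when the mean difference is 0,
#' otherwise the 0-limit is reported with a flag.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return a `t_result` (`statistic`, `df`, `p`, `paired`, `degenerate`).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop_input("paired_t: unequal lengths")
  if (length(x) < 2) stop_input("paired_t: need >= 2 pairs")
  d <- x - y
  n <- length(d)
  sdd <- sd(d)
  if (sdd == 0) {
    return(t_result(if (mean(d) == 0) 0 else Inf * sign(mean(d)), n - 1,
                    if (mean(d) == 0) 1 else 0, TRUE, degenerate = TRUE))
  }
  t <- mean(d) / (sdd / sqrt(n))
  t_result(t, n - 1, 2 * pt(-abs(t), n - 1), TRUE)
}

#' Unpaired Student t-test (pooled variance)
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return a `t_result`.
#' @export
unpaired_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop_input("unpaired_t: need >= 2 per group")
  s2p <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  dm <- mean(x) - mean(y)
  if (s2p == 0) {
    return(t_result(if (dm == 0) 0 else Inf * sign(dm), n1 + n2 - 2,
                    if (dm == 0) 1 else 0, FALSE, degenerate = TRUE))
  }
  t <- dm / sqrt(s2p * (1 / n1 + 1 / n2))
  t_result(t, n1 + n2 - 2, 2 * pt(-abs(t), n1 + n2 - 2), FALSE)
}
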