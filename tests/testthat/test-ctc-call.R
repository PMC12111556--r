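make_cell <- function(cell_id = "c1", diameter = 15, nc_ratio = 0.9,
                      nuclear_irregular = TRUE, cd45_intensity = "negative",
                      cd45_homogeneous = FALSE,
                      stain_MARCKSL1 = "negative",
                      stain_SLC9A3R1 = "negative",
                      stain_RHOD = "negative") {
  tibble::tibble(cell_id = cell_id, diameter = diameter, nc_ratio = nc_ratio,
                 nuclear_irregular = nuclear_irregular,
                 cd45_intensity = cd45_intensity,
                 cd45_homogeneous = cd45_homogeneous,
                 stain_MARCKSL1 = stain_MARCKSL1,
                 stain_SLC9A3R1 = stain_SLC9A3R1, stain_RHOD = stain_RHOD)
}

test_that("leukocyte mean diameter and its fallback", {
  cells <- tibble::tibble(cell_id = c("a", "b"), diameter = c(10, 14),
                          cd45_intensity = "intense", cd45_homogeneous = TRUE)
  expect_equal(leukocyte_mean_diameter(cells), 12)
  expect_equal(leukocyte_mean_diameter(cells[1, ]), 10)

  no_leuko <- make_cell()
  expect_message(d <- leukocyte_mean_diameter(no_leuko), "fallback")
  expect_equal(d, 12)
})

test_that("CD45-intense homogeneous cells are never atypical, and the N/C
           threshold is strict", {
  leuko_like <- make_cell(cd45_intensity = "intense", cd45_homogeneous = TRUE,
                          diameter = 30, nc_ratio = 0.99)
  expect_false(call_atypical(leuko_like, leuko_mean = 12)$atypical)

  border <- make_cell(nc_ratio = 0.75)
  expect_false(call_atypical(border, leuko_mean = 12)$atypical)
  above <- make_cell(nc_ratio = 0.7500001)
  expect_true(call_atypical(above, leuko_mean = 12)$atypical)

  at_mean <- make_cell(diameter = 12)
  expect_false(call_atypical(at_mean, leuko_mean = 12)$atypical)
})

test_that("atypicality matches the exhaustive 32-case truth table", {
  grid <- expand.grid(cd45_intensity = c("intense", "weak"),
                      cd45_homogeneous = c(TRUE, FALSE),
                      diameter = c(11, 13), nuclear_irregular = c(TRUE, FALSE),
                      nc_ratio = c(0.7, 0.8), stringsAsFactors = FALSE)
  cells <- tibble::as_tibble(grid)
  cells$cell_id <- sprintf("c%02d", seq_len(nrow(cells)))
  calls <- call_atypical(cells, leuko_mean = 12)
  want <- vapply(seq_len(nrow(cells)), function(i)
    brute_atypical(cells$cd45_intensity[i], cells$cd45_homogeneous[i],
                   cells$diameter[i], 12, cells$nuclear_irregular[i],
                   cells$nc_ratio[i]), TRUE)
  expect_identical(calls$atypical, want)
  # reasons cover all four criteria for every cell
  expect_true(all(grepl("cd45=.*size=.*nucleus=.*nc_ratio=", calls$reasons)))
})

test_that("making any criterion more atypical never flips a call to FALSE", {
  set.seed(12)
  for (i in 1:50) {
    cell <- make_cell(diameter = runif(1, 8, 20), nc_ratio = runif(1, 0.5, 1),
                      nuclear_irregular = runif(1) < 0.5,
                      cd45_intensity = sample(c("negative", "weak",
                                                "intense"), 1),
                      cd45_homogeneous = runif(1) < 0.5)
    base <- call_atypical(cell, leuko_mean = 12)$atypical
    bigger <- cell; bigger$diameter <- cell$diameter + 5
    higher <- cell; higher$nc_ratio <- min(1, cell$nc_ratio + 0.1)
    weaker <- cell; weaker$cd45_intensity <- "negative"
    weaker$cd45_homogeneous <- FALSE
    for (v in list(bigger, higher, weaker))
      if (base) expect_true(call_atypical(v, leuko_mean = 12)$atypical)
  }
})

test_that("CTC labeling follows the any-positive panel rule", {
  rules <- ctc_rules()
  none <- make_cell()
  calls <- call_atypical(none, rules, 12)
  expect_identical(call_ctc(none, calls, rules)$label, "potential_CTC")

  one_low <- make_cell(stain_RHOD = "low")
  calls1 <- call_atypical(one_low, rules, 12)
  expect_identical(call_ctc(one_low, calls1, rules)$label, "CTC")

  leuko <- make_cell(cd45_intensity = "intense", cd45_homogeneous = TRUE)
  calls2 <- call_atypical(leuko, rules, 12)
  expect_identical(call_ctc(leuko, calls2, rules)$label, "leukocyte")
})

test_that("random staining maps match the enumeration oracle in both modes", {
  set.seed(21)
  levs <- c("negative", "low", "high")
  cells <- tibble::as_tibble(expand.grid(stain_MARCKSL1 = levs,
                                         stain_SLC9A3R1 = levs,
                                         stain_RHOD = levs,
                                         stringsAsFactors = FALSE))
  cells$cell_id <- sprintf("c%02d", seq_len(nrow(cells)))
  cells$diameter <- 15; cells$nc_ratio <- 0.9
  cells$nuclear_irregular <- TRUE
  cells$cd45_intensity <- "negative"; cells$cd45_homogeneous <- FALSE
  for (mode in c("any", "all")) {
    rules <- ctc_rules(panel_mode = mode)
    calls <- call_ctc(cells, call_atypical(cells, rules, 12), rules)
    want <- vapply(seq_len(nrow(cells)), function(i)
      brute_ctc_label(TRUE, c(cells$stain_MARCKSL1[i],
                              cells$stain_SLC9A3R1[i], cells$stain_RHOD[i]),
                      panel_mode = mode), "")
    expect_identical(calls$label, want)
  }
})

test_that("panel growth never decreases the CTC count; missing markers error", {
  set.seed(22)
  cells <- make_cell(cell_id = sprintf("c%02d", 1:30),
                     stain_MARCKSL1 = sample(c("negative", "low", "high"),
                                             30, TRUE),
                     stain_SLC9A3R1 = sample(c("negative", "low", "high"),
                                             30, TRUE),
                     stain_RHOD = sample(c("negative", "low", "high"),
                                         30, TRUE))
  n_ctc <- function(panel) {
    r <- ctc_rules(panel = panel)
    sum(call_ctc(cells, call_atypical(cells, r, 12), r)$label == "CTC")
  }
  expect_lte(n_ctc("MARCKSL1"), n_ctc(c("MARCKSL1", "SLC9A3R1")))
  expect_lte(n_ctc(c("MARCKSL1", "SLC9A3R1")),
             n_ctc(c("MARCKSL1", "SLC9A3R1", "RHOD")))

  r_bad <- ctc_rules(panel = c("MARCKSL1", "EpCAM"))
  expect_error(call_ctc(cells, call_atypical(cells, r_bad, 12), r_bad),
               "'EpCAM' missing")

  na_cells <- cells
  na_cells$stain_RHOD[3] <- NA
  r3 <- ctc_rules()
  expect_error(call_ctc(na_cells, call_atypical(na_cells, r3, 12), r3),
               "lacks a stain for marker 'RHOD'")
})

test_that("cohort calling counts agree with a direct recount", {
  cfg <- cohort_sim_config(n_patients = 5, n_donors = 3,
                           patient_ac_mean = 10, leukocytes_per_support = 20)
  cells <- simulate_cohort_cells(cfg, seed = 14)
  res <- call_cohort(cells)

  # generator-truth recount: planted ACs are the nuclear_irregular cells
  truth_ac <- c(tapply(cells$nuclear_irregular, cells$support_id, sum))
  got_ac <- setNames(as.numeric(res$supports$n_ac), res$supports$support_id)
  expect_equal(got_ac[names(truth_ac)], truth_ac)

  # donor supports with no planted ACs yield zero calls
  cfg0 <- cohort_sim_config(n_patients = 2, n_donors = 4, donor_ac_mean = 0)
  res0 <- call_cohort(simulate_cohort_cells(cfg0, seed = 2))
  expect_true(all(res0$subjects$n_ac[res0$subjects$cohort == "donor"] == 0))
})
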