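#' Decision rules for atypical-cell and CTC calling
#'
#' The four atypicality criteria: (1) no intense AND homogeneous CD45
#' staining, (2) diameter strictly greater than the mean leukocyte diameter
#' on the same isolation support, (3) irregular nuclear outline, and
#' (4) nuclear/cytoplasmic ratio strictly greater than `nc_ratio_min`
#' (default 0.75). Atypical cells positive (low or high) for any panel
#' marker are CTCs; the rest are potential CTCs.
#'
#' @param nc_ratio_min N/C ratio threshold in (0, 1); strict inequality.
#' @param panel ordered character vector of marker names.
#' @param positive_levels staining levels counted as positive.
#' @param panel_mode `"any"` (default: one positive member suffices) or
#'   `"all"`.
#' @param fallback_leuko_diameter mean leukocyte diameter (micrometers)
#'   assumed when a support carries no leukocyte.
#' @return a validated `ctc_rules` list.
#' @export
ctc_rules <- function(nc_ratio_min = 0.75,
                      panel = c("MARCKSL1", "SLC9A3R1", "RHOD"),
                      positive_levels = c("low", "high"),
                      panel_mode = c("any", "all"),
                      fallback_leuko_diameter = 12) {
  if (nc_ratio_min <= 0 || nc_ratio_min >= 1)
    stop_config("nc_ratio_min", "must lie in (0, 1)")
  if (length(panel) == 0) stop_config("panel", "must list >= 1 marker")
  structure(list(nc_ratio_min = nc_ratio_min, panel = panel,
                 positive_levels = positive_levels,
                 panel_mode = match.arg(panel_mode),
                 fallback_leuko_diameter = fallback_leuko_diameter),
            class = "ctc_rules")
}

is_leukocyte_morphology <- function(cells) {
  cells$cd45_intensity == "intense" & cells$cd45_homogeneous
}

#' Mean leukocyte diameter on one isolation support
#'
#' Arithmetic mean diameter of the CD45 intense-and-homogeneous cells; if
#' the support carries none, falls back to the configured constant with a
#' message.
#'
#' @param cells cell records of one support.
#' @param rules a [ctc_rules()].
#' @return mean diameter in micrometers.
#' @export
leukocyte_mean_diameter <- function(cells, rules = ctc_rules()) {
  leuko <- is_leukocyte_morphology(cells)
  if (!any(leuko)) {
    message("no leukocyte on support; using fallback diameter ",
            rules$fallback_leuko_diameter, " um")
    return(rules$fallback_leuko_diameter)
  }
  mean(cells$diameter[leuko])
}

#' Call atypical cells against the four criteria
#'
#' @param cells cell-record tibble (one support's cells, or any subset to
#'   which `leuko_mean` applies).
#' @param rules a [ctc_rules()].
#' @param leuko_mean mean leukocyte diameter to compare sizes against.
#' @return tibble `cell_id`, `atypical`, the four per-criterion outcomes
#'   (`crit_cd45`, `crit_size`, `crit_nucleus`, `crit_nc_ratio`) and a
#'   semicolon-joined `reasons` string.
#' @export
call_atypical <- function(cells, rules = ctc_rules(), leuko_mean) {
  crit_cd45 <- !(cells$cd45_intensity == "intense" & cells$cd45_homogeneous)
  crit_size <- cells$diameter > leuko_mean
  crit_nucleus <- cells$nuclear_irregular
  crit_nc <- cells$nc_ratio > rules$nc_ratio_min
  atypical <- crit_cd45 & crit_size & crit_nucleus & crit_nc
  tibble(cell_id = cells$cell_id, atypical = atypical,
         crit_cd45 = crit_cd45, crit_size = crit_size,
         crit_nucleus = crit_nucleus, crit_nc_ratio = crit_nc,
         reasons = sprintf("cd45=%s;size=%s;nucleus=%s;nc_ratio=%s",
                           crit_cd45, crit_size, crit_nucleus, crit_nc))
}

#' Label atypical cells as CTC or potential CTC by panel staining
#'
#' Under `panel_mode = "any"` an atypical cell is a CTC if any panel marker
#' stains at a positive level (low or high); under `"all"`, if every panel
#' marker does. Non-atypical cells are labeled leukocyte.
#'
#' @param cells cell-record tibble with `stain_<marker>` columns covering
#'   the rules' panel (a missing or NA stain is an input error naming the
#'   cell and marker).
#' @param calls atypical calls from [call_atypical()] for the same cells.
#' @param rules a [ctc_rules()].
#' @return `calls` with a `label` column (`leukocyte`, `CTC`,
#'   `potential_CTC`).
#' @export
call_ctc <- function(cells, calls, rules = ctc_rules()) {
  cols <- paste0("stain_", rules$panel)
  missing_col <- setdiff(cols, names(cells))
  if (length(missing_col) > 0)
    stop_input("call_ctc: marker '%s' missing from cell records",
               sub("^stain_", "", missing_col[1]))
  stains <- as.matrix(cells[, cols, drop = FALSE])
  atyp <- calls$atypical
  if (any(atyp)) {
    na_cell <- which(atyp & rowSums(is.na(stains)) > 0)
    if (length(na_cell) > 0) {
      mk <- cols[which(is.na(stains[na_cell[1], ]))[1]]
      stop_input("call_ctc: cell '%s' lacks a stain for marker '%s'",
                 cells$cell_id[na_cell[1]], sub("^stain_", "", mk))
    }
  }
  pos <- matrix(stains %in% rules$positive_levels, nrow = nrow(stains))
  is_pos <- if (rules$panel_mode == "any") rowSums(pos) > 0
            else rowSums(pos) == ncol(pos)
  calls$label <- ifelse(!atyp, "leukocyte",
                        ifelse(is_pos, "CTC", "potential_CTC"))
  calls
}

#' Call a whole cohort of isolated cells
#'
#' Groups cells by isolation support, computes each support's leukocyte
#' mean diameter, calls atypicality and CTC status (each support is scored
#' with its own staining panel), and aggregates counts.
#'
#' @param cells cohort cell records (see [simulate_cohort_cells()]); must
#'   carry `support_id`, `subject_id`, `cohort` and `panel` columns.
#' @param panels named list mapping panel name to marker vector.
#' @param rules a [ctc_rules()]; its `panel` field is overridden per
#'   support by `panels`.
#' @return list with `calls` (per-cell tibble incl. support/subject ids),
#'   `supports` (per-support `n_ac`, `n_ctc`) and `subjects` (per
#'   subject x panel `n_ac`, `n_ctc`, `pct_stained` = 100 n_ctc / n_ac,
#'   NA when n_ac = 0).
#' @export
call_cohort <- function(cells,
                        panels = list(conventional = c("EpCAM", "CK"),
                                      cocktail = c("MARCKSL1", "SLC9A3R1",
                                                   "RHOD")),
                        rules = ctc_rules()) {
  stopifnot(all(c("support_id", "subject_id", "cohort", "panel") %in%
                  names(cells)))
  out <- lapply(split(seq_len(nrow(cells)), cells$support_id), function(i) {
    sup <- cells[i, ]
    panel_name <- sup$panel[1]
    if (!panel_name %in% names(panels))
      stop_input("call_cohort: unknown panel '%s'", panel_name)
    r <- rules
    r$panel <- panels[[panel_name]]
    lm <- leukocyte_mean_diameter(sup, r)
    calls <- call_ctc(sup, call_atypical(sup, r, lm), r)
    calls$support_id <- sup$support_id
    calls$subject_id <- sup$subject_id
    calls$cohort <- sup$cohort
    calls$panel <- panel_name
    calls
  })
  calls <- bind_rows(out)
  supports <- calls %>%
    group_by(.data$support_id, .data$subject_id, .data$cohort,
             .data$panel) %>%
    summarise(n_ac = sum(.data$atypical),
              n_ctc = sum(.data$label == "CTC"), .groups = "drop")
  subjects <- supports %>%
    group_by(.data$subject_id, .data$cohort, .data$panel) %>%
    summarise(n_ac = sum(.data$n_ac), n_ctc = sum(.data$n_ctc),
              .groups = "drop") %>%
    mutate(pct_stained = ifelse(.data$n_ac > 0,
                                100 * .data$n_ctc / .data$n_ac, NA_real_))
  list(calls = calls, supports = supports, subjects = subjects)
}

#' Write cell calls as TSV
#' @param calls per-cell calls tibble.
#' @param path file path.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
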