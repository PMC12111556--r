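#' Simulation configuration
#'
#' Parameters of the synthetic datasets that stand in for the study's real
#' inputs: a bulk tumor/adjacent-tissue microarray-like matrix, a
#' heterogeneous cell-line panel, a sparse single-cell CTC matrix, gene
#' annotations (membrane / immune-cell flags from two databases, ordinal
#' IHC levels), protein sequences and a patient/donor cell cohort.
#'
#' Defaults are frozen to the study conditions the pipeline is meant to
#' emulate: a clear log2-scale tumor shift for a minority of genes, a
#' cell-line panel in which roughly 10% of genes are both expressed and
#' variable, dropout-dominated single-cell values, and annotation fractions
#' echoing the published 26-of-50 both-database / 4-of-50 one-database
#' membrane split.
#'
#' @param seed integer RNG seed; identical (config, seed) pairs give
#'   byte-identical outputs.
#' @param n_genes,n_tumor,n_adjacent matrix dimensions for the bulk dataset.
#' @param n_true_deg number of genes receiving the planted tumor shift
#'   (may be 0).
#' @param deg_log2_shift planted tumor-vs-adjacent shift, log2 units.
#' @param bulk_noise_sd residual Gaussian noise SD on the log2 scale.
#' @param n_cell_lines number of cell lines in the panel matrix.
#' @param frac_expressed_variable fraction of genes planted as
#'   expressed-and-variable in the cell-line panel.
#' @param sc_n_cells,sc_dropout single-cell matrix: number of cells and
#'   fraction of entries forced to exactly zero.
#' @param frac_membrane_both,frac_membrane_one fractions of genes flagged as
#'   membrane-localized by both annotation databases / by exactly one.
#' @param frac_immune fraction of genes flagged as expressed by immune cells.
#' @param frac_ihc_high fraction of genes with a high-IHC expression profile
#'   across simulated tumor sections.
#' @param frac_go_membrane fraction of extra genes (beyond database-flagged
#'   ones) carrying the Gene Ontology plasma-membrane flag.
#' @param n_ihc_samples number of simulated tumor sections graded per gene.
#' @param protein_length_range integer range of simulated protein lengths.
#' @param cohort a [cohort_sim_config()].
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       n_tumor = 20L,
                       n_adjacent = 20L,
                       n_true_deg = 100L,
                       deg_log2_shift = 2,
                       bulk_noise_sd = 0.7,
                       n_cell_lines = 50L,
                       frac_expressed_variable = 0.1,
                       sc_n_cells = 100L,
                       sc_dropout = 0.6,
                       frac_membrane_both = 0.52,
                       frac_membrane_one = 0.08,
                       frac_immune = 0.2,
                       frac_ihc_high = 0.6,
                       frac_go_membrane = 0.4,
                       n_ihc_samples = 11L,
                       protein_length_range = c(80L, 300L),
                       cohort = cohort_sim_config()) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_tumor = as.integer(n_tumor), n_adjacent = as.integer(n_adjacent),
              n_true_deg = as.integer(n_true_deg),
              deg_log2_shift = deg_log2_shift, bulk_noise_sd = bulk_noise_sd,
              n_cell_lines = as.integer(n_cell_lines),
              frac_expressed_variable = frac_expressed_variable,
              sc_n_cells = as.integer(sc_n_cells), sc_dropout = sc_dropout,
              frac_membrane_both = frac_membrane_both,
              frac_membrane_one = frac_membrane_one,
              frac_immune = frac_immune, frac_ihc_high = frac_ihc_high,
              frac_go_membrane = frac_go_membrane,
              n_ihc_samples = as.integer(n_ihc_samples),
              protein_length_range = as.integer(protein_length_range),
              cohort = cohort)
  for (f in c("n_genes", "n_tumor", "n_adjacent", "n_cell_lines",
              "sc_n_cells", "n_ihc_samples"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop_config(f, "must be a count >= 1")
  if (is.na(cfg$n_true_deg) || cfg$n_true_deg < 0L)
    stop_config("n_true_deg", "must be a count >= 0")
  if (cfg$n_true_deg > cfg$n_genes)
    stop_config("n_true_deg", "must be <= n_genes")
  for (f in c("frac_expressed_variable", "sc_dropout", "frac_membrane_both",
              "frac_membrane_one", "frac_immune", "frac_ihc_high",
              "frac_go_membrane"))
    if (!is.numeric(cfg[[f]]) || is.na(cfg[[f]]) ||
        cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_config(f, "must be a fraction in [0, 1]")
  if (cfg$frac_membrane_both + cfg$frac_membrane_one > 1)
    stop_config("frac_membrane_one",
                "plus frac_membrane_both must not exceed 1")
  if (cfg$bulk_noise_sd <= 0) stop_config("bulk_noise_sd", "must be > 0")
  if (length(cfg$protein_length_range) != 2L ||
      any(is.na(cfg$protein_length_range)) ||
      cfg$protein_length_range[1] > cfg$protein_length_range[2] ||
      cfg$protein_length_range[1] < 2L)
    stop_config("protein_length_range", "must be an increasing range >= 2")
  class(cfg) <- "sim_config"
  cfg
}

#' Cohort simulation configuration
#'
#' Study conditions of the clinical validation arm: atypical-cell (AC)
#' burdens are Poisson counts per 3 mL isolation support, and each AC
#' stains positive with a panel's per-cell sensitivity. Defaults mirror the
#' validated cohort: 40 lymph-node-invaded patients vs 18 healthy donors,
#' cohort-average AC burdens of 27.14 vs 0.77 per 3 mL, and per-cell
#' staining sensitivities of 0.6582 for the conventional EpCAM+CK panel vs
#' 0.9959 for the MARCKSL1+SLC9A3R1+RHOD cocktail.
#'
#' @param n_patients,n_donors subjects per cohort.
#' @param patient_ac_mean,donor_ac_mean expected atypical cells per 3 mL
#'   support (Poisson means).
#' @param conventional_sensitivity,cocktail_sensitivity per-cell probability
#'   that an AC stains positive with the respective panel.
#' @param high_given_positive probability a positive stain is scored high
#'   (vs low).
#' @param leukocytes_per_support residual leukocytes retained per support.
#' @return a validated `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_patients = 40L,
                              n_donors = 18L,
                              patient_ac_mean = 27.14,
                              donor_ac_mean = 0.77,
                              conventional_sensitivity = 0.6582,
                              cocktail_sensitivity = 0.9959,
                              high_given_positive = 0.7,
                              leukocytes_per_support = 50L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_donors = as.integer(n_donors),
              patient_ac_mean = patient_ac_mean,
              donor_ac_mean = donor_ac_mean,
              conventional_sensitivity = conventional_sensitivity,
              cocktail_sensitivity = cocktail_sensitivity,
              high_given_positive = high_given_positive,
              leukocytes_per_support = as.integer(leukocytes_per_support))
  for (f in c("n_patients", "n_donors"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stop_config(f, "must be a count >= 1")
  for (f in c("patient_ac_mean", "donor_ac_mean"))
    if (!is.numeric(cfg[[f]]) || is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop_config(f, "must be a non-negative mean")
  for (f in c("conventional_sensitivity", "cocktail_sensitivity",
              "high_given_positive"))
    if (!is.numeric(cfg[[f]]) || is.na(cfg[[f]]) ||
        cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_config(f, "must be a probability in [0, 1]")
  if (cfg$leukocytes_per_support < 0L)
    stop_config("leukocytes_per_support", "must be a count >= 0")
  class(cfg) <- "cohort_sim_config"
  cfg
}

sim_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate a bulk tumor vs adjacent-tissue expression matrix
#'
#' Log2-scale intensities: a per-gene Gaussian baseline plus Gaussian noise;
#' `n_true_deg` randomly chosen genes additionally receive
#' `+deg_log2_shift` in every tumor sample.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (an `expr_matrix`, platform `bulk_log`),
#'   `design` (tibble `sample_id`, `group` in BT/BNT) and `truth`
#'   (character vector of planted gene ids).
#' @export
simulate_bulk <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sim_gene_ids(cfg$n_genes)
  n <- cfg$n_tumor + cfg$n_adjacent
  samples <- c(sprintf("BT%02d", seq_len(cfg$n_tumor)),
               sprintf("BNT%02d", seq_len(cfg$n_adjacent)))
  group <- rep(c("BT", "BNT"), c(cfg$n_tumor, cfg$n_adjacent))
  baseline <- rnorm(cfg$n_genes, mean = 7, sd = 1.5)
  # mildly heterogeneous per-gene residual SDs (lognormal around
  # bulk_noise_sd), as on real arrays; gives the shrinkage prior finite df
  gene_sd <- cfg$bulk_noise_sd * exp(rnorm(cfg$n_genes, 0, 0.25))
  m <- baseline + matrix(rnorm(cfg$n_genes * n), nrow = cfg$n_genes) * gene_sd
  truth <- sort(sample(genes, cfg$n_true_deg))
  m[match(truth, genes), group == "BT"] <-
    m[match(truth, genes), group == "BT"] + cfg$deg_log2_shift
  dimnames(m) <- list(genes, samples)
  list(matrix = expression_matrix(m, "bulk_log"),
       design = tibble(sample_id = samples, group = group),
       truth = truth)
}

#' Simulate a heterogeneous cell-line expression panel
#'
#' A planted fraction of genes is expressed-and-variable (high mean, high
#' between-line variance); the rest sit at a low, tight baseline. The
#' planted set is exactly what the `overmean` selector is designed to
#' recover.
#'
#' @param cfg a [sim_config()].
#' @param planted_genes optional character vector of gene ids to plant as
#'   expressed-and-variable; `NULL` picks a random fraction
#'   `frac_expressed_variable`.
#' @return list with `matrix` (`bulk_log` platform) and `truth` (planted
#'   gene ids).
#' @export
simulate_cell_lines <- function(cfg, planted_genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  genes <- sim_gene_ids(cfg$n_genes)
  lines <- sprintf("CL%03d", seq_len(cfg$n_cell_lines))
  if (is.null(planted_genes)) {
    n_planted <- round(cfg$frac_expressed_variable * cfg$n_genes)
    truth <- sort(sample(genes, n_planted))
  } else {
    if (!all(planted_genes %in% genes))
      stop_input("planted_genes not in the gene universe: %s",
                 paste(head(setdiff(planted_genes, genes), 5),
                       collapse = ", "))
    truth <- sort(unique(planted_genes))
    n_planted <- length(truth)
  }
  base_mean <- rnorm(cfg$n_genes, mean = 6, sd = 0.5)
  base_sd <- runif(cfg$n_genes, 0.2, 0.4)
  planted <- match(truth, genes)
  base_mean[planted] <- runif(n_planted, 8, 10)
  base_sd[planted] <- runif(n_planted, 1.5, 2.5)
  m <- base_mean + matrix(rnorm(cfg$n_genes * cfg$n_cell_lines),
                          nrow = cfg$n_genes) * base_sd
  dimnames(m) <- list(genes, lines)
  list(matrix = expression_matrix(m, "bulk_log"), truth = truth)
}

#' Simulate a sparse single-cell CTC FPKM matrix
#'
#' Non-negative lognormal signal with per-cell library-size heterogeneity,
#' masked by Bernoulli dropout: a fraction `sc_dropout` of entries is
#' exactly zero. Genes listed in `expressed_genes` are planted as highly
#' expressed and variable so the downstream expressed-in-CTC intersection
#' has a known truth; by default a fraction `frac_expressed_variable` of
#' genes is planted.
#'
#' @param cfg a [sim_config()].
#' @param expressed_genes optional character vector of gene ids to plant as
#'   expressed; `NULL` picks a random fraction.
#' @param gene_ids gene universe (defaults to the shared simulated ids).
#' @return list with `matrix` (`fpkm` platform) and `truth` (expressed
#'   gene ids).
#' @export
simulate_ctc_singlecell <- function(cfg, expressed_genes = NULL,
                                    gene_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  genes <- if (is.null(gene_ids)) sim_gene_ids(cfg$n_genes) else gene_ids
  if (anyDuplicated(genes)) stop_input("gene ids must be unique")
  ng <- length(genes)
  cells <- sprintf("CTC%03d", seq_len(cfg$sc_n_cells))
  if (is.null(expressed_genes)) {
    expressed_genes <- sort(sample(genes,
                                   round(cfg$frac_expressed_variable * ng)))
  } else if (!all(expressed_genes %in% genes)) {
    stop_input("expressed_genes not in the gene universe: %s",
               paste(head(setdiff(expressed_genes, genes), 5), collapse = ", "))
  }
  log_mu <- rnorm(ng, mean = 0, sd = 0.3)
  log_sd <- rep(0.5, ng)
  idx <- match(expressed_genes, genes)
  log_mu[idx] <- rnorm(length(idx), mean = log(50), sd = 0.3)
  log_sd[idx] <- 1
  size_factor <- rlnorm(cfg$sc_n_cells, 0, 0.3)
  m <- exp(log_mu + matrix(rnorm(ng * cfg$sc_n_cells), nrow = ng) * log_sd)
  m <- sweep(m, 2, size_factor, `*`)
  keep <- matrix(rbinom(ng * cfg$sc_n_cells, 1, 1 - cfg$sc_dropout),
                 nrow = ng)
  m <- m * keep
  dimnames(m) <- list(genes, cells)
  list(matrix = expression_matrix(m, "fpkm"),
       truth = sort(expressed_genes))
}

ihc_levels_ordered <- c("not_detected", "low", "medium", "high")

#' Simulate a gene annotation table
#'
#' Per-gene membrane flags from two databases (both with probability
#' `frac_membrane_both`, exactly one with `frac_membrane_one`), concordant
#' immune-expression flags (probability `frac_immune`), a Gene Ontology
#' plasma-membrane flag, and ordinal IHC grades over `n_ihc_samples`
#' simulated tumor sections. Genes drawn as high-IHC (probability
#' `frac_ihc_high`) grade mostly medium/high; the rest mostly
#' not-detected/low.
#'
#' @param genes unique character gene ids.
#' @param cfg a [sim_config()].
#' @return tibble with columns `gene_id`, `membrane_db1`, `membrane_db2`,
#'   `immune_db1`, `immune_db2`, `go_plasma_membrane` and list-column
#'   `ihc_levels`.
#' @export
simulate_annotations <- function(genes, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (anyDuplicated(genes)) stop_input("duplicate gene ids in 'genes'")
  set.seed(cfg$seed + 3L)
  n <- length(genes)
  u <- runif(n)
  both <- u < cfg$frac_membrane_both
  one <- !both & u < cfg$frac_membrane_both + cfg$frac_membrane_one
  which_db <- runif(n) < 0.5
  membrane_db1 <- both | (one & which_db)
  membrane_db2 <- both | (one & !which_db)
  immune <- runif(n) < cfg$frac_immune
  go_pm <- (membrane_db1 | membrane_db2) | (runif(n) < cfg$frac_go_membrane)
  high_profile <- runif(n) < cfg$frac_ihc_high
  probs_high <- c(0.05, 0.15, 0.40, 0.40)
  probs_low <- c(0.60, 0.30, 0.08, 0.02)
  ihc <- lapply(seq_len(n), function(i) {
    p <- if (high_profile[i]) probs_high else probs_low
    sample(ihc_levels_ordered, cfg$n_ihc_samples, replace = TRUE, prob = p)
  })
  tibble(gene_id = genes,
         membrane_db1 = membrane_db1, membrane_db2 = membrane_db2,
         immune_db1 = immune, immune_db2 = immune,
         go_plasma_membrane = go_pm,
         ihc_levels = ihc)
}

#' Write / read a gene annotation table as TSV
#'
#' IHC level lists are serialized comma-joined in a single column.
#' @param annot annotation tibble from [simulate_annotations()].
#' @param path file path.
#' @export
write_annotation_tsv <- function(annot, path) {
  out <- annot
  out$ihc_levels <- vapply(annot$ihc_levels, paste, "", collapse = ",")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  df$ihc_levels <- strsplit(df$ihc_levels, ",", fixed = TRUE)
  for (f in c("membrane_db1", "membrane_db2", "immune_db1", "immune_db2",
              "go_plasma_membrane"))
    df[[f]] <- as.logical(df[[f]])
  as_tibble(df)
}

aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Simulate protein sequences for a gene set
#'
#' Background sequences are i.i.d. draws over the 20 standard residues.
#' A fraction `frac_antigenic` of sequences instead carries an amphipathic
#' periodic structure (alternating hydrophobic / polar blocks of period 4
#' with 10% random substitution), which produces strong lagged
#' auto/cross-covariance signal that an antigenicity head can learn.
#' `mode = "homopolymer"` emits single-residue repeats (useful because
#' centered ACC descriptors of a homopolymer are identically zero).
#'
#' @param genes unique gene ids (one protein per gene).
#' @param cfg a [sim_config()]; `protein_length_range` bounds the lengths.
#' @param frac_antigenic fraction of sequences generated with the antigenic
#'   structure.
#' @param mode `"random"` or `"homopolymer"`.
#' @return list with `records` (tibble `id`, `sequence`) and `truth`
#'   (ids of antigenic-structured sequences).
#' @export
simulate_proteins <- function(genes, cfg, frac_antigenic = 0,
                              mode = c("random", "homopolymer")) {
  stopifnot(inherits(cfg, "sim_config"))
  mode <- match.arg(mode)
  if (anyDuplicated(genes)) stop_input("duplicate gene ids in 'genes'")
  if (frac_antigenic < 0 || frac_antigenic > 1)
    stop_config("frac_antigenic", "must be a fraction in [0, 1]")
  set.seed(cfg$seed + 4L)
  n <- length(genes)
  rng <- cfg$protein_length_range
  lens <- if (rng[1] == rng[2]) rep(rng[1], n) else
    sample(seq(rng[1], rng[2]), n, replace = TRUE)
  antigenic <- sort(sample(genes, round(frac_antigenic * n)))
  hydrophobic <- c("I", "L", "V", "F", "M", "W")
  polar <- c("K", "R", "D", "E", "N", "Q", "S")
  seqs <- vapply(seq_len(n), function(i) {
    L <- lens[i]
    if (mode == "homopolymer")
      return(strrep(sample(aa_alphabet, 1), L))
    if (genes[i] %in% antigenic) {
      phase <- (seq_len(L) - 1) %% 4 < 2
      res <- ifelse(phase,
                    sample(hydrophobic, L, replace = TRUE),
                    sample(polar, L, replace = TRUE))
      sub <- runif(L) < 0.1
      res[sub] <- sample(aa_alphabet, sum(sub), replace = TRUE)
      paste(res, collapse = "")
    } else {
      paste(sample(aa_alphabet, L, replace = TRUE), collapse = "")
    }
  }, "")
  list(records = tibble(id = genes, sequence = seqs), truth = antigenic)
}

stain_levels <- c("negative", "low", "high")

sim_panels <- list(conventional = c("EpCAM", "CK"),
                   cocktail = c("MARCKSL1", "SLC9A3R1", "RHOD"))

# draw staining levels for one AC under one panel: panel-positive with
# probability `sens`; a positive cell has at least one member marker
# positive (high vs low per `p_high`), others positive with prob 0.5
draw_stains <- function(markers, sens, p_high) {
  lev <- setNames(rep("negative", length(markers)), markers)
  if (runif(1) < sens) {
    pos <- runif(length(markers)) < 0.5
    pos[sample(length(markers), 1)] <- TRUE
    lev[pos] <- ifelse(runif(sum(pos)) < p_high, "high", "low")
  }
  lev
}

#' Simulate a patient/donor cohort of isolated cells
#'
#' For each subject, two isolation supports (3 mL each) are simulated: one
#' stained with the conventional EpCAM+CK panel, one with the
#' MARCKSL1+SLC9A3R1+RHOD cocktail. Each support carries
#' `leukocytes_per_support` leukocytes (CD45 intense and homogeneous, small
#' diameter, regular nucleus, N/C at most 0.75) and a Poisson number of
#' atypical cells with the cohort's mean (CD45 not intense/homogeneous,
#' diameter above the support's leukocyte mean, irregular nucleus,
#' N/C above 0.75). Atypical cells stain with the support's panel at the
#' panel's per-cell sensitivity; leukocytes never stain.
#'
#' @param cfg a [cohort_sim_config()].
#' @param seed integer RNG seed.
#' @return tibble of cell records: `cell_id`, `subject_id`, `support_id`,
#'   `cohort`, `panel`, `diameter`, `nc_ratio`, `nuclear_irregular`,
#'   `cd45_intensity`, `cd45_homogeneous`, plus one `stain_<marker>` column
#'   per marker of that support's panel (NA on the other panel's supports).
#' @export
simulate_cohort_cells <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(as.integer(seed))
  subjects <- tibble(
    subject_id = c(sprintf("P%02d", seq_len(cfg$n_patients)),
                   sprintf("D%02d", seq_len(cfg$n_donors))),
    cohort = rep(c("patient", "donor"), c(cfg$n_patients, cfg$n_donors)))
  all_markers <- unlist(sim_panels, use.names = FALSE)
  rows <- list()
  for (s in seq_len(nrow(subjects))) {
    subj <- subjects$subject_id[s]
    coh <- subjects$cohort[s]
    ac_mean <- if (coh == "patient") cfg$patient_ac_mean else cfg$donor_ac_mean
    for (panel_name in names(sim_panels)) {
      support <- sprintf("%s_IS_%s", subj, panel_name)
      markers <- sim_panels[[panel_name]]
      sens <- if (panel_name == "conventional")
        cfg$conventional_sensitivity else cfg$cocktail_sensitivity
      n_leuko <- cfg$leukocytes_per_support
      n_ac <- rpois(1, ac_mean)
      n_cells <- n_leuko + n_ac
      if (n_cells == 0) next
      is_ac <- rep(c(FALSE, TRUE), c(n_leuko, n_ac))
      leuko_d <- rnorm(n_leuko, mean = 10, sd = 1.2)
      leuko_mu <- if (n_leuko > 0) mean(leuko_d) else 12
      diam <- c(leuko_d, leuko_mu + 2 + abs(rnorm(n_ac, 4, 2)))
      nc <- c(runif(n_leuko, 0.35, 0.70), runif(n_ac, 0.76, 0.98))
      stains <- matrix(NA_character_, nrow = n_cells,
                       ncol = length(all_markers),
                       dimnames = list(NULL, paste0("stain_", all_markers)))
      stains[, paste0("stain_", markers)] <- "negative"
      if (n_ac > 0) {
        for (i in which(is_ac))
          stains[i, paste0("stain_", markers)] <-
            draw_stains(markers, sens, cfg$high_given_positive)
      }
      rows[[length(rows) + 1L]] <- tibble(
        cell_id = sprintf("%s_c%03d", support, seq_len(n_cells)),
        subject_id = subj, support_id = support, cohort = coh,
        panel = panel_name,
        diameter = diam, nc_ratio = nc,
        nuclear_irregular = is_ac,
        cd45_intensity = ifelse(is_ac,
                                sample(c("negative", "weak"), n_cells,
                                       replace = TRUE)[seq_len(n_cells)],
                                "intense"),
        cd45_homogeneous = !is_ac) %>%
        dplyr::bind_cols(as_tibble(stains))
    }
  }
  bind_rows(rows)
}

#' Write / read a cohort cell table as TSV
#' @param cells tibble from [simulate_cohort_cells()].
#' @param path file path.
#' @export
write_cells_tsv <- function(cells, path) {
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_tsv
#' @export
read_cells_tsv <- function(path) {
  df <- as_tibble(read.delim(path, check.names = FALSE))
  for (f in c("nuclear_irregular", "cd45_homogeneous"))
    df[[f]] <- as.logical(df[[f]])
  df
}
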