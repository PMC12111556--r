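#' Select expressed-and-variable genes ("overmean")
#'
#' Keeps genes that are both expressed — per-gene mean strictly above the
#' grand mean of all matrix entries — and variable — unbiased between-sample
#' variance strictly above a reference variance. The reference is the mean
#' of the per-gene variances (`ref_var = "mean_gene_var"`, default) or the
#' variance of all entries pooled (`"total_var"`). The selection is
#' invariant to adding a constant to every entry and to multiplying every
#' entry by a positive constant.
#'
#' @param matrix an `expr_matrix` with >= 2 samples.
#' @param ref_var reference-variance definition.
#' @return list with `genes` (selected ids) and `matrix` (the row-subset
#'   expression matrix).
#' @export
overmean <- function(matrix, ref_var = c("mean_gene_var", "total_var")) {
  ref_var <- match.arg(ref_var)
  if (ncol(matrix) < 2)
    stop_input("overmean: variance undefined for a single-sample matrix")
  m <- unclass(matrix)
  gene_mean <- rowMeans(m)
  grand_mean <- mean(m)
  gene_var <- row_vars(m)
  rv <- if (ref_var == "mean_gene_var") mean(gene_var) else var(as.vector(m))
  sel <- gene_mean > grand_mean & gene_var > rv
  genes <- rownames(m)[sel]
  list(genes = genes, matrix = subset_expr(matrix, genes))
}

#' Filter a gene set to plasma-membrane genes (GO flag)
#'
#' Genes missing from the annotation are treated as not membrane-localized
#' (fail-closed) with a message.
#'
#' @param genes character gene ids.
#' @param annot annotation tibble with `gene_id` and `go_plasma_membrane`.
#' @return the membrane-flagged subset, input order preserved.
#' @export
filter_plasma_membrane <- function(genes, annot) {
  missing <- setdiff(genes, annot$gene_id)
  if (length(missing) > 0)
    message(length(missing),
            " gene(s) missing from annotation treated as non-membrane: ",
            paste(head(missing, 5), collapse = ", "))
  flag <- annot$go_plasma_membrane[match(genes, annot$gene_id)]
  genes[!is.na(flag) & flag]
}

#' Intersect gene sets with Venn region counts
#'
#' @param sets named list of >= 2 character vectors.
#' @return list with `genes` (the common intersection, sorted) and
#'   `regions`: for 2 sets, counts named `only_A`, `common`, `only_B`; for
#'   3 sets, the 7 region counts (`only_A` ... `common`).
#' @export
intersect_sets <- function(sets) {
  if (length(sets) < 2) stop_input("intersect_sets: need >= 2 sets")
  sets <- lapply(sets, unique)
  common <- Reduce(intersect, sets)
  regions <- NULL
  if (length(sets) == 2) {
    a <- sets[[1]]; b <- sets[[2]]
    regions <- c(only_A = length(setdiff(a, b)),
                 common = length(common),
                 only_B = length(setdiff(b, a)))
  } else if (length(sets) == 3) {
    a <- sets[[1]]; b <- sets[[2]]; c3 <- sets[[3]]
    regions <- c(
      only_A = length(setdiff(a, union(b, c3))),
      only_B = length(setdiff(b, union(a, c3))),
      only_C = length(setdiff(c3, union(a, b))),
      AB = length(setdiff(intersect(a, b), c3)),
      AC = length(setdiff(intersect(a, c3), b)),
      BC = length(setdiff(intersect(b, c3), a)),
      common = length(common))
  }
  list(genes = sort(common), regions = regions)
}

#' Keep candidate genes expressed in single-cell CTCs
#'
#' A candidate survives if it is selected by [overmean()] on the
#' single-cell FPKM matrix.
#'
#' @param candidates character gene ids.
#' @param sc_matrix an `expr_matrix` with platform `fpkm`.
#' @param ref_var passed to [overmean()].
#' @return list with `genes` (surviving candidates), `n_sc_expressed`
#'   (size of the single-cell overmean set).
#' @export
filter_expressed_in_ctc <- function(candidates, sc_matrix,
                                    ref_var = "mean_gene_var") {
  if (!identical(platform_of(sc_matrix), "fpkm"))
    stop_input("filter_expressed_in_ctc: sc_matrix platform must be 'fpkm'")
  expressed <- overmean(sc_matrix, ref_var = ref_var)$genes
  list(genes = intersect(candidates, expressed),
       n_sc_expressed = length(expressed))
}

#' Cascade configuration
#'
#' Thresholds of the filtering cascade. `membrane_rule = "at_least_one"`
#' keeps genes flagged by either annotation database (so as not to discard
#' borderline candidates); `"both_dbs"` is the stricter variant. The IHC
#' criterion keeps genes graded at least `ihc_min_level` in at least
#' `ihc_min_fraction` of tumor sections.
#'
#' @param fdr_threshold FDR cutoff of the differential-expression stage.
#' @param antigenicity_threshold antigenicity score cutoff.
#' @param ihc_min_level minimal ordinal IHC level
#'   (`not_detected < low < medium < high`).
#' @param ihc_min_fraction minimal fraction of sections at/above that level.
#' @param membrane_rule `"at_least_one"` or `"both_dbs"`.
#' @param ref_var reference-variance rule for [overmean()].
#' @return a validated `cascade_config` list.
#' @export
cascade_config <- function(fdr_threshold = 0.05,
                           antigenicity_threshold = 0.5,
                           ihc_min_level = "medium",
                           ihc_min_fraction = 0.5,
                           membrane_rule = c("at_least_one", "both_dbs"),
                           ref_var = c("mean_gene_var", "total_var")) {
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stop_config("fdr_threshold", "must lie in (0, 1]")
  if (!ihc_min_level %in% ihc_levels_ordered)
    stop_config("ihc_min_level",
                "must be one of not_detected/low/medium/high")
  if (ihc_min_fraction < 0 || ihc_min_fraction > 1)
    stop_config("ihc_min_fraction", "must be a fraction in [0, 1]")
  structure(list(fdr_threshold = fdr_threshold,
                 antigenicity_threshold = antigenicity_threshold,
                 ihc_min_level = ihc_min_level,
                 ihc_min_fraction = ihc_min_fraction,
                 membrane_rule = match.arg(membrane_rule),
                 ref_var = match.arg(ref_var)),
            class = "cascade_config")
}

ihc_meets <- function(levels_chr, min_level, min_fraction) {
  if (length(levels_chr) == 0) return(FALSE)
  rank <- match(levels_chr, ihc_levels_ordered)
  mean(rank >= match(min_level, ihc_levels_ordered)) >= min_fraction
}

#' Three-criterion in silico sort
#'
#' Sequentially (1) keeps genes with membrane localization under the
#' configured rule, reporting the both-database and one-database counts
#' separately; (2) drops genes flagged as expressed by immune cells in
#' either database; (3) keeps genes whose IHC grades reach
#' `ihc_min_level` in at least `ihc_min_fraction` of tumor sections.
#' Genes missing from the annotation fail all criteria (fail-closed, with
#' a message).
#'
#' @param genes character gene ids entering the sort.
#' @param annot annotation tibble (see [simulate_annotations()]).
#' @param cfg a [cascade_config()].
#' @return list with `genes` (final survivors) and `fragment`, a tibble of
#'   the three sub-stages (stage, criterion, n_in, n_out) carrying the
#'   membrane both/one split as attributes `n_membrane_both`,
#'   `n_membrane_one`.
#' @export
insilico_sort <- function(genes, annot, cfg = cascade_config()) {
  missing <- setdiff(genes, annot$gene_id)
  if (length(missing) > 0)
    message(length(missing),
            " gene(s) missing from annotation fail all sort criteria: ",
            paste(head(missing, 5), collapse = ", "))
  idx <- match(genes, annot$gene_id)
  db1 <- ifelse(is.na(idx), FALSE, annot$membrane_db1[idx])
  db2 <- ifelse(is.na(idx), FALSE, annot$membrane_db2[idx])
  both <- db1 & db2
  one <- xor(db1, db2)
  keep1 <- if (cfg$membrane_rule == "both_dbs") both else (both | one)
  g1 <- genes[keep1]
  idx1 <- match(g1, annot$gene_id)
  imm <- annot$immune_db1[idx1] | annot$immune_db2[idx1]
  g2 <- g1[!imm]
  idx2 <- match(g2, annot$gene_id)
  pass3 <- vapply(annot$ihc_levels[idx2], ihc_meets, TRUE,
                  min_level = cfg$ihc_min_level,
                  min_fraction = cfg$ihc_min_fraction)
  g3 <- g2[pass3]
  fragment <- tibble(
    stage = c("sort_membrane", "sort_immune_exclusion", "sort_ihc"),
    criterion = c(
      sprintf("membrane localization (%s; both=%d, one=%d)",
              cfg$membrane_rule, sum(both), sum(one)),
      "not expressed by immune cells (either database)",
      sprintf("IHC >= %s in >= %.0f%% of tumor sections",
              cfg$ihc_min_level, 100 * cfg$ihc_min_fraction)),
    n_in = c(length(genes), length(g1), length(g2)),
    n_out = c(length(g1), length(g2), length(g3)))
  attr(fragment, "n_membrane_both") <- sum(both)
  attr(fragment, "n_membrane_one") <- sum(one)
  list(genes = g3, fragment = fragment,
       sets = list(sort_membrane = g1, sort_immune_exclusion = g2,
                   sort_ihc = g3))
}
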