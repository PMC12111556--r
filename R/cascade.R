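#' Run the full marker-discovery cascade
#'
#' Executes the in silico marker prioritization end to end:
#' \enumerate{
#'   \item expressed-and-variable genes in the cell-line panel
#'     ([overmean()]);
#'   \item tumor-upregulated genes at the FDR threshold
#'     ([moderated_t()], [select_upregulated()]) restricted to
#'     plasma-membrane genes ([filter_plasma_membrane()]);
#'   \item intersection of the two profiles ([intersect_sets()], with Venn
#'     region counts);
#'   \item antigenicity filter on the candidates' protein sequences
#'     ([score_sequences()]);
#'   \item restriction to genes expressed in single-cell CTCs
#'     ([filter_expressed_in_ctc()]);
#'   \item the three-criterion in silico sort ([insilico_sort()]).
#' }
#' Every stage is appended to an ordered ledger of (stage, criterion,
#' input count, output count) with the surviving gene sets retained.
#'
#' @param bulk tumor/adjacent `expr_matrix` (platform `bulk_log`).
#' @param design sample design tibble for `bulk`.
#' @param lines_matrix cell-line panel `expr_matrix`.
#' @param sc_matrix single-cell `expr_matrix` (platform `fpkm`).
#' @param annot gene annotation tibble.
#' @param proteins protein records tibble (`id`, `sequence`); candidates
#'   without a sequence are dropped at the antigenicity stage with a
#'   message.
#' @param cfg a [cascade_config()].
#' @param head an `antigen_head`; `NULL` trains [default_antigen_head()].
#' @return a `cascade_report`: list with `stages` (the ledger tibble),
#'   `sets` (named list of surviving gene-id vectors), `venn` (region
#'   counts of the intersection stage), and `final` (the final marker
#'   set).
#' @export
run_cascade <- function(bulk, design, lines_matrix, sc_matrix, annot,
                        proteins, cfg = cascade_config(), head = NULL) {
  universe <- rownames(bulk)
  for (nm in c("lines_matrix", "sc_matrix")) {
    other <- rownames(get(nm))
    if (!setequal(universe, other)) {
      off <- c(setdiff(universe, other), setdiff(other, universe))
      stop_input("run_cascade: gene ids of '%s' do not match bulk (%d offending: %s%s)",
                 nm, length(off), paste(head(off, 5), collapse = ", "),
                 if (length(off) > 5) ", ..." else "")
    }
  }
  if (is.null(head)) head <- default_antigen_head()
  stages <- list()
  sets <- list()
  add_stage <- function(stage, criterion, n_in, genes) {
    stages[[length(stages) + 1L]] <<- tibble(
      stage = stage, criterion = criterion,
      n_in = as.integer(n_in), n_out = length(genes))
    sets[[stage]] <<- genes
  }

  om_lines <- overmean(lines_matrix, ref_var = cfg$ref_var)$genes
  add_stage("cell_line_overmean",
            "mean over grand mean and variance over reference variance",
            nrow(lines_matrix), om_lines)

  deg <- moderated_t(bulk, design, fdr_threshold = cfg$fdr_threshold)
  up <- select_upregulated(deg, cfg$fdr_threshold)
  add_stage("tumor_upregulated",
            sprintf("log2fc > 0 and FDR < %g", cfg$fdr_threshold),
            nrow(bulk), up)

  mem <- filter_plasma_membrane(up, annot)
  add_stage("plasma_membrane_go", "GO plasma-membrane flag",
            length(up), mem)

  iv <- intersect_sets(list(membrane_upregulated = mem,
                            cell_line_variable = om_lines))
  add_stage("intersect_lines",
            "common to membrane-upregulated and cell-line profiles",
            length(mem), iv$genes)

  cand <- iv$genes
  with_seq <- intersect(cand, proteins$id)
  if (length(with_seq) < length(cand))
    message(length(cand) - length(with_seq),
            " candidate(s) without a protein sequence dropped")
  scored <- if (length(with_seq) > 0)
    score_sequences(proteins[match(with_seq, proteins$id), ], head,
                    threshold = cfg$antigenicity_threshold)
  else tibble(id = character(), score = numeric(), antigenic = logical())
  antigenic <- scored$id[scored$antigenic]
  add_stage("antigenic",
            sprintf("antigenicity score >= %g", cfg$antigenicity_threshold),
            length(cand), antigenic)

  ctc_f <- filter_expressed_in_ctc(antigenic, sc_matrix,
                                   ref_var = cfg$ref_var)
  add_stage("ctc_expressed",
            sprintf("overmean-expressed in single-cell CTCs (%d genes)",
                    ctc_f$n_sc_expressed),
            length(antigenic), ctc_f$genes)

  srt <- insilico_sort(ctc_f$genes, annot, cfg)
  for (i in seq_len(nrow(srt$fragment)))
    add_stage(srt$fragment$stage[i], srt$fragment$criterion[i],
              srt$fragment$n_in[i], srt$sets[[srt$fragment$stage[i]]])
  structure(list(stages = bind_rows(stages), sets = sets,
                 venn = iv$regions,
                 membrane_split = c(
                   both = attr(srt$fragment, "n_membrane_both"),
                   one = attr(srt$fragment, "n_membrane_one")),
                 deg = deg, final = srt$genes),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  df <- as.data.frame(x$stages)
  print(df, row.names = FALSE)
  cat(sprintf("final markers (%d): %s\n", length(x$final),
              paste(head(x$final, 12), collapse = ", ")))
  invisible(x)
}

#' Serialize a cascade ledger as JSON
#'
#' Deterministic (byte-identical for identical reports): stage array with
#' counts, Venn region counts, membrane split and the final marker set.
#'
#' @param report a `cascade_report`.
#' @param path optional output file; omit to get the JSON string.
#' @return the JSON string, invisibly when written to a file.
#' @export
cascade_ledger_json <- function(report, path = NULL) {
  obj <- list(stages = report$stages,
              venn = as.list(report$venn),
              membrane_split = as.list(report$membrane_split),
              final = report$final)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Default antigenicity head
#'
#' A deterministic logistic head trained on an internal fixed-seed corpus
#' of 200 simulated sequences (half with the antigenic amphipathic
#' structure, half background). Used by [run_cascade()] when no head is
#' supplied; replace it with an externally trained head (via
#' [train_head()] / [read_head_json()]) for real-data use.
#'
#' @return an `antigen_head`.
#' @export
default_antigen_head <- function() {
  cfg <- sim_config(seed = 20394L, n_genes = 200L,
                    protein_length_range = c(80L, 200L))
  prot <- simulate_proteins(sim_gene_ids(200L), cfg, frac_antigenic = 0.5)
  feats <- acc_features(prot$records)
  train_head(feats, prot$records$id %in% prot$truth)
}

#' Render the final analysis report
#'
#' Writes a machine-readable JSON and a human-readable text summary
#' combining the cascade ledger, marker/cocktail positivity tables,
#' per-cohort summaries and t-test results. Output is deterministic for
#' identical inputs.
#'
#' @param out_dir output directory (created if needed).
#' @param cascade a `cascade_report`, or `NULL`.
#' @param positivity positivity tibble from [positivity_table()], or
#'   `NULL`.
#' @param summary cohort summary tibble from [cohort_summary()], or
#'   `NULL`.
#' @param tests named list of `t_result`s, or `NULL`.
#' @return invisibly, the paths of the two files written.
#' @export
render_report <- function(out_dir, cascade = NULL, positivity = NULL,
                          summary = NULL, tests = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- list()
  txt <- c("CTC marker pipeline report", "==========================")
  if (!is.null(cascade)) {
    obj$cascade <- list(stages = cascade$stages,
                        venn = as.list(cascade$venn),
                        membrane_split = as.list(cascade$membrane_split),
                        final = cascade$final)
    txt <- c(txt, "", "Cascade stages (input -> output):",
             sprintf("  %-22s %5d -> %5d  [%s]", cascade$stages$stage,
                     cascade$stages$n_in, cascade$stages$n_out,
                     cascade$stages$criterion),
             sprintf("Final markers (%d): %s", length(cascade$final),
                     paste(cascade$final, collapse = ", ")))
  }
  if (!is.null(positivity)) {
    obj$positivity <- positivity
    txt <- c(txt, "", "Positivity (% of evaluated cells):",
             sprintf("  %-20s neg %6.2f  low %6.2f  high %6.2f  positive %6.2f",
                     positivity$marker, positivity$pct_negative,
                     positivity$pct_low, positivity$pct_high,
                     positivity$pct_positive))
  }
  if (!is.null(summary)) {
    obj$cohort_summary <- summary
    txt <- c(txt, "", "Cohort summaries (mean +/- SEM, median, n):",
             sprintf("  %-8s %-13s %-12s %8.2f +/- %5.2f  med %6.1f  n=%d",
                     summary$cohort, summary$panel, summary$quantity,
                     summary$mean, summary$sem, summary$median, summary$n))
  }
  if (!is.null(tests)) {
    obj$tests <- lapply(tests, unclass)
    txt <- c(txt, "", "Hypothesis tests:",
             vapply(names(tests), function(nm) {
               tt <- tests[[nm]]
               sprintf("  %-38s %s t = %8.3f, df = %s, p = %.3g",
                       nm, if (tt$paired) "paired  " else "unpaired",
                       tt$statistic, format(tt$df), tt$p)
             }, ""))
  }
  if (length(obj) == 0) {
    obj <- list(note = "no subjects / no inputs")
    txt <- c(txt, "", "no subjects / no inputs")
  }
  json_path <- file.path(out_dir, "report.json")
  txt_path <- file.path(out_dir, "report.txt")
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), json_path)
  writeLines(txt, txt_path)
  invisible(c(json = json_path, txt = txt_path))
}
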