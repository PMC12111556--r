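random_expr <- function(seed, n_genes, n_samples) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = runif(1, 2, 8),
                    sd = runif(1, 0.5, 2)),
              nrow = n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  expression_matrix(m, "bulk_log")
}

test_that("overmean agrees with the brute-force loop oracle", {
  for (seed in 1:10) {
    n_g <- sample(20:500, 1)
    n_s <- sample(2:50, 1)
    m <- random_expr(seed, n_g, n_s)
    expect_setequal(overmean(m)$genes, brute_overmean(unclass(m)))
    expect_setequal(overmean(m, ref_var = "total_var")$genes,
                    brute_overmean(unclass(m), "total_var"))
  }
})

test_that("overmean is translation- and positive-scale-invariant", {
  m <- random_expr(42, 300, 20)
  base <- overmean(m)$genes
  for (c_add in c(-3, 0.5, 100)) {
    shifted <- expression_matrix(unclass(m) + c_add, "bulk_log")
    expect_identical(overmean(shifted)$genes, base)
  }
  for (c_mul in c(0.01, 3, 1000)) {
    scaled <- expression_matrix(unclass(m) * c_mul, "bulk_log")
    expect_identical(overmean(scaled)$genes, base)
  }
})

test_that("overmean degenerate inputs: constant matrix and single sample", {
  const <- expression_matrix(
    matrix(5, 10, 4, dimnames = list(paste0("g", 1:10), paste0("s", 1:4))),
    "bulk_log")
  expect_length(overmean(const)$genes, 0)

  single <- expression_matrix(
    matrix(1:5, 5, 1, dimnames = list(paste0("g", 1:5), "s1")), "bulk_log")
  expect_error(overmean(single), "single-sample")
})

test_that("overmean returns the matching row-subset matrix", {
  m <- random_expr(7, 100, 10)
  om <- overmean(m)
  expect_identical(rownames(om$matrix), om$genes)
  expect_identical(platform_of(om$matrix), "bulk_log")
  expect_equal(unclass(om$matrix), unclass(m)[om$genes, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("plasma-membrane filter respects flags and missing annotation", {
  annot <- tibble::tibble(gene_id = sprintf("g%02d", 1:100),
                          go_plasma_membrane = rep(c(TRUE, FALSE),
                                                   c(40, 60)))
  genes <- annot$gene_id
  expect_length(filter_plasma_membrane(genes, annot), 40)
  none <- annot; none$go_plasma_membrane <- FALSE
  expect_length(filter_plasma_membrane(genes, none), 0)
  all_t <- annot; all_t$go_plasma_membrane <- TRUE
  expect_identical(filter_plasma_membrane(genes, all_t), genes)
  expect_message(out <- filter_plasma_membrane(c(genes, "novel"), annot),
                 "missing from annotation")
  expect_false("novel" %in% out)
})

test_that("set intersection reports correct genes and Venn regions", {
  a <- c("a", "b", "c")
  expect_identical(intersect_sets(list(A = a, B = a))$genes, sort(a))

  d <- intersect_sets(list(A = c("a", "b"), B = c("x", "y", "z")))
  expect_length(d$genes, 0)
  expect_equal(sum(d$regions), 5)

  iv <- intersect_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_identical(iv$genes, c("b", "c"))
  expect_equal(unname(iv$regions), c(1, 2, 1))

  iv3 <- intersect_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                             C = c("c", "d", "e")))
  expect_identical(iv3$genes, "c")
  expect_equal(sum(iv3$regions), 5)  # a,b,c,d,e each counted once
  expect_error(intersect_sets(list(a)), ">= 2")
})

test_that("expressed-in-CTC filter intersects with single-cell overmean", {
  cfg <- sim_config(seed = 21, n_genes = 300, sc_dropout = 0.4)
  planted <- sprintf("G%05d", seq(5, 290, by = 12))
  sim <- simulate_ctc_singlecell(cfg, expressed_genes = planted)
  res <- filter_expressed_in_ctc(planted, sim$matrix)
  expect_gte(length(res$genes) / length(planted), 0.9)

  zero <- expression_matrix(
    matrix(0, 20, 5, dimnames = list(sprintf("G%05d", 1:20),
                                     paste0("c", 1:5))), "fpkm")
  expect_length(filter_expressed_in_ctc(sprintf("G%05d", 1:5), zero)$genes, 0)
  expect_error(filter_expressed_in_ctc("g1", random_expr(1, 10, 4)), "fpkm")
})

test_that("in silico sort matches exhaustive per-gene rule evaluation", {
  set.seed(33)
  genes <- sprintf("g%03d", 1:200)
  annot <- tibble::tibble(
    gene_id = genes,
    membrane_db1 = runif(200) < 0.5, membrane_db2 = runif(200) < 0.5,
    immune_db1 = runif(200) < 0.25, immune_db2 = runif(200) < 0.25,
    go_plasma_membrane = runif(200) < 0.5,
    ihc_levels = lapply(1:200, function(i)
      sample(c("not_detected", "low", "medium", "high"), 8, replace = TRUE)))
  for (rule in c("at_least_one", "both_dbs")) {
    cfg <- cascade_config(membrane_rule = rule)
    got <- insilico_sort(genes, annot, cfg)$genes
    want <- genes[vapply(seq_along(genes), function(i) {
      mem <- if (rule == "both_dbs")
        annot$membrane_db1[i] && annot$membrane_db2[i]
      else annot$membrane_db1[i] || annot$membrane_db2[i]
      imm <- annot$immune_db1[i] || annot$immune_db2[i]
      lev <- annot$ihc_levels[[i]]
      ihc <- mean(lev %in% c("medium", "high")) >= 0.5
      mem && !imm && ihc
    }, TRUE)]
    expect_identical(got, want)
  }
})

test_that("the tuned 50-gene fixture yields the published sort counts", {
  annot <- papercounts_annotation()
  srt <- insilico_sort(annot$gene_id, annot)
  expect_identical(srt$fragment$n_out, c(30L, 19L, 12L))
  expect_identical(attr(srt$fragment, "n_membrane_both"), 26L)
  expect_identical(attr(srt$fragment, "n_membrane_one"), 4L)
})

full_synthetic_run <- function(seed = 17) {
  cfg <- sim_config(seed = seed, n_genes = 300, n_tumor = 12,
                    n_adjacent = 12, n_true_deg = 60)
  bulk <- simulate_bulk(cfg)
  lines <- simulate_cell_lines(cfg, planted_genes = bulk$truth)
  sc <- simulate_ctc_singlecell(cfg, expressed_genes = bulk$truth)
  annot <- simulate_annotations(rownames(bulk$matrix), cfg)
  prot <- simulate_proteins(rownames(bulk$matrix), cfg, frac_antigenic = 0.5)
  run_cascade(bulk$matrix, bulk$design, lines$matrix, sc$matrix, annot,
              prot$records)
}

test_that("cascade stages only ever shrink their input sets", {
  rep <- full_synthetic_run()
  filtering <- rep$stages$stage[-(1:2)]  # first two start from the universe
  frag <- rep$stages[rep$stages$stage %in% filtering, ]
  expect_true(all(frag$n_out <= frag$n_in))
  for (s in seq_len(nrow(rep$stages)))
    expect_equal(rep$stages$n_out[s], length(rep$sets[[rep$stages$stage[s]]]))
  # sequential containment through the funnel
  expect_true(all(rep$sets$antigenic %in% rep$sets$intersect_lines))
  expect_true(all(rep$sets$ctc_expressed %in% rep$sets$antigenic))
  expect_true(all(rep$final %in% rep$sets$ctc_expressed))
})

test_that("cascade ledger is deterministic for identical inputs", {
  r1 <- full_synthetic_run()
  r2 <- full_synthetic_run()
  expect_identical(cascade_ledger_json(r1), cascade_ledger_json(r2))
})

test_that("cascade rejects mismatched gene universes", {
  cfg <- sim_config(seed = 1, n_genes = 50, n_tumor = 4, n_adjacent = 4,
                    n_true_deg = 5)
  bulk <- simulate_bulk(cfg)
  lines <- simulate_cell_lines(cfg)
  bad <- unclass(lines$matrix)[1:40, ]
  expect_error(
    run_cascade(bulk$matrix, bulk$design,
                expression_matrix(bad, "bulk_log"),
                simulate_ctc_singlecell(cfg)$matrix,
                simulate_annotations(rownames(bulk$matrix), cfg),
                simulate_proteins(rownames(bulk$matrix), cfg)$records),
    "gene ids")
})
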