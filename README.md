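# ctcmarkers

Marker discovery and detection statistics for circulating tumor cells
(CTCs) in breast cancer.

CTCs are rare tumor-derived cells in peripheral blood — on the order of
1–100 per 3 mL against millions of leukocytes. After size-based
enrichment, identifying which retained cells are tumor-derived depends on
immunostaining, and the conventional epithelial markers (EpCAM,
cytokeratins) leave a substantial fraction of candidate cells unlabeled.
`ctcmarkers` implements the full in silico strategy for proposing and
evaluating better staining markers:

* **Prioritization cascade** (`run_cascade()`): differential expression by
  a re-implemented moderated t-statistic with empirical-Bayes variance
  shrinkage — $\tilde s^2_g = (d_0 s_0^2 + d\,s^2_g)/(d_0+d)$, prior
  estimated by moments on $\log s^2_g$ — and Benjamini–Hochberg FDR
  control (`moderated_t()`, `bh_adjust()`); the "overmean"
  expressed-and-variable gene selector (mean above grand mean **and**
  variance above the reference variance, `overmean()`); plasma-membrane
  and gene-set intersection stages with Venn counts; protein antigenicity
  scoring by auto/cross-covariance descriptors
  $A_{jk}(l) = \sum_i (z_j(i)-\bar z_j)(z_k(i+l)-\bar z_k)/(n-l)$
  over the classical three z-scales with a trainable logistic head
  (`acc_transform()`, `train_head()`, `score_sequences()`); and a
  three-criterion in silico sort on membrane localization, immune-cell
  expression and immunohistochemistry level (`insilico_sort()`).
* **Cell calling** (`call_cohort()`): rule-based classification of
  isolated cells — atypical iff no intense-and-homogeneous CD45, diameter
  strictly above the support's mean leukocyte diameter, irregular nuclear
  outline, and nuclear/cytoplasmic ratio strictly > 0.75 — then CTC vs
  potential CTC by panel staining.
* **Cohort statistics** (`positivity_table()`, `cohort_summary()`,
  `paired_t()`, `unpaired_t()`): marker/cocktail positivity tables with
  the identities `negative+low+high = 100` and `positive = low+high`,
  per-subject mean ± SEM summaries, and classical Student t-tests.
* **Synthetic data** (`simulate_*()`): generators for every input the
  pipeline consumes — bulk tumor/adjacent matrices, heterogeneous
  cell-line panels, sparse single-cell FPKM, annotations, protein
  sequences, and patient/donor cell cohorts — with planted ground truth,
  so the whole cascade is testable offline.

See the vignette (`vignettes/marker-cascade.Rmd`) for the models,
assumptions and design choices.

## Worked example

```r
library(ctcmarkers)

cfg <- sim_config(seed = 1)                       # 1000 genes, 20 vs 20 samples
bulk <- simulate_bulk(cfg)
lines <- simulate_cell_lines(cfg, planted_genes = bulk$truth)
sc <- simulate_ctc_singlecell(cfg, expressed_genes = bulk$truth)
annot <- simulate_annotations(rownames(bulk$matrix), cfg)
prot <- simulate_proteins(rownames(bulk$matrix), cfg, frac_antigenic = 0.5)

run_cascade(bulk$matrix, bulk$design, lines$matrix, sc$matrix,
            annot, prot$records)
```

```
<cascade_report>
                 stage                                                 criterion n_in n_out
    cell_line_overmean mean over grand mean and variance over reference variance 1000   100
     tumor_upregulated                                 log2fc > 0 and FDR < 0.05 1000   100
    plasma_membrane_go                                   GO plasma-membrane flag  100    75
       intersect_lines     common to membrane-upregulated and cell-line profiles   75    75
             antigenic                                 antigenicity score >= 0.5   75    38
         ctc_expressed         overmean-expressed in single-cell CTCs (96 genes)   38    35
         sort_membrane      membrane localization (at_least_one; both=29, one=2)   35    31
 sort_immune_exclusion           not expressed by immune cells (either database)   31    27
              sort_ihc                 IHC >= medium in >= 50% of tumor sections   27    16
final markers (16): G00035, G00147, G00194, G00238, G00286, G00291, ...
```

The ledger reads as a funnel: of 1000 genes, 100 are
expressed-and-variable across the cell-line panel, 100 are
tumor-upregulated at FDR < 0.05 (the 100 planted genes — recall here is
1.0), 75 of those carry the plasma-membrane flag, all 75 survive the
intersection (truths were planted to overlap), 38 score antigenic, 35 are
expressed in the single-cell CTC matrix, and the three-step sort leaves a
final panel of 16 markers.

Scoring a simulated clinical cohort (40 patients, 18 donors) compares the
two staining panels per patient:

```r
cells <- simulate_cohort_cells(cohort_sim_config(), seed = 1001)
res <- call_cohort(cells)
s <- cohort_summary(res$subjects)
s[s$quantity == "pct_stained" & s$cohort == "patient", ]
```

```
  cohort        panel    quantity     mean       sem sem_degenerate    median  n
 patient     cocktail pct_stained 99.80797 0.1352578          FALSE 100.00000 40
 patient conventional pct_stained 65.04533 1.2836106          FALSE  64.83516 40
```

The three-marker cocktail stains 99.8% of each patient's atypical cells
on average versus 65.0% for the conventional EpCAM+CK panel — a gap of
about 35 percentage points, strongly significant under the paired test:

```r
paired_t(pct_cocktail, pct_conventional)
#> paired t-test: t = 27.1345, df = 39, p = 6.245e-27
```

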