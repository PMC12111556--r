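---
title: "From transcriptomes to a CTC staining cocktail: the ctcmarkers pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From transcriptomes to a CTC staining cocktail: the ctcmarkers pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcmarkers)
```

## The problem

Circulating tumor cells (CTCs) are rare tumor-derived cells in peripheral
blood — typically between one and a hundred cells per 3 mL in breast cancer
patients, against millions of leukocytes. Size-based filtration retains
candidate cells on an isolation support, but confirming which retained cells
are tumor-derived relies on immunostaining. The conventional epithelial
markers (EpCAM and cytokeratins) miss a substantial fraction of candidate
cells, notably those that have undergone epithelial–mesenchymal transition.

`ctcmarkers` implements, as reusable and tested components, a complete
in silico strategy for proposing better staining markers and quantifying
how much better they are: (i) a transcriptome-driven prioritization cascade
that funnels a gene universe down to a small panel of membrane-expressed,
antigenic, tumor-enriched candidates; (ii) rule-based classification of
isolated cells into leukocytes, atypical cells and CTCs; and (iii) the
cohort statistics used to compare marker panels. Because the original
inputs are external repositories and curated databases, the package ships a
synthetic-data generator that reproduces their statistical structure, so
every stage runs and is verifiable offline.

## The prioritization cascade

`run_cascade()` executes six stages, each recorded in a ledger of
(criterion, input count, output count):

1. **Cell-line heterogeneity.** `overmean()` keeps genes that are
   *expressed* (per-gene mean strictly above the grand mean of all matrix
   entries) and *variable* (unbiased between-sample variance strictly above
   a reference variance). The reference variance is the mean of the
   per-gene variances by default; a pooled-total-variance alternative is
   available via `ref_var = "total_var"` because the verbal definition of
   the selection rule admits both readings — for matrices without strong
   outliers the two selections nearly coincide. Strict inequalities mean a
   constant matrix selects nothing. The rule is invariant to adding a
   constant to all entries and to positive rescaling, which the test suite
   asserts as properties.

2. **Tumor upregulation.** `moderated_t()` fits the two-group comparison
   (tumor vs adjacent tissue) per gene and shrinks residual variances
   empirically: with per-gene variance $s^2_g$ on $d$ degrees of freedom,
   the posterior variance is
   $\tilde s^2_g = (d_0 s_0^2 + d\, s^2_g)/(d_0 + d)$, where the prior
   $(d_0, s_0^2)$ is estimated by the method of moments on $\log s^2_g$
   (digamma/trigamma matching, with a Newton inversion of the trigamma
   function). The moderated statistic $t_g = \Delta_g / (\tilde s_g
   \sqrt{1/n_1 + 1/n_2})$ is referred to a t distribution on $d_0 + d$
   degrees of freedom (normal in the infinite-prior limit). Setting
   `prior_df = 0` recovers the ordinary pooled t exactly, which is both a
   sanity limit and a tested equivalence. Multiplicity is handled by a
   re-implemented Benjamini–Hochberg step-up adjustment (`bh_adjust()`),
   and only genes with positive effect and FDR below the threshold
   (default 0.05) proceed. Genes with zero residual variance are floored
   to the smallest positive variance before prior estimation so
   $\log s^2$ stays finite; a matrix where *every* gene is constant falls
   back to the ordinary t with a warning.

3. **Membrane localization and intersection.** The upregulated set is
   restricted to genes carrying the Gene Ontology plasma-membrane flag and
   intersected with the cell-line profile (`intersect_sets()` also reports
   Venn region counts). Missing annotation is treated as
   not-membrane — filtering fails closed, with a message.

4. **Antigenicity.** Candidate proteins are embedded residue-by-residue
   with the classical three-component z-scales (hydrophilicity, steric
   bulk, polarity) and summarized by the auto/cross-covariance (ACC)
   transform: for descriptor pair $(j,k)$ and lag $l \le L$ (default
   $L = 8$),
   $$A_{jk}(l) = \frac{1}{n-l}\sum_{i=1}^{n-l}
     (z_j(i)-\bar z_j)(z_k(i+l)-\bar z_k),$$
   giving a fixed-length vector of $3 \times 3 \times L$ components
   regardless of sequence length. Per-sequence centering makes a
   homopolymer map to exactly zero and makes the features invariant to
   constant offsets of a descriptor column. The published antigenicity
   classifier that this stage stands in for does not publish its trained
   weights, so the discriminant head here is a ridge-regularized logistic
   model (`train_head()`) trained on labeled sequences — synthetic ones in
   the shipped pipeline — and is fully pluggable: heads serialize to JSON
   (`write_head_json()`) so externally trained weights can be substituted.
   The score threshold (default 0.5) is exposed in `cascade_config()`; the
   number of genes this stage keeps is therefore a property of the head
   and threshold, not a universal constant.

5. **Expression in CTCs.** Candidates are intersected with
   `overmean()` applied to the single-cell FPKM matrix — the same
   expressed-and-variable rule, reused on sparse non-negative data.

6. **In silico sorting.** Three sequential criteria against curated
   annotation: membrane localization per database (default
   `at_least_one`, because discarding a candidate flagged by only one of
   two databases would be needlessly conservative; `both_dbs` is available
   for sensitivity analysis), exclusion of genes expressed by immune cells
   (either database suffices to exclude), and an immunohistochemistry
   criterion — at least `medium` staining in at least half of the
   annotated tumor sections. "Several tumor samples" is not a number, so
   both the minimal level and the minimal fraction are configuration
   knobs with those defaults.

## Cell calling and cohort statistics

`call_atypical()` applies the four cytomorphological criteria exactly as
stated: a cell is *atypical* iff it lacks intense-and-homogeneous CD45
staining, is strictly larger than the mean leukocyte diameter on its own
isolation support (each support is its own reference preparation; a
support without leukocytes falls back to a configurable 12 µm), has an
irregular nuclear outline, and has nuclear/cytoplasmic ratio strictly
greater than 0.75. Ties fail: a cell at N/C = 0.75 exactly is not
atypical. `call_ctc()` labels atypical cells CTC when any panel marker
stains positive (low or high); an all-members rule is available via
`panel_mode`. The any-member rule is the one consistent with published
cocktail positivity exceeding each member's positivity.

`positivity_table()` scores marker columns the way a cocktail is read out
under the microscope: a cell is *high* if any member is high, else *low*
if any member is low, else negative — one precedence rule for single
markers and cocktails alike, which forces the accounting identities
`negative + low + high = 100` and `positive = low + high` on every column
the package computes. `cohort_summary()` reports per-subject atypical-cell
and CTC counts and percent-stained values as mean ± SEM (sd/√n) and
median per cohort; subjects with zero atypical cells have no defined
staining percentage and are excluded from that average with a message.
Percentages are averaged per subject, then across subjects (matching the
per-patient presentation of such data); pooling cells across subjects
would weight heavy-burden patients more. `paired_t()`/`unpaired_t()` are
the classical closed forms (paired differences; pooled variance),
two-sided, with explicit degenerate handling: zero variance yields p = 1
when the mean difference is zero and a flagged 0-limit otherwise.

## What the generator emulates — and what it does not

`sim_config()` / `cohort_sim_config()` defaults encode the study
conditions end to end:

* **Bulk matrix** (default 1000 genes, 20 tumor vs 20 adjacent samples):
  log2-scale Gaussian baseline (mean 7, SD 1.5) with mildly heterogeneous
  per-gene noise (lognormal around SD 0.7) and a +2 log2 shift planted in
  100 genes. The heterogeneous noise is what gives the shrinkage prior a
  finite df to estimate.
* **Cell-line panel** (50 lines): 10% of genes planted high-mean
  (8–10) and high-variance (SD 1.5–2.5) against a tight low baseline —
  exactly the structure `overmean()` selects for. On a panel with *no*
  planted structure the selector keeps the chance-level ~25% of genes
  whose mean and variance both happen to exceed their references; that is
  a property of the rule, not noise in the generator.
* **Single-cell matrix** (100 cells): multiplicative lognormal signal,
  per-cell library-size factors, and Bernoulli dropout (60% exact zeros).
* **Annotations**: membrane flags echo the published 26-of-50
  both-database and 4-of-50 one-database split (fractions 0.52/0.08);
  immune flags are drawn concordantly across the two simulated databases
  from one latent Bernoulli(0.2); IHC grades come from high- or
  low-expression profiles per gene.
* **Proteins**: background sequences are i.i.d. over the 20 residues;
  "antigenic" sequences carry an amphipathic period-4 hydrophobic/polar
  alternation with 10% substitution noise. This matters because centered
  ACC features of i.i.d. sequences are near zero regardless of
  composition — only *order* structure is learnable, so the planted class
  is defined by order structure.
* **Cohort** (40 patients, 18 donors): atypical-cell counts are Poisson
  per 3 mL support with means 27.14 (patients) and 0.77 (donors) — the
  published cohort-wide averages — naturally reproducing the
  median-of-zero behavior of donors. Staining sensitivities are 0.6582
  (EpCAM+CK) and 0.9959 (three-marker cocktail) per cell; positives split
  high vs low at 0.7. Each support carries 50 leukocytes (the source
  reports only "a small fraction of large leukocytes", so this is a fixed
  nominal contamination).

The generator does **not** emulate probe-level microarray artifacts, real
cell-line identities, empirical FPKM distributions, CTC clusters (the
underlying single-cell resource excluded them), staining-intensity
correlations between markers on the same cell, or per-patient clinical
covariates. Passing tests therefore demonstrate that the algorithms
implement their definitions correctly and recover planted structure under
realistic noise — not that the pipeline would reproduce any specific
external dataset's gene lists, whose stage counts depend on those real
data and on manual database curation.

## Numerical and design choices

* Strict inequalities throughout (`overmean` exceedances, diameter, N/C
  ratio), so boundary cases are excluded deterministically.
* The trigamma inversion uses Newton iteration to relative tolerance
  1e-10; prior estimation degenerates gracefully to infinite prior df
  (pure pooling) when the observed log-variance spread is below its
  sampling floor.
* `bh_adjust` preserves input order and clips at 1; it is
  cross-checked against an independent sort/cummin oracle and
  `p.adjust`.
* Determinism: every generator seeds the RNG from its config, so
  identical (config, seed) pairs give byte-identical TSV/FASTA/JSON
  outputs; ledgers and reports serialize with fixed field order.
* Problem sizes in the shipped tests and the acceptance script (hundreds
  to a thousand genes, tens of samples, 10^4 t-test replicates) were
  chosen as the smallest scales at which every statistical assertion has
  comfortable margin; all of them are configuration, not constants.

## Known limitations

* The antigenicity head is trained on synthetic labels; its absolute
  scores are meaningful only relative to its training corpus. Swapping in
  externally trained weights via the JSON head format is the intended
  path to real-data use.
* The overmean reference variance has two defensible readings (mean
  per-gene variance vs pooled total variance); both are implemented, the
  first is the default, and conclusions that depend on the choice should
  be checked under both.
* Cohort staining draws are independent across cells; real
  immunocytochemistry has slide-level correlation that would widen the
  cohort SEMs.
* The package consumes pre-extracted per-cell features; image analysis
  (what "irregular nuclear outline" means operationally) is out of scope.

## A minimal run

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
bulk <- simulate_bulk(cfg)
lines <- simulate_cell_lines(cfg, planted_genes = bulk$truth)
sc <- simulate_ctc_singlecell(cfg, expressed_genes = bulk$truth)
annot <- simulate_annotations(rownames(bulk$matrix), cfg)
prot <- simulate_proteins(rownames(bulk$matrix), cfg, frac_antigenic = 0.5)

casc <- run_cascade(bulk$matrix, bulk$design, lines$matrix, sc$matrix,
                    annot, prot$records)
casc$stages

cells <- simulate_cohort_cells(cohort_sim_config(), seed = 1001)
res <- call_cohort(cells)
cohort_summary(res$subjects)
```
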