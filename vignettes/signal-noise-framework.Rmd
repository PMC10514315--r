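---
title: "A signal-to-noise framework for RNA-binding protein enrichment proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A signal-to-noise framework for RNA-binding protein enrichment proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpsignal)
```

## The measurement problem

RNA-centric capture methods (phase separation, silica, oligo-dT and related
protocols) recover UV-crosslinked ribonucleoprotein adducts from cells, and
LC-MS/MS quantifies the proteins in the captured fraction. The difficulty is
that every captured protein intensity is a mixture: part of it comes from
protein molecules covalently crosslinked to RNA (the *signal*, `S`) and part
from RNA-free molecules of the same protein that co-purify (the *noise*,
`N`). A protein can be strongly "UV-enriched" yet almost entirely RNA-free,
and an abundant free-protein background can mask genuine occupancy changes.
Distinguishing the two components per protein — not just per sample — is what
this package implements.

## The pooled-channel SILAC decomposition

The key experimental design is a pooled SILAC experiment: heavy-labeled,
UV-crosslinked (CL) cells are mixed with light-labeled, non-crosslinked (nCL)
cells *before* extraction. From that point on, every purification step acts
on the mixture, so RNA-free protein molecules from the two populations are
chemically indistinguishable and partition identically. The nCL channel can
contain no crosslinked protein; it measures free protein only. Under this
**equal noise-partitioning** assumption, the free protein `N` splits 1:1
between channels, so with per-protein sum peptide intensities
(SPI, averaged over replicates):

$$S = \mathrm{SPI}_{CL} - \mathrm{SPI}_{nCL}, \qquad
  N = 2\,\mathrm{SPI}_{nCL}, \qquad
  S/N = \frac{\mathrm{SPI}_{CL} - \mathrm{SPI}_{nCL}}{2\,\mathrm{SPI}_{nCL}},$$

and the observed total is `O = S + N`. The percent of a protein's captured
quantity that is RNA-bound follows directly:

$$\%\mathrm{RNA\text{-}bound} = \frac{S}{S+N} \times 100
  = 100\,\frac{CL/nCL - 1}{CL/nCL + 1}.$$

Two anchor points are worth memorizing: a CL/nCL ratio of 3 corresponds to
`S/N = 1` (50% RNA-bound), and `S/N = 3` corresponds to 75% RNA-bound.

```{r identities}
x <- intensity_table(
  cbind(matrix(rep(c(3, 7), 3), ncol = 3), matrix(1, 2, 3)),
  proteins = data.frame(protein_id = c("half_bound", "sn3"),
                        gene_name = NA, unique_peptides = 3L,
                        contaminant_flag = FALSE),
  samples = data.frame(
    sample_id = c(paste0("CL_", 1:3), paste0("nCL_", 1:3)),
    group = rep(c("CL", "nCL"), each = 3), replicate = rep(1:3, 2))
)
compute_signal_profiles(x)[, c("protein_id", "S", "N", "cl_ncl",
                               "log2_sn", "pct_bound")]
```

A *naive* alternative treats the whole nCL channel as the noise estimate
(`N = SPI_nCL`). Because it halves the noise attributed to the CL channel, it
strictly overestimates the bound fraction for every protein with `S > 0`;
`compute_signal_profiles(..., partition_model = "naive")` exposes it for
exactly that comparison, and the package's tests assert the direction of the
bias rather than its dataset-specific magnitude.

The decomposition fails gracefully at the edges. When
`SPI_CL <= SPI_nCL`, the point estimate of `S` is non-positive: the protein
behaves as pure background (`N = B`), and `pct_bound`, `%TP_S` and the
confidence score treat `S` as 0 while the signed value is retained for
reporting. Proteins detected only in the CL channel have no noise estimate at
all; they are flagged `cl_only`, given sentinel ratios (`Inf`), and handled
by pseudo-values in the enrichment test rather than by extrapolation.

## Abundance bookkeeping: %TP and its components

The Total Protein Approach expresses a protein's abundance as its share of
total intensity, `%TP = 100 * O / sum(O)` over the retained protein set.
Splitting each protein's `%TP` proportionally to its signal fraction gives
`%TP_S` and `%TP_N`; summed over all proteins these report what fraction of
the captured material is RNA-bound at all — the single most informative
number about a method's specificity. Summing `S` within annotation categories
(e.g. GO-annotated RBPs vs everything else) gives `%TP_(S)`, each category's
share of total RNA-bound intensity; `summarize_categories()` computes both.
Denominators are formed after contaminant curation and detection filtering,
so `%TP` always sums to 100 on the analyzed set.

## Preprocessing rules and their order

`preprocess_silac()` applies, in this order:

1. **Contaminant curation** — keratins, BSA, porcine trypsin, yeast alcohol
   dehydrogenase, casein spike-ins (`contaminant_patterns()`), plus any rows
   flagged at read time.
2. **Detection filter** — SILAC mode requires detection in *all* CL
   replicates (one missing CL value excludes the protein); comparative mode
   requires full detection in both condition groups and at least two unique
   peptides. Proteins with no nCL evidence are kept and flagged `cl_only`.
3. **Mean normalization** — every sample is scaled to the mean of per-sample
   totals, conserving the grand total. In SILAC designs one LC-MS/MS run
   carries both channels, so normalization operates per replicate
   (`by = "replicate"`), scaling CL and nCL columns of a run jointly and
   preserving within-run CL/nCL ratios. Normalizing the channels separately
   would equalize their totals and erase the enrichment the experiment is
   designed to measure. Label-free comparative designs normalize per column.
4. **nCL zero replacement** — remaining zero/missing nCL cells are replaced
   by the protein's own non-zero nCL mean. Imputation is deliberately
   per-protein (not dataset-wide), which makes imputed replicate ratios
   identical — one reason the enrichment test flags zero-variance proteins.

Filtering precedes normalization so that excluded rows never distort totals.
Every step appends to an audit log; `replay_log()` re-applies a recorded
sequence to the raw table and reproduces the processed table bit-identically,
and `preprocess_report()` summarizes the funnel.

## Calling UV-enrichment

A protein is UV-enriched* when its CL recovery significantly exceeds nCL.
The package's default test (`test_uv_enrichment(form = "welch")`) is an
unpaired, upper-tailed, unequal-variance t-test of the log2 CL replicate
values against the log2 nCL replicate values, with Benjamini–Hochberg control
at 5% FDR. The reported effect size is the conventional mean log2(CL/nCL)
ratio formed against the protein's nCL mean.

Two alternatives are provided because the literature's description of this
test is ambiguous, and the choice matters:

* `form = "ratio"` tests the per-replicate ratios
  `log2(CL_i / mean(nCL))` against zero with a one-sample t-test. All three
  ratios share the same nCL mean, so their spread reflects only CL
  variability while the mean ratio also carries the nCL sampling error: the
  variance of the mean is understated by roughly a factor of two, and the
  test is anti-conservative (realized size near 0.08 at a nominal 0.05 in the
  package's null simulations). It is retained for sensitivity analysis, not
  recommended.
* `form = "pooled"` is the equal-variance two-sample form; with equal
  replicate numbers it shares the Welch statistic but uses the full
  `n1 + n2 - 2` degrees of freedom.

At three replicates per channel no small-sample t-test is perfectly sized:
Welch's Satterthwaite degrees of freedom make it slightly conservative (true
size ≈ 0.04 at nominal 0.05), while the pooled form is exact only if the
equal-variance assumption holds. The default favors the form whose standard
error is honest about both channels' noise.

CL-only proteins bypass testing entirely: they are scored UV-enriched* with
the plotting pseudo-values `log2(CL/nCL) = 10`, `-log10(p) = 10`, and are
excluded from the BH multiplicity. Zero-variance proteins (possible after
imputation) get `p = 0` or `1` by the sign of the effect, with a flag.

## Ranking candidates: the RBP-confidence score

Enrichment significance alone saturates: with a clean method, even trace
non-specific crosslinking of an abundant free protein is statistically
detectable. To order candidates by evidence of genuine RNA binding, the
confidence score multiplies enrichment efficiency by abundance:

$$\mathrm{RCS} = \log_2(S/N) \times \log_{10}(\%\mathrm{TP}).$$

The raw product is sign-ambiguous when both factors are negative, so ranking
(`compute_rcs()`) is two-tiered: proteins with `S/N >= 1` are ordered by RCS
descending; proteins with `S/N < 1` (or `S <= 0`) rank strictly below them,
ordered by `log2(S/N)`. CL-only proteins head the list ordered by abundance,
since their enrichment is unbounded but unquantified. Ties break by `%TP`
and then accession, making ranks a deterministic permutation independent of
input order. `rank_bin_analysis()` summarizes annotated-RBP density, RCS,
`%TP`, S/N, peptide evidence and sensitivity across rank bins of 100.

## Sensitivity: what change in S is detectable?

Because only `O = S + N` is observed, a fold-change in RNA-bound quantity is
diluted by the free fraction before it reaches the measurement. With
replicate standard deviation of `log2(O)` and the one-sided 95% Student
quantile at `n - 1` degrees of freedom,

$$\mathrm{detectable}\ \Delta\log_2(O) = t_{0.95} \cdot \mathrm{SEM}(\log_2 O), \qquad
  \mathrm{detectable}\ \Delta\log_2(S) =
  \log_2\!\left(2^{\Delta\log_2(O)} - N/O\right) - \log_2(S/O).$$

As `N/O -> 0` the two coincide; as `S/N` falls, the detectable change in `S`
grows without bound. Applying the returned fold-change to `S` moves
`log2(O)` by exactly the detectable amount (a round-trip identity the tests
check to 1e-9). One boundary case is worth noting: any *increase* in `O` is
attainable by increasing `S`, since `2^d > 1 >= N/O`; only a requested
decrease below `log2(N/O)` is impossible (removing all signal still leaves
`N`), and `detectable_delta_S()` then returns `-Inf` with a warning.

## S/N-gated differential occupancy

Comparative experiments (e.g. a translation-initiation inhibitor vs vehicle)
quantify input and clRNP fractions per condition by label-free LC-MS/MS.
`test_occupancy_change()` uses the pooled-variance two-tailed t-test on log2
SPI and runs BH twice: over all tested proteins, and over only those whose
companion-SILAC `S/N` exceeds 3 (strict inequality; 75% RNA-bound). The gate
serves two purposes: proteins dominated by free protein cannot show a clean
occupancy signal in the first place, and shrinking the multiplicity raises
power for the proteins that can. Hits are classed `purple` (both passes),
`gold` (gated only), `teal` (ungated only). `compare_fractions()` joins the
two fractions and separates occupancy-specific changes (clRNP moves, input
flat) from abundance-driven ones (both move).

The S/N gate comes from a *separate* SILAC experiment joined by primary
accession; proteins without a profile are ungateable and simply excluded
from the gated pass. With three replicates per condition the pooled test has
four degrees of freedom, so only sub-unit log2 fold-changes at low replicate
CV — or larger shifts — reach BH significance; the package's property tests
assert the direction of the power gain from gating and the FDR control of
both passes, not a fixed sensitivity, because at 20% replicate CV and a
one-unit log2 shift the absolute power of a df = 4 test is intrinsically low.

## The synthetic-data generator

`generate_silac()` and `generate_comparative()` draw datasets with known
truth so every stage is testable without external downloads. Per protein:
captured intensity `A` (lognormal, `meanlog = log(1e7)`, `sdlog = 1.5`,
spanning the few orders of magnitude typical of MS protein intensities) and
bound fraction `f` (Beta(2.5, 1.5) for the 30% of proteins that are RBPs —
a high-specificity, LEAP-like capture; 0 otherwise), giving `S = A f` and
`N = A (1 - f)`. Non-RBP free-protein recovery is scaled by
`background_free_protein` (default 0.1). Expected channels are
`E[CL] = S + N/2` and `E[nCL] = N/2`; a `noise_partition` knob breaks the
1:1 split to study how the naive estimator misbehaves under asymmetric
partitioning. Replicates get mean-preserving multiplicative lognormal noise
at 20% CV (3 replicates), and a hard detection floor (5e4 intensity units)
records low cells as missing — deliberately deterministic rather than
probabilistic dropout, so the truth stays auditable. Contaminant spike-ins
are appended under keratin-style accessions.

What the generator does *not* emulate: peptide-level sampling, ratio
compression, retention-time artifacts, shared-peptide protein inference, or
intensity-dependent variance. Passing recovery tests on synthetic data
therefore validates the estimators' algebra and calibration under the stated
noise model, not robustness to every failure mode of real spectra.

Study-scale choices used by the test-suite and acceptance checks: parameter
recovery runs at 2,000 proteins (median absolute error of the estimated
percent bound is well under 10 points at 20% CV for proteins at least half
bound, and exact to 1e-9 without noise); enrichment-test calibration uses
20,000 null proteins; FDR checks use 200 simulated comparative datasets of
300 proteins.

## Numerical and design choices

* Missing vs zero: the MaxQuant dialect maps intensity 0 to missing at read
  time (MaxQuant writes 0 for "not detected"); the generic dialect keeps
  literal zeros and uses `NA` for missing, so synthetic fixtures can be
  exact.
* Duplicate primary accessions after majority-ID extraction raise an error
  rather than being silently summed or maxed — there is no principled merge
  rule without peptide-level evidence.
* `%TP` denominators use the post-filter protein set; replicate means (not
  per-replicate values) feed the headline decomposition, with a
  `per_replicate` option for diagnostics.
* Ranking, ties, and ordering are fully deterministic; rerunning a recorded
  pipeline manifest reproduces every output byte-for-byte.
* Two-replicate external datasets can be augmented with an averaged
  pseudo-replicate (`add_pseudo_replicate()`), and replicate-free multi-
  sample designs collapsed with `aggregate_samples()`; both are explicit,
  logged transforms, never defaults.

## Limitations

The equal-partitioning assumption holds only for the pooled-SILAC design it
models; applying the decomposition to separately processed CL and nCL
samples makes `N` a lower bound at best. The S/N gate inherits whatever
biases the companion SILAC run has, and accession-based joins across
experiments lose proteins whose protein-group inference differs. Estimates
for proteins near the detection floor are noisy and censored; `cl_only`
pseudo-values are a reporting convention, not a measurement. None of the
statistics here moderate variance across proteins; with three replicates an
empirical-Bayes approach would gain power, but plain t-tests keep the
framework transparent and match how such experiments are usually analyzed.
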