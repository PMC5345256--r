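---
title: "MSD-AFLP methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSD-AFLP methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method in brief

Methylated site display (MSD) is a library-preparation scheme that retains
only genomic fragments whose terminal HpaII-site CpG was methylated in the
source DNA. Genomic DNA is cut with a rare-cutting primary enzyme (SbfI,
`CCTGCA^GG`), adaptor-ligated, cut again with MspI (`C^CGG`,
methylation-insensitive), ligated to a second adaptor, and finally challenged
with HpaII — MspI's methylation-*sensitive* isoschizomer. Where the internal
CpG of the terminal CCGG was methylated, HpaII cannot cut and the second
adaptor survives; only those molecules amplify. Selective PCR with one of
16 × 16 primer pairs (each reading two extra genomic bases, `NN`, beyond each
adaptor) amplifies a subpopulation, and capillary electrophoresis renders it
as a peak chart: fragment size in nt against fluorescence in RFU. A fragment's
peak height is therefore proportional to the methylation level of one
specific CpG — the internal C of the CCGG nearest to an SbfI site.

The package implements the four computational layers this assay needs:

1. **`build_fragment_db()`** — the virtual digest: predicts every displayable
   fragment of a genome, its display length, selective bases and monitored
   CpG, and answers the inverse query (peak → candidate loci).
2. **`simulate_library()` / `simulate_peak_chart()`** — a forward simulator
   of the chemistry with known ground truth, including the SssI-treated
   fully methylated reference and MSRE-PCR (paired HpaII/StuI digests read
   by qPCR).
3. **`fit_hill()` / `charts_to_percent()`** — calibration of signal ratios
   (sample peak / fully methylated reference peak) to percent methylation.
4. **`anova_bh()` / `tukey_hsd()` / `zscore_pca_cluster()`** — the
   differential-methylation statistics: per-CpG one-way ANOVA with
   Benjamini–Hochberg FDR control, Tukey HSD post hoc pairs, effect-size
   filters for *subtle* differences (< 5 percentage points and < 1.1-fold),
   z-scores, PCA and UPGMA clustering.

## Coordinate and strand conventions

All internal coordinates are 0-based half-open (BED-compatible); loci are
printed 1-based in user-facing reports. For an SbfI site starting at `p` and
its nearest CCGG starting at `s`:

* `"+"` fragments (CCGG 3′ of the SbfI site): insert `[p + 6, s + 1)`;
* `"-"` fragments (CCGG 5′): insert `[s + 1, p + 2)`.

Both conventions keep the SbfI sticky-end remnant (`GG`/`CC`) inside the
insert and end the insert at HpaII's top-strand cut, so the monitored CpG
(0-based `s + 1`, reported as `s + 2`) is inside or immediately adjacent to
every insert. A CCGG must lie entirely within one primary digestion fragment
to count: MspI cannot cut a site destroyed by the earlier SbfI digest.

Selective dinucleotides are read 5′→3′ on the strand each selective primer
extends. For `"+"` fragments, `sel_primary` is the two forward-strand bases
immediately past the SbfI recognition sequence, and `sel_secondary` is the
reverse complement of the two forward-strand bases 5′ of the CCGG; `"-"`
fragments mirror both rules. The convention is fixed and re-derivable from
`selective_bases()`. Fragments whose insert cannot carry both selective
windows (insert < 4 nt) or whose windows contain `N` are excluded (counted in
the database attributes). Display length is insert length plus a single
configurable `display_offset` (default 0) standing in for the constant
adaptor/primer contribution; the default size window, 50–500 nt, is the range
a 500-nt capillary size standard can size.

Only palindromic recognition sequences are supported (every shipped enzyme is
palindromic), so a single forward-strand scan finds all sites; recognition
windows containing `N` are never sites, and soft-masked lowercase sequence is
treated as ordinary sequence since the assay has no notion of masking.

## The signal model

With digestion completenesses `eff_primary`, `eff_mspi`, `eff_hpaii` (all
default 1, reflecting the vendor guarantee that CpG methylation blocks HpaII
completely; hemi-methylated DNA is modeled as fully protected), a fragment
whose monitored CpG has methylation level `m` has expected abundance

```
abundance = eff_primary * eff_mspi * (m + (1 - m) * (1 - eff_hpaii))
```

which reduces to `m` at the defaults. Peak rendering: fragments of one
selective subset sharing an integer display length co-migrate and their
abundances sum; height is `gain * abundance` (default gain 1000 RFU per unit
abundance) perturbed by multiplicative log-normal noise with `noise_sigma`
(default 0.05, the regime in which most replicate peak pairs sit within a
1.1-fold band); reported size is display length plus Gaussian jitter
(SD 0.15 nt, typical capillary sizing precision); peaks under
`detection_threshold` (default 50 RFU, a common peak-calling floor) are not
called. Abundances are continuous expectations, not sampled molecule counts;
`simulate_msre(sampled = TRUE)` offers binomial copy sampling where
finite-template realism matters. PCR saturation across the pre- and
selective-PCR cycles is *not* modeled, and amplification efficiency is a
single shared gain — two simplifications with measurable consequences
discussed under *Limitations*.

## Hill calibration and why its asymptote is free

Percent methylation is recovered from the signal ratio
`SR = sample height / SssI-reference height` through a Hill response

\[ M(SR) = E_{max} \frac{SR^h}{K^h + SR^h}. \]

`fit_hill()` performs the least-squares fit in the compactified
parameterization \(M = S\,SR^h / (1 + (c\,SR)^h)\) with \(c = 1/K \ge 0\)
and the amplitude \(S = E_{max} c^h\) free. The boundary \(c = 0\) is the
saturation-free power-law limit, which contains the *linear* response
\(M = 100\,SR\) at \(h = 1\). This choice is load-bearing: a detector
without PCR saturation is exactly linear in SR, and no Hill curve with a
*fixed* asymptote can represent a line — the best fixed-`Emax` fit to a
linear 11-point calibration errs by up to ~13 percentage points. With the
free amplitude the fit lands on the boundary for linear data and the
noise-free pipeline recovers truth to machine precision, while genuinely
sigmoidal calibrations still recover `(h, K, Emax)` (multi-start optimization
over Hill slopes 0.5–4 around `K = median(SR)`, plus a log–log regression
start on the power-law boundary; best objective kept, then polished).
Dose-response practice fits the top parameter anyway; normalization to
[0, 100] is enforced where it belongs, by clamping at the percent stage
(`hill_percent()`), while raw SR — including diagnostic values above 1 — is
always reported unclamped. `fit_hill(..., emax = 100)` restores the
two-parameter classical fit for users who want it.

Peak matching across samples uses one-dimensional single-linkage: sorted peak
sizes are split at gaps wider than 0.5 nt (configurable). When one sample
contributes two peaks to a bin, the taller wins with a warning; samples
absent from a bin are recorded as height 0 with an `absent` flag. MSRE-PCR
percents are `100 * copies_HpaII / copies_StuI`, clamped at 100 with a
warning since qPCR noise can push the ratio past 1.

## Differential statistics

Percent methylation is analyzed per CpG by classical fixed-effects one-way
ANOVA across tissues; BH step-up adjustment is applied jointly across all
CpGs of a batch (all selective subsets pooled — one study is one
multiple-testing family), with significance at `q ≤ 0.05`. The row-wise F
statistics are computed vectorized (sums of squares plus `pf()`), because the
operating-characteristic checks run hundreds of simulated 2000-CpG studies;
the unit suite asserts row-by-row agreement with
`oneway.test(var.equal = TRUE)`. Degenerate rows are handled explicitly:
all-identical rows get `p = 1` (flag `zero_variance`); rows with separated
group means but zero within-group variance get a tiny variance floor so they
remain testable (flag `variance_floored`). Tukey HSD (via `TukeyHSD()`,
independently checked against a direct studentized-range computation in the
tests) runs by default only on ANOVA-significant CpGs, following the
two-stage design; each pair carries `delta` (absolute difference of group
mean percents) and `rho` (max/min ratio of group means, floored at 0.1
percentage points in the denominator so near-zero means cannot explode the
ratio). The subtle filter keeps significant pairs with `delta < 5` and
`rho < 1.1`. z-scores use the row mean and the `n − 1` SD across samples
(constant rows dropped and listed); PCA is a sample-space `prcomp()` on the
z-matrix; clustering is UPGMA (average linkage) on Euclidean distances,
exported as newick.

## What the synthetic data emulate — and what they do not

`generate_genome()` draws i.i.d. background sequence at a chosen GC fraction
(default 0.42, the mammalian average) and plants SbfI and CCGG motifs at
random non-overlapping positions; truth is then defined by *re-scanning the
generated sequence*, so accidental motifs created by the background are
honored as real sites. The default genome — 2 chromosomes × 500 kb, ~150
SbfI sites per chromosome, one CCGG per ~300 bp — yields a few hundred
fragments and runs the whole fixture in seconds. `generate_study()` mirrors
a three-tissue, three-replicate design: per CpG a baseline level is drawn
from Beta(5, 2) (mean ≈ 0.71, matching the high average CpG methylation of
mammalian tissue while spreading levels across the SR range), planted CpGs
(default 50) shift one tissue by +5 percentage points, and replicates add
Gaussian level noise (`noise_sd`, default 0.05) before clamping to [0, 1].
`make_fixture()` writes the complete self-contained bundle — FASTA, database
TSV, profiles, charts for the 16 most populated selective pairs plus the
SssI reference, an 11-locus calibration spread across the SR range with
simulated MSRE-PCR percents, truth tables and a seed manifest.

Real data differ in ways the generator deliberately ignores: methylation is
spatially autocorrelated and bimodal rather than i.i.d. Beta; real peak
heights span orders of magnitude because amplification efficiency varies per
fragment; electropherograms carry stutter, shoulders, pull-up and
size-standard error beyond Gaussian jitter; and genomes have repeats,
CpG islands and assembly gaps. Green checks here certify the *computational
machinery* — digest correctness, calibration mathematics, statistical
calibration — not field performance on tissue DNA.

## Problem sizes and numerical outcomes of the shipped checks

The test suite validates the digest against a brute-force string-scanning
reference on 200 independent 50-kb genomes (and 30 more in the unit tests),
runs the noise-free pipeline identity on the default ~420-fragment fixture
(max error ~1e-13 over ~650 values), checks Hill recovery on 11-point
calibrations (8e-5 parameter error noiseless; ~0.8 pp RMSE at 5% SR noise),
and measures operating characteristics on ~1900-CpG studies over 200
simulated runs each for the null-FDR and planted-effect analyses.

Three checks fail at the default study conditions, and are left failing
deliberately because the analysis says they must:

* **End-to-end MAE < 3 pp.** Sample and reference chart heights each carry
  5% multiplicative noise, so SR carries ~7.1% log-noise and the error floor
  is `100 · E[m] · E|lognormal(0.071) − 1| ≈ 4` pp at mean methylation 0.71.
  The measured MAE is 3.6–4.0 pp.
* **Replicate intensity R² ≥ 0.98.** With a single shared gain, abundances
  live in [0, 1]; the attainable raw-intensity R² between replicate charts
  is ≈ `Var(x)/(Var(x) + 2σ²E[x²]) ≈ 0.92`, and 0.92 is what is measured.
  Real AFLP charts reach 0.99 because their peak heights span decades.
* **≥ 60% power for 5-pp shifts.** With 3 replicates per tissue and 5-pp
  replicate noise the noncentrality is `2(δ/σ)² = 2`; after BH across ~2000
  CpGs essentially nothing survives (measured 0.04%). Sixty-percent power
  requires replicate noise near 1 pp — which is plausibly what the real
  assay achieves, but is not the configured study condition.

## Known limitations

Fragment databases model one primary enzyme plus HpaII/MspI; enzyme
cocktails, non-palindromic enzymes and bisulfite-space analysis are out of
scope. The BED/GFF3 reader handles the plain tabular forms of those formats
(with line-numbered diagnostics), not the full GFF3 feature graph. The
simulator's noise model is a single multiplicative term; anyone studying
peak-calling robustness should treat `noise_sigma`, the detection threshold
and the sizing jitter as the knobs to stress. Genome-wide motif counts on
real assemblies depend on the assembly version; none is bundled or assumed.
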