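---
title: "Strand-resolved CpG methylation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-resolved CpG methylation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandmeth)
```

## The scientific problem

A CpG dinucleotide is palindromic: each site carries a cytosine on both
the sense and the antisense strand, and the two can be methylated
asymmetrically. Because bisulfite conversion acts independently on each
strand, a bisulfite assay interrogates only the strand its primers were
designed against. Promoter methylation assays that target different
strands of the same locus can therefore disagree systematically — a real
concern for a tumour marker such as methylated promoter DNA in
hepatocellular carcinoma (HCC), where adult liver tissue carries
antisense-strand background methylation that is absent from the sense
strand. This package implements the complete strand-resolved analysis:
in-silico bisulfite strand modelling, chromatogram-based per-site
methylation classification, clone-level density analysis, quantitative
methylation-specific PCR (MSP), and biomarker evaluation, together with a
synthetic-cohort generator that reproduces the statistical structure of
such a study so the full pipeline is testable without external data.

## Coordinate and strand conventions

CpG sites are enumerated on the sense strand 5'→3' and numbered
consecutively from 1; antisense-strand results are always reported
against the same sense-strand site numbers, so one canonical site map
serves both strands. Conversion of the antisense strand operates on the
reverse complement of the sense sequence. All coordinates are 1-based
inclusive.

Sequencing reads are modelled as visiting sites in ascending site order
on either strand. A homopolymer-T run of 16 or more bases in a converted
template (the toy region places one between sites 20 and 21, arising from
a poly-A stretch on the sense strand) truncates the read: every site
downstream of the run start is flagged unreadable. This is why the
antisense analysis range defaults to sites 1–20 while the site map holds
30 sites.

## The chromatogram reference index

Direct Sanger sequencing of a bisulfite PCR product shows, at each CpG,
a C peak (methylated molecules) and a T peak (unmethylated molecules).
Each site is classified by literal peak comparison:

| category | rule | calibrated methylated fraction |
|---|---|---|
| `T_ONLY` | only T detected | 0 |
| `C_LE_T` | both detected, C ≤ T (ties here) | (0, 0.10) |
| `C_GT_T` | both detected, C > T | [0.10, 0.25) |
| `C_ONLY` | only C detected | [0.25, 1] |
| `MISSING` | neither detected / unreadable | — |

"Detected" means the channel rises above a noise floor, by default 5% of
the larger channel at that position (instrument detection limits are not
published constants; the default is a package choice, configurable in
`calibration_index()`).

The fraction bands attached to the categories come from calibration
against reconstituted standards — defined mixtures of fully methylated
and fully unmethylated converted DNA at 0/10/25/50/100%. A key empirical
fact from that calibration is that the chromatogram response is *not*
proportional to the methylated fraction: a 25% mixture already yields an
essentially pure C peak, and a 10% mixture yields a C peak at or above
the T peak. This reflects the well-known amplification bias of bisulfite
PCR toward the methylated (C-retaining) template. The synthetic trace
generator therefore maps the population methylated fraction *f* to the C
channel's signal share through a monotone calibration response anchored
at (0, 0), (0.10, 0.50), (0.25, 0.96) and (1, 1)
(`chromatogram_response()`). With this response and the default noise
floor, the peak-comparison classifier recovers the calibrated bands
exactly at the standard fractions; the recovery is approximate only in a
transition sliver (width < 0.004) just below the 0.25 band edge, where
the T channel dips under the noise floor slightly early.

Conversion QC: incomplete bisulfite conversion leaves residual C at
non-CpG cytosines and would mimic methylation, so a sample is analyzed
only if more than 95% of its non-CpG reference cytosines read as
converted. The gate is strict (`> 0.95`), and gated samples are dropped,
not corrected. At a true failure rate of exactly 5% the observed rate
straddles the threshold binomially, so the gate's guarantee is stated on
the *realized* failure fraction: any sample whose realized non-CpG
failure fraction is ≥ 5% is excluded.

## Clone analysis

Cloning the bisulfite PCR product isolates single molecules, so each
clone reads either "C only" or "T only" at every site. Per-site percent
methylation is the methylated fraction of readable clones (unreadable
entries leave both numerator and denominator; a site with no readable
clone is reported absent, not 0). Group-level density contrasts pool
methylated/unmethylated site-calls over all clones and samples of a
group — the group comparison is over totals, not per site — and use a
two-sided Pearson χ² test without continuity correction. Seven to
nineteen clones per sample is the sampled range in the generator.

## Quantitative MSP model

The quantification cycle is linear in log10 input copies,
`Cq = intercept + slope · log10(copies)`, with amplification efficiency
`E = 10^(-1/slope)` (a perfect doubling assay has slope −3.3219
cycles/decade). Curves are least-squares fits to ten-fold dilution
series. Copy estimates invert the curve; the limit of detection is 6
copies per assay, and sub-LOD or not-detected reactions carry 0 copies
for marker logic. Input is first measured with a methylation-neutral
BS-actin assay and marker copies are rescaled to the nominal 150-copy
input; a conversion factor of 6 pg DNA per cell (2 locus copies per
diploid cell, configurable to haploid counting) converts mass to copies.

Reactions run in duplicate. The mean of the two normalized values is the
quantitative marker value; positivity is *any* detectable methylation per
nominal input, read as the either-replicate rule (one detected replicate
suffices). How a detected/not-detected disagreement should be resolved is
not prescribed by the assay definition; the either-replicate reading
follows the "any detectable methylation" cutoff and is configurable
(`average_duplicates(detect_rule = "both")`). Not-detected replicates
contribute 0 to the mean, which keeps averages well defined at the cost
of a slight downward bias for discordant pairs.

Near the LOD the dominant stochasticity is which template molecules make
it into the reaction: the generator draws template counts
Poisson(expected copies), yields not-detected at zero templates, and adds
Gaussian cycle noise (SD 0.15 cycles) otherwise.

## Biomarker evaluation

Positivity rules: BSP-positive means methylation detected (any category
with visible C, configurable) at ≥ 50% of readable sites; MSP-positive
means detected at the LOD cutoff. Sensitivity is computed over HCC;
specificity pools adjacent non-tumor, normal, hepatitis and cirrhosis
controls. ROC curves are empirical with tie-aware steps; the area equals
the Mann–Whitney probability (verified against an all-pairs oracle at
1e-12), and paired curves are compared with the DeLong test. The
combined-marker analysis cross-tabulates marker positivity against serum
AFP ≥ 20 ng/mL among cases with AFP data. Clinicopathological contrasts
use Kruskal–Wallis on the quantitative sense marker (stages 2–4 pooled,
grades 2–3 pooled, because upper strata are small), Spearman correlation
for marker versus AFP, Student t for age and Fisher's exact test for sex.
No multiplicity correction is applied, matching the single-comparison
reporting style of the source analyses.

## The synthetic cohort generator

`default_generator_config()` encodes the study conditions: cohort sizes
58/58/41/39/6 (HCC, adjacent, cirrhosis, hepatitis, normal liver) plus
12 nonhepatic, 1 fetal and 3 murine negative controls; 30 CpG sites with
sites 1–20 analyzable; and the default liver biology — antisense
background methylation in all adult liver groups, sense methylation
predominantly in HCC, nothing in nonliver/fetal/mouse tissue.

One latent truth drives all assays: per sample and strand, the sample is
methylated with a group-specific probability and, if so, carries a
per-site methylated fraction drawn uniformly from a group-specific range
(uniform across sites for simplicity; the per-site interface accepts
gradients). The same fraction produces the chromatogram signal, the clone
calls, and the expected MSP template count (fraction × actual input
copies). Group defaults (probability; fraction range):

| group | sense | antisense |
|---|---|---|
| HCC | 0.70; 0.20–0.80 | 0.75; 0.25–0.85 |
| adjacent non-tumor | 0.15; 0.04–0.20 | 0.60; 0.05–0.30 |
| normal liver | 0 | 0.83; 0.05–0.25 |
| hepatitis | 0.10; 0.04–0.15 | 0.75; 0.05–0.30 |
| cirrhosis | 0.17; 0.20–0.60 | 0.50; 0.05–0.30 |
| nonliver / fetal / mouse | 0 | 0 |

No quantitative per-site fractions are published for the benign-liver
antisense background, so these are order-of-magnitude choices: the
positivity probabilities mirror the published per-group positive counts
(e.g. 5/6 normal livers antisense-positive, roughly two-thirds of HCC
MSP-positive per strand), and the low-level sense ranges in benign groups
reproduce the minority of sense-MSP false positives that a specificity in
the mid-80s implies. Cirrhosis is modelled with independent per-strand
probabilities approximating its published mixture (some antisense-biased,
one symmetric, several unmethylated). AFP is log-normal per group with
the HCC parameters (meanlog `log(20) − 0.176·2`, sdlog 2) chosen so about
43% of HCC exceed 20 ng/mL; benign groups sit far below the cutoff.
Demographics mirror the published cohort table.

All randomness flows from the single config seed through one sequential
stream seeded once at the start of `generate_cohort()`; identical
configs produce byte-identical written cohorts.

What the generator does *not* emulate: sequence-dependent PCR bias,
bisulfite degradation, chimeric clones, between-site correlation of
methylation along the island, assay cross-reactivity, or measurement
drift between runs. Passing tests therefore demonstrate that the
pipeline's logic and statistics behave correctly under the assumed data
model, not that the assays would achieve these operating characteristics
on real tissue.

## Numerical choices and degenerate inputs

* Ties in peak comparison go to `C_LE_T`, matching the index's grouping
  of C = T with C < T.
* The noise floor is relative (5% of the larger channel) with an optional
  absolute floor; at (0, 0) both channels are undetected and the site is
  `MISSING`.
* The QC threshold, BSP positivity threshold, LOD, nominal input and AFP
  cutoff are all carried in `run_config()` with the stated defaults.
* The positivity boundary is inclusive (≥ 50% of sites; AFP ≥ 20 ng/mL);
  copy estimates exactly at the LOD count as detected.
* Zero-margin contingency tables, single-class label vectors, all-missing
  call vectors and empty cohorts raise errors or `NA`-with-warning rather
  than silently degrading.
* Standard-curve fits require ≥ 3 distinct dilution points; Cq values
  outside the calibrated range extrapolate with a warning.
* `N` bases are excluded from CpG enumeration (with a warning) and pass
  through conversion unchanged.

## Problem sizes

The shipped example cohort keeps chromatograms for six samples so the
repository stays lightweight; the analysis scripts regenerate a
full-sized cohort (218 samples) in seconds. The replicate study behind
the strand-specificity property uses 50 seeded full-size cohorts with the
MSP arm only, and the distributional checks use 10,000 clones and
10,000 qPCR draws, sizes at which binomial and Poisson intervals are
tight enough to be discriminating while the whole suite runs in about a
minute.

## Known limitations

* The chromatogram response curve is anchored at the published
  calibration points but its shape between anchors is an interpolation;
  classification near band edges inherits that uncertainty.
* The MSP assays are represented by their targeted site ranges only
  (sense sites 7–17, antisense 11–18); amplification is not
  sequence-simulated, so primer-mismatch effects are out of scope.
* Clone counts, not clone identity, are modelled; within-clone long-range
  haplotype structure is not represented.
* The per-strand truth is independent between strands within a sample,
  which understates the coupling expected for symmetric methylation
  spreading.
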