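---
title: "Models and methods for quantifying random monoallelic expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantifying random monoallelic expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armae)
```

## The biological setting

Autosomal random monoallelic expression (aRMAE) is the probabilistic,
mitotically persistent silencing of one allele of an autosomal gene. In a
*C. elegans* strain heterozygous for two differently coloured fluorescent
reporter alleles at one locus, every cell reports the expression of each
allele at the protein level. The 20 cells of the adult intestine descend
clonally from the single E blastomere of the 8-cell embryo through a fixed
division series (E → E2 → E4 → E8 → E16, with four E16 cells dividing once
more), arranged in nine anteroposterior rings (ring I holds 4 cells, rings
II–IX hold 2). Because silencing, once initiated, is propagated through
mitosis, the adult pattern of monoallelic cells is a fossil record of when
in the lineage the decision was taken: a whole-intestine monoallelic animal
points to an event in E itself, a half-intestine patch to one of the two E2
daughters, a single cell to the final divisions.

`armae` packages the complete quantitative chain for this design: a
generative simulator, a synthetic image-cytometry stage, the noise and
allele-bias statistics, state calling with parsimony-based lineage
inference, and the rank-based test battery.

## The generative model

`simulate_silencing()` walks the lineage from the root. For each allele
independently, a node whose parent still has that allele active silences it
with the stage-specific probability `p_init[stage + 1]` (stage 0 = E); a
silenced label is transmitted to each daughter with probability
`maintenance` (default 1, i.e. fully clonal — the "persistent but not
heritable" regime; values below 1 support robustness studies). With
initiation restricted to the E stage at per-allele probability $q$ and full
maintenance, the probability that an animal's whole intestine is
monoallelic is exactly $2q(1-q)$ (one allele silenced at E, the other not),
which the test suite verifies by Monte Carlo.

`simulate_animal()` generates expression. For a sampled cell $c$ and allele
$a$:

$$\mathrm{raw}_{c,a} = \mu_a \cdot E_c \cdot I_{c,a} \cdot A_{c,a} + b$$

with $E_c \sim \mathrm{lognormal}(0, \sigma_{\mathrm{ext}})$ shared by both
alleles of the cell (cell size, ribosome content, imaging depth),
$I_{c,a} \sim \mathrm{lognormal}(0, \sigma_{\mathrm{int}})$ independent per
allele, $A = 1$ for an active allele and $A = s$ (the silenced residual,
default 0.02) otherwise, and $b$ an additive background (default 0).
Lognormal factors keep intensities strictly positive, which is how
fluorescence data behave; one intensity per cell per channel is the
appropriate resolution because nuclear signal of a freely diffusing
monomeric fluorophore tracks the cytoplasmic content almost perfectly.

`simulate_cohort()` adds the experimental design: `n_experiments`
independent experiments (three in the standard design), each with its own
multiplicative per-channel scale factor
($\mathrm{lognormal}(0, \mathtt{batch\_sd})$, default 0.15) standing in for
acquisition settings, and `n_animals` animals of `n_cells` measured cells
(default 7, the yield of a one-sided confocal field covering intestinal
rings I–IV; 3 × 10 × 7 = 210 cells per group). Each simulated group is its
own acquisition series with its own batch factors, so when groups are
combined, normalization is applied per series before pooling. The RNG seed
is recorded on the output, and identical seeds give identical tables.

### Genotype presets and their calibration

The three `genotype_preset()` parameter sets are the package's study
conditions; they were fixed once, against published summary values for this
assay, and are not tuned per analysis:

* **wild-type** — rare initiation (`p_init = c(0.001, 0, 0, 5e-4, 5e-4,
  5e-4)`), placed mostly at late divisions so that stray control silencing
  shows up as single cells, not clones: early events at appreciable rates
  would produce whole-intestine monoallelic control animals, which control
  data do not show. $\sigma_{\mathrm{int}} = 0.080$ reproduces a control
  median intrinsic noise near 0.0023, and $\sigma_{\mathrm{ext}} = 0.38$ a
  control allele $R^2$ near 0.92–0.93 (a single monoallelic cell is a large
  leverage point for $R^2$ at $n \approx 210$, which is why the control
  initiation rate matters).
* **met-2-null-like** — `p_init = c(0.24, 0.12, 0.03, 0, 0, 0)`,
  $\sigma_{\mathrm{ext}} = 0.60$, $\sigma_{\mathrm{int}} = 0.30$.
  Calibration targets, in priority order: about a quarter of animals called
  almost/entirely monoallelic, about half with at least 50% of cells in the
  same monoallelic state, and a median intrinsic noise near 0.19. The
  E-stage probability is larger than the idealized $2q(1-q) = 0.25$ root
  ($q = 0.146$) because with both alleles at risk, later events and 7-cell
  sampling, some would-be fully monoallelic animals acquire dual-silenced
  (dim, biallelic-looking) cells. The raised noise scales encode the
  mutant's pervasive continuum allele decoupling; clean binary silencing
  alone cannot produce a *median* cell with strong bias while only half the
  animals are coherent. One printed mutant quantity is knowingly not
  matched: a group $R^2$ as high as ~0.27 together with this much
  intrinsic decoupling is not attainable under independent-allele lognormal
  noise, and the simulated mutant $R^2$ comes out lower (~0.1–0.2).
* **set-25-mutant-like** — no initiation,
  $\sigma_{\mathrm{int}} = 0.055$ (median intrinsic noise near 0.001,
  below control).

## Image cytometry

`render_animal_stack()` draws each cell as a nucleus in a two-channel
voxel stack (default 2 µm z step and slice thickness, 16-bit): a flat-top
spheroid (in-plane radius 4 px, axial radius 2 slices) with a Gaussian-soft
edge (0.8 px). The per-channel amplitude is calibrated by direct summation
so that the mean intensity over the nominal equatorial disk equals the
cell's raw value exactly. A flat-top profile is both how real intestine
nuclei look at this sampling (uniformly filled with freely diffusing
fluorophore) and what makes quantification robust: for a sharply peaked
blob, the mean over a threshold-derived mask depends strongly on where the
threshold happens to cut, and no amplitude calibration can make it
mask-independent. Optional Poisson shot noise and Gaussian read noise are
applied before quantization to the requested bit depth; 8-bit renderings
differ from 16-bit only through quantization, which per-experiment
normalization makes irrelevant downstream.

`segment_nuclei()` re-implements equatorial-slice nuclear cytometry as a
transparent recipe (the original acquisition used a proprietary plugin, and
the analysis depends only on per-nucleus two-channel means, not on the
specific segmenter): per-slice Gaussian smoothing (σ = 1 px) plus a light
1–2–1 axial filter; one global Otsu threshold for the whole stack (pooled
histogram, 256 levels); 6-connected 3-D components; a volume filter; the
equatorial slice chosen as the z index of maximal cross-section (ties to
the lower z); and a per-nucleus mask refinement to pixels at or above half
the component's peak 2-D-smoothed intensity, evaluated in a local window so
a dim nucleus is not truncated by the single global threshold. The
half-maximum rule is evaluated on the per-slice smoothed image because the
axial filter mixes in smaller off-equator cross-sections and shrinks the
half-max ring by several percent. The area filter is applied to the
refined mask.

`quantify_nuclei()` reports, per channel, the mean intensity over the
equatorial mask minus a background estimate, clipped at zero, and converts
counts back to generator units via the recorded gain. Two background modes
are provided because the published processing does not specify one: the
global median outside all components (default), and a local annulus
(3 px gap + 3 px ring, excluding all component pixels); both agree on a
constant background, and the mode used is recorded in the output. The
noise-off round trip — simulate → render → segment → quantify — detects
every expressing nucleus and recovers per-cell values within 5% (a small
systematic component, ≈3%, comes from the half-max mask sitting just
inside the calibration disk; it is common to both channels and cancels in
every ratio-based statistic). A nucleus silenced on both alleles is
genuinely dark and may legitimately fall below detection.

## Noise statistics

`normalize_per_experiment()` divides each channel by its mean within the
experiment, making every per-experiment per-channel mean exactly 1; this
removes acquisition-setting differences (including bit depth) before
pooling. The per-cell intrinsic noise is

$$\eta = \frac{(x - y)^2}{2\,\langle x\rangle\langle y\rangle},$$

where $x, y$ are the cell's normalized allele values and $\langle x\rangle,
\langle y\rangle$ the allele means over the reference group of cells. The
extrinsic factor shared by both alleles cancels in $x - y$ up to the
allele-mean ratio, so $\eta$ isolates allele-specific deviation: 0 for a
cell on the group's average allele ratio, of order 1 for a monoallelic
cell. `group_noise()` computes the means per group × experiment stratum by
default — the published description ("the average value for each allele")
does not say whether means were taken per experiment or per pooled group,
so the policy is explicit, recorded on the result, and switchable
(`means = "group"`); for data normalized per experiment the two differ
little. Cells from all experiments are pooled for summaries, matching the
convention of reporting N cells over three independent experiments.

The allele-bias score `allele_r2()` is the coefficient of determination
between $x$ and $y$ across all cells of a group: near 1 for tightly coupled
biallelic expression, near 0 when alleles are decoupled. Two routes are
provided behind one interface — squared Pearson correlation and
$1 - SS_{\mathrm{res}}/SS_{\mathrm{tot}}$ from the least-squares line of
$y$ on $x$ — because the reported score does not state the regression
direction; for a straight-line fit with intercept they are analytically
identical, and the tests assert their agreement. Pearson-based $R^2$ is
invariant to positive affine per-channel scaling, so it does not matter
whether it is computed before or after normalization.

`boxplot_summary()` reports the median and the 5/10/25/75/90/95
percentiles (box = quartiles, whiskers = 10/90, dots = 5/95) using linear
interpolation between closest ranks (`quantile` type 7), the common
plotting default.

## State calling, coherence, and lineage inference

`call_mae_state()` cuts the allele fraction $f = x/(x+y)$ at explicit
thresholds: $f \ge 0.9$ mono-green, $0.7 \le f < 0.9$ green-biased,
$0.3 < f < 0.7$ biallelic, symmetric for red. Published descriptions of
"the same MAE state" are qualitative, so the cuts (0.9/0.7) are
configuration with recorded defaults, not claims; cells with $x + y \le 0$
are excluded with a logged count. `animal_coherence()` summarizes per
animal: the modal state (ties broken toward biallelic, then
alphabetically), the coherence (fraction of cells in the modal state, with
`coherent` at ≥ 0.5, boundary inclusive), `coherent_mae` (at least half
the cells share one *monoallelic* state), and `fully_mono` (fraction of
cells monoallelic for one and the same allele ≥ 0.9 — the "almost or
entirely monoallelic" reading; with 7 sampled cells this means all 7).

`fitch_min_events()` solves small parsimony on the lineage for the two
states active/silenced by bottom-up cost propagation, counting
active→silenced transitions; the root descends from an active ancestor, so
a silenced root costs one event. The default mode forbids silenced→active
transitions, matching persistent silencing (`maintenance = 1`); a
reversible mode allows and counts them. Unsampled leaves contribute no
cost in either state (universal-set semantics) rather than being imputed.
Tie-breaks in the backtrace keep the parent's state, and the root prefers
active, so the reported labeling is one minimum-event solution; the count
is exact (verified against exhaustive enumeration on trees up to 8
leaves). `infer_initiation_stage()` maps calls to per-allele leaf labels
(mono against an allele ⇒ silenced; biased states are treated as active by
default, configurable) and reports the minimum division stage among the
inferred events — stage 0 is the E cell. On clonal single-event animals
with all 20 leaves sampled, the true stage is recovered essentially always
at control noise levels.

`pattern_heritability()` compares each parent's signed allele-fraction
score (`allele_bias_score()`: mean $f$ − 0.5) with its brood's mean score
by Spearman correlation and a seeded permutation p-value (default 10,000
permutations); zero-variance inputs are flagged as degenerate rather than
tested. Silencing that is re-randomized at each generation gives
correlations near zero.

## Rank-based tests

All group comparisons are nonparametric, as these intensity-derived
quantities are non-normal even after log transformation.
`mann_whitney_u()` computes U from midranks and a two-sided p: exact by
full enumeration of group assignments when the number of combinations is
small (this also handles ties exactly), exact by the classical count
recurrence for tie-free samples up to $n \cdot m \le 400$, and otherwise a
normal approximation with tie correction and (default) continuity
correction. `kruskal_wallis()` applies the tie-corrected H with a
chi-square reference ($k - 1$ df); all-identical data give H = 0, p = 1.
`dunns_procedure()` uses global midranks:

$$z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
\frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
\frac{1}{n_j}\right)}}$$

with two-sided p per pair and Bonferroni control over the requested
comparison set — the exact multiple-comparison internals of the original
desktop statistics software are not documented, so a conservative,
reproducible choice is made and labelled in the output. Global ranks (the
standard Dunn construction) are used rather than per-pair re-ranking, also
noted in the output. Each implementation is cross-checked in the tests
against both brute-force oracles and the corresponding base R tests where
they exist.

## Ingesting deposited workbooks

`read_source_data_workbook()` reads an XLSX workbook laid out sheet per
figure panel with `<group> x`/`<group> y` column pairs, locating the panel
sheet by case-insensitive substring and the column pairs by header scan; if
a group has more than one candidate pair it refuses to guess and lists the
candidates, and the mapping actually used is attached to the result. The
package also ships a *synthetic* workbook writer
(`write_source_workbook()`, implemented via Python's openpyxl since no R
XLSX writer is available here) so the ingest path is testable without any
external file; tests verify that the ingest → normalize → group-noise →
median chain reproduces exactly the medians computed from the pre-export
table, and will verify published panel medians directly if a real workbook
is supplied via the `armae.source_data` option.

## Numerical choices and problem sizes

* Percentiles: linear interpolation (type 7), documented above.
* Mann–Whitney exactness switch: $n \cdot m \le 400$; enumeration cap
  200,000 combinations; continuity correction on by default.
* Otsu threshold: 256 levels on the pooled voxel histogram.
* Segmentation defaults: smoothing σ = 1 px, component volume 20–20,000
  voxels, equatorial area 5–5,000 px; equatorial tie-break toward lower z.
* Degenerate inputs: blank or saturated stacks yield zero ROIs (not an
  error); empty ROI masks, zero-variance $R^2$ inputs, empty groups and
  nonpositive means raise named errors; indeterminate MAE calls are
  excluded with a recorded count.
* Test and acceptance problem sizes are chosen to keep the whole suite in
  tens of seconds while leaving Monte-Carlo bands at ±3 standard errors:
  10,000 animals for the fully-monoallelic fraction, 10,000 replicates for
  the type-I error of Kruskal–Wallis, 4,000 for Dunn's family-wise error,
  2,000 cells per point for monotonicity scans, 300 animals for
  initiation-stage recovery.

## What the simulator does and does not show

The generator reproduces the statistical structure the analysis relies on:
clonal silencing on a fixed lineage, shared extrinsic and independent
intrinsic lognormal variation, near-dark silenced alleles, batch effects
removed by per-experiment normalization. It does not attempt spatial
realism (nuclei are laid out in a row, not in the worm's geometry), optical
realism (no depth-dependent attenuation, no point-spread anisotropy beyond
the axial radius, no autofluorescence), partial or graded silencing, allele
coupling (initiation is independent per allele), germline transmission, or
any molecular mechanism — chromatin regulators appear only as named
parameter presets. Passing tests therefore demonstrate the correctness and
calibration of the *analysis* on data satisfying its assumptions, not that
real intestines satisfy them. One deliberate simplification is stated plainly: under this
expression model the silencing-prone preset cannot simultaneously match all
published summary values (see the preset calibration section), and the
calibration priorities chosen there are documented rather than hidden.
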