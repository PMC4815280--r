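---
title: "Methods: integrated AF/AI/LOH/CNV analysis of SNP-array intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated AF/AI/LOH/CNV analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpscan)
```

# The problem

A SNP genotyping array measures, at each polymorphic site, two allele-specific
hybridization intensities and emits a genotype call. The total intensity is
proportional (noisily, on the log scale) to the DNA amount, and the relative
intensity of the two alleles estimates the within-individual allele
frequency. From a panel of normal reference samples, `snpscan` derives
per-marker reference distributions and scans a test sample for four coupled
signals: allele-frequency shifts, allelic imbalance (AI), loss of
heterozygosity or long contiguous stretches of homozygosity (LOH/LCSH), and
copy-number change (CNV/CNA), followed by copy-number segmentation.

# Allele-frequency estimation

The raw AF of allele A is $h = h_A/(h_A + h_B)$, undefined when the total
intensity is zero. Two systematic distortions are corrected:

**Preferential hybridization (CPA).** Alleles hybridize with unequal
efficiency, so heterozygotes drift from $h = 1/2$. The per-marker coefficient
is the mean odds over reference heterozygotes,
$\kappa_m = \overline{h/(1-h)}$, and the corrected AF is
$\hat h = h / (h + \kappa_m (1 - h))$ — a monotone bijection of $[0,1]$
fixing the endpoints, the identity at $\kappa = 1$. The literature formula
this estimator descends from prints an additional correction term whose
sample index dangles outside its own summation; read as the mean of
deviations from the mean it is identically zero, and it is exposed as the
(equivalent) `correction = "loo"` mode of `estimate_cpa()` rather than
invented into something else. Markers with fewer than two reference
heterozygotes carry no information about $\kappa$ and fall back to 1 with a
logged count.

**Cluster recalibration (LIM).** Even after the CPA correction the three
genotype clusters do not sit at the ideal 1, ½, 0. The piecewise-linear map
`lim_calibrate()` sends the reference cluster means
$\bar h(BB) < \bar h(AB) < \bar h(AA)$ of the CPA-adjusted AF exactly onto
$0, \tfrac12, 1$, interpolates linearly between adjacent anchors, and clamps
beyond the outer anchors. The printed source of this map contains an empty
third branch (its inequality bounds are swapped); the implementation uses the
unique correction that makes the map total, continuous and monotone. Values
exactly at an anchor take the lower branch. Markers whose cluster means are
missing (a genotype with fewer than two reference carriers) or unordered are
*uncalibratable*: their calibrated AF is missing and they are excluded from
AF-based detection — the same behaviour a real pipeline applies to
low-minor-allele-frequency markers.

With ideal clusters $(1, \tfrac12, 0)$ and $\kappa = 1$ the composition is
the identity, so the trisomy allele proportions $1, \tfrac23, \tfrac13, 0$
are fixed points — the analytic anchor used in the acceptance tests.

# Intensity preprocessing

The per-marker total intensity passes through up to three optional steps in a
fixed order — log2 transform, chip-effect removal (subtract the per-sample
mean *or* median over autosomal SNPs, then divide by the per-sample SD in
either mode, following the source pipeline literally), and quantile
normalization (each sample's sorted values mapped to the across-sample mean
of sorted values; ties get the mean of their target slots; rows with missing
cells are left untouched). All eight on/off combinations are expressible,
matching the 8-database preprocessing grid of reference panels.

The final copy-number track subtracts, from every marker, the mean intensity
over *allelically balanced* autosomal SNPs ("aberrant-probe perturbation
removal"): markers inside an aberration are excluded from the centering mean
because their intensities are shifted by the very signal being sought. The
balance flags are the negation of the single-point AI flags computed from the
calibrated AF (the AF track itself is computed from raw, pre-normalization
intensities). If no balanced SNP exists the caller may opt into the all-SNP
mean; an annotation without autosomes (the simulation's single-X template)
centers on all SNP probes. After this step, 0 means copy-neutral, positive
gain, negative loss.

# Single-point detectors

With $\bar f(g), S(g)$ the per-genotype reference mean and unbiased SD of the
calibrated AF, $\bar t, \hat\sigma$ the (pooled or genotype-specific)
reference moments of the final intensity, $M$ the per-chromosome count of
usable markers (CN probes, when present, form their own track with their own
$M$), and $z_q$ the standard-normal quantile:

* **AI**: flag iff $\hat f$ lies outside *all three* of
  $[\bar f(AA) - z_{1-\alpha/3M} S(AA),\, 1]$,
  $\bar f(AB) \pm z_{1-\alpha/6M} S(AB)$,
  $[0,\, \bar f(BB) + z_{1-\alpha/3M} S(BB)]$.
* **LOH/LCSH**: flag iff $\hat f \notin \bar f(AB) \pm z_{1-\alpha/2M} S(AB)$.
  Homozygous SNPs flag by design; runs of them are the LCSH signature, and
  the multipoint scan normalizes against how often normal samples do the
  same.
* **CNV/CNA**: flag $+1$/$-1$ for $t$ strictly above/below
  $\bar t \pm z_{1-\alpha/2M}\hat\sigma$, with statistic
  $Z = (t - \bar t)/\hat\sigma$ and adjusted p-value
  $\min\{2(1-\Phi(|Z|))\,M,\, 1\}$. The printed form doubles $\Phi(Z)$
  itself, which exceeds one for negative $Z$; the absolute-value reading is
  the standard two-sided test and is what is implemented.

Paired mode replaces the reference *center* with the paired-normal sample's
value (AF or intensity) and keeps the panel SD — a single paired sample has
no dispersion of its own (a user-supplied technical-replicate SD could be
substituted; the panel SD is the default). The AI quantiles become
$1-\alpha/M$ (homozygous) and $1-\alpha/2M$ (heterozygous) because only one
interval is tested. Degenerate markers (zero reference SD, or missing
genotype statistics) yield missing flags and are excluded from $M$.

# Multipoint scan

Within one chromosome, marker $x$ is *run-significant*, $J_x = 1$, iff it
belongs to a run of at least $n_c$ consecutive single-point flags (all
placements of $n_c$ consecutive markers covering $x$ are enumerated; only
placements fully inside the chromosome count; a chromosome shorter than
$n_c$ has none). For copy number, gain and loss flags are binarized into
separate tracks first — a "run" mixing directions has no biological reading.
The window-based aberrant proportion at anchor $m$ is the mean of $J$ over
the window $\{m-v, \dots, m+v\}$, truncated at chromosome ends with the
actual marker count as denominator so every marker gets a WAP.

Two significance procedures:

1. **Reference quantile.** Each normal reference sample's WAP track is
   computed leave-one-out (its own values removed from the comparison
   statistics — not from the calibration constants $\kappa$ and cluster
   means, which are panel-wide fixtures) and LOESS-smoothed; the per-anchor
   type-7 empirical $Q\%$ quantile of the smoothed reference WAPs is the
   threshold, exceeded strictly by the test sample's smoothed WAP. With
   fewer than $100/(100-Q)$ reference samples the quantile falls back to the
   per-anchor maximum, with a warning.
2. **Hypothesis test.** $Z = (W - \hat\mu + 1/M)/S$ with the reference WAP
   mean $\hat\mu$ and SD $S$, one-sided
   $p = \min\{(1-\Phi(Z))\,M,\,1\}$, flagged when $p < 0.05$ strictly.

The combined call multiplies the two flags. Where $S = 0$ — in a clean
synthetic panel that is *most* anchors, because normal samples essentially
never carry Bonferroni-level copy-number flags — procedure 2 is undefined;
its flag is missing and the combined call falls back to procedure 1 alone,
with the count of such anchors reported. Without this fallback the combined
detector would never fire in the stated synthetic world; with it, the
false-positive criteria still hold because procedure 1 alone is controlled.

Smoothing uses `stats::lowess` (local linear, no robustness iterations — a
rare isolated spike must attenuate, not vanish) over the marker index, with
span expressed as a fraction of the chromosome's markers (default 0.02) and
the result clipped to $[0,1]$. Only the WAP of procedure 1 is smoothed,
matching the printed order of operations; the test statistic of procedure 2
uses the raw WAP.

Regions are joined per aberration type: maximal runs of flagged markers
(single-point) or the union of the flagged anchors' windows (multipoint),
with 1-based inclusive coordinates internally and 0-based half-open BED on
export. A single non-significant marker breaks a run; gains and losses are
never merged.

# Segmentation

`cbs_segment()` is a circular binary segmentation: the chromosome is closed
into a circle, the arc maximizing the two-sample mean-difference statistic
against its complement is the candidate change, and a permutation test
(shuffling values within the segment) accepts it at `alpha_change`; the
recursion continues in each piece. Both the arc and its complement must hold
`min_markers` markers. The statistic winsorizes at the `trim_fraction`
quantiles (outlier guard) — reported segment means use raw data. The exact
$O(n^2)$ arc scan is used up to `exact_max_n` markers; above that a
boundary grid (used consistently for the observed and permuted statistics,
so the test stays valid) is refined locally around the winning arc. The
permutation loop stops early once significance is out of reach. Note the
granularity constraint: the smallest attainable permutation p is
$1/(n_{perm}+1)$, so `alpha_change = 0.01` requires at least 100
permutations before any split can be accepted (defaults: 0.01 and 1000).

The **quick** variant exploits that copy-number changes concentrate where AI
or LOH/LCSH is already detected: it runs the recursion only inside those
regions, groups each complement gap into a single flanking segment, and
weights the split statistic by
$\tilde w_m \propto 10^{-10} + \max(\tilde d^A_m, \tilde d^L_m)
 \, I[\max > 0]$, where $d = W - \tilde Q$ is the test WAP minus the
reference quantile and $\tilde d$ is its per-track linear rescale onto
$[-1, 1]$ (a constant track rescales to 0 by convention, so two constant
tracks give uniform weights rather than an error). The weighted split
statistic is the difference of weighted means over the pooled weighted
variance, $s^2_p = (SSE_L + SSE_R)/(W_L + W_R)$ — a Welch-style variant was
the other candidate; pooled was chosen because the permutation calibration
makes the denominator convention immaterial for validity, and pooled reduces
exactly to the classical statistic under uniform weights. Permutations
shuffle data-weight pairs. The time saving comes from evaluating strictly
fewer candidate splits whenever the AI/LOH regions cover less than the whole
chromosome; the `b/a < 5%` applicability rule (fragments shorter than 1% of
the chromosome over total fragments) is checked and warned about, never
enforced.

# The synthetic world

`generate_reference_population()` states the data-generating model used by
every test and by the acceptance report:

| parameter | default | meaning |
|---|---|---|
| markers | 2001 on one chromosome | template length of the simulation design |
| allele frequency | Uniform(0.05, 0.95) | per-marker, genotypes under Hardy–Weinberg |
| cluster AF means | 0.95 / 0.50 / 0.05 | observed allele-fraction clusters (AA/AB/BB) |
| cluster AF SDs | 0.02 / 0.03 / 0.02 | within-cluster spread |
| $\kappa$ | 1.2 | hybridization bias injected, later recovered by CPA |
| log2 intensity SD | 0.25 | chip noise on the log2 total intensity |
| marker baseline SD | 0.15 | fixed per-probe effects |
| copy shift | 1.0 log2/halving | one copy vs two copies differ by 1 log2 unit |

The copy shift deserves its rationale: halving the target DNA halves the
fluorescence on a well-behaved array, i.e. a −1 shift in log2 — with chip
noise 0.25 that is a 4-SD separation between the one- and two-copy states.
An alternative reading of the design ("separation of 1 chip-SD") was
rejected a priori: under it the donor-truncation filters leave less than 1%
of injected markers beyond the Bonferroni threshold, so no detector could
reach the stated power targets, and it contradicts the physics the filter
emulates. Both knobs (`log2_sd`, `copy_shift_log2`) are exposed, so harder
worlds are one argument away.

Aberration injection replaces the genotypes and intensities of the central
$N_T$ markers with donor draws filtered against the reference panel's
per-genotype log2-intensity statistics $(\hat\mu_g, \hat\sigma_g)$: loss
keeps one-copy draws $\le \hat\mu - r\hat\sigma$; gain keeps two-copy draws
$\ge \hat\mu + r\hat\sigma$ and is run against a *one-copy* template
population (an all-male X chromosome), mirroring the loss contrast — a
2→3-copy autosomal gain would be a log2(3/2) = 0.58 shift and a different,
harder problem; neutral keeps two-copy draws within $\pm 3\hat\sigma$. The
statistics are those of the donated genotype's class (the donor replaces the
genotype, so this *is* the recipient's post-injection class), with a pooled
fallback. With probability $q\%$ a marker instead receives an unconstrained
draw within $\pm 2\hat\sigma$, emulating admixture or noise interference.
Rejection sampling is capped at $10^5$ draws per marker, after which the
(marker, r) pair is reported as infeasible.

**What a green test does and does not establish.** The generator reproduces
the features the detectors rely on — genotype clusters with hybridization
bias, dosage-proportional intensities, per-probe baselines, Hardy–Weinberg
genotype frequencies — and omits GC waves, batch effects, probe
cross-hybridization, genuine linkage disequilibrium and population structure.
Controlled false-positive rates and high recovery here validate the
statistical machinery (interval construction, Bonferroni scaling, WAP
normalization, segmentation), not robustness to those real-data artifacts.
Two consequences of the clean world are worth naming: normal reference
samples carry essentially no Bonferroni copy-number flags, so the WAP
reference quantile track is zero (any positive smoothed WAP is significant
under procedure 1) and the procedure-2 reference SD is zero at most anchors
(the combined call falls back to procedure 1 there). Real reference panels
leave both nonzero.

# Numerical and procedural choices

* Variances from sums-of-squares are clamped to zero below $10^{-12}$
  (catastrophic cancellation on constant classes); unbiased $n-1$
  denominators throughout; per-genotype statistics require $n \ge 2$.
* Empirical quantiles are type-7 (linear interpolation between order
  statistics) everywhere, so reference thresholds are reproducible.
* Boundary conventions are strict where the source prints strict: CNV flags,
  smoothed-WAP > quantile, multipoint $p < 0.05$; LIM branch boundaries take
  the lower branch.
* Genotype code map defaults to 0/1/2/−1 → AA/AB/BB/NoCall and is
  configurable; NoCall genotypes are excluded from all per-genotype
  reference statistics and fall back to pooled statistics in
  genotype-specific CNV detection. Missing intensity cells are missing
  markers, never zeros. Chromosome labels are normalized by stripping a
  leading `chr`.
* All stochastic paths (generation, injection, permutation tests, the
  simulation study) take explicit seeds, restore the caller's RNG state, and
  are bit-reproducible.
* The "boundary recovery" property (detected region covers 80–120% of an
  injected target) is assessed on CBS segments classified by the copy-level
  midpoint, not on multipoint window-union regions: a window-union region is
  at least $N_T + 2v$ markers long by construction (already ~120% at
  $N_T = 51$, $v = 5$), so it can localize but not delimit; delimiting is
  the segmentation step's job.

# Known limitations

* The reference panel must be copy-neutral where it is used; contaminated
  "normals" inflate reference SDs and deflate sensitivity (the leave-one-out
  WAP reference limits, but does not remove, self-contamination).
* Quantile normalization skips rows with missing cells rather than
  normalizing the observed subset.
* Paired mode borrows the panel SD; a paired design with technical
  replicates would estimate its own.
* X-chromosome handling is by configuration (`center_chromosomes`, sample
  sex in the generator); no automatic sex inference.
* CN (non-polymorphic) probes are carried through annotation, preprocessing
  and their own detection track, but the synthetic generator emits SNP
  probes only.
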