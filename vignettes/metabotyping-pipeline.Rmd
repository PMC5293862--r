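---
title: "Mining multi-batch LC-MS peak tables for population-level metabolic variation"
author: "grassmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining multi-batch LC-MS peak tables for population-level metabolic variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassmet)
```

## The problem

Untargeted reversed-phase LC-MS profiling of a large plant collection —
hundreds of clonally replicated genotypes drawn from many populations —
cannot be run in a single analytical batch. Spread over dozens of batches
and months, the resulting aligned peak table (tens of thousands of peaks
by more than a thousand injections) is dominated by technical structure:
batch-to-batch intensity shifts, retention-time drift that fractures one
compound into several table rows, isotope envelopes that triple-count
every metabolite, and occasional aberrant replicate injections. Only
after this structure is removed can the biological question — which
metabolites distinguish the populations — be asked.

`grassmet` implements that workflow end to end on a
`PeakExperiment` container (a `SummarizedExperiment` whose `rowData` is
the peak annotation table and whose `colData` is the sample metadata),
together with a synthetic-data generator that renders a
multi-batch survey with known ground truth so that every stage can be
validated quantitatively.

## Quality control

**Duplicate merging.** Split detection of one chromatographic peak
leaves near-identical rows. Rows within 20 ppm in m/z and 0.2 min in
apex retention time are grouped transitively and collapsed to one row
carrying the per-sample maximum. The tolerances mirror the instrument's
mass accuracy window and typical apex jitter; pairs further apart than
0.2 min are treated as genuine isomers.

**Batch correction.** Intensities are modelled on the natural-log scale
(a `+1` offset guards zero-filled cells) as
$y_{pbs} = \alpha_p + \gamma_{pb} + \delta_{pb}\,\varepsilon_{pbs}$:
an additive batch location effect and a multiplicative batch scale
effect per peak. Per-peak data are standardised, the location effects
are shrunk toward a normal prior and the squared scale effects toward an
inverse-gamma prior — hyperparameters fitted by the method of moments
across peaks — and the posterior estimates are found by the standard
iterative empirical-Bayes solution (relative convergence $10^{-4}$) and
removed. Shrinkage across peaks is what makes the adjustment stable for
weak peaks; the unit tests verify agreement with an independently coded
direct implementation ($10^{-8}$) and with `sva::ComBat` ($10^{-4}$ on
complete data). After correction, a per-peak one-way ANOVA of log
intensity on batch removes anything still batch-structured at
$\alpha = 0.05$. Peaks that are constant across batches carry no
testable batch effect and are retained ($p$ defined as 1); conversely,
the invariance filter (below) treats constant peaks as removable, since
no variation is exactly what it screens out.

**Replicate screening.** For every peak and genotype, the coefficient of
variation over the clonal replicates is computed with pairwise deletion
of missing cells; the per-peak summary is the median cv across
genotypes. Replicate groups with cv > 0.2 are inspected with modified
Z-scores, $Z_i = 0.6745\,(x_i - \mathrm{median}\,x)/\mathrm{mad}(x)$
with the *unscaled* median absolute deviation, and cells with
$|Z| > 3$ are set to missing. Two conventions close the formula's edge
cases: when mad is 0 every score is 0 (constant groups flag nothing),
and at most $\lfloor n/2 \rfloor$ cells may be removed per group so a
group can never lose its majority. The screen is two-sided: an
aberrantly low injection is as suspect as an aberrantly high one, and
the trigger cv is evaluated after batch correction so that a batch shift
spanning a replicate group is not mistaken for an outlier. At $n = 5$
the modified Z-score is known to be liberal — about 3–4 % of clean cells
in triggered groups exceed the threshold — which the generator-based
tests quantify (sensitivity ≥ 0.9, per-cell false-flag rate ≤ 0.05).

**Invariance filter.** Clonal replicates are collapsed to genotype
medians and each peak is tested across populations with the
Kruskal–Wallis test; peaks with $p > 0.05$ carry no population signal
and are dropped. **PCA diagnostics** on the log, peak-centred matrix
verify that the bulk control samples — a composition unlike any single
population — separate from experimental samples once batch structure is
gone.

## De-isotoping

Candidate envelopes $[M], [M+1], [M+2]$ must satisfy four criteria
conjointly: successive members spaced 1.00336 Da (the ^13^C–^12^C mass
difference; singly charged ions only, appropriate for this compound
class) within a 20 ppm window; apex retention times within 0.2 min;
Pearson correlation of the member intensity profiles above 0.9 across
samples (pairwise-complete, at least 3 shared samples); and mean
intensity ratios $[M]/[M+1] > 2$ and $[M+1]/[M+2] > 2$. Under the
binomial isotope model with $p(^{13}C) = 0.0107$ the ratio criterion
admits compounds up to roughly 46 carbons, comfortably covering
flavonoid glycosides. Envelopes are assembled greedily in descending
monoisotopic mean intensity (ties by ascending m/z; the partner closest
to the expected spacing wins), each peak joins at most one envelope, and
only $[M]$ survives.

Two properties are worth stating precisely. Equality with an exhaustive
oracle that tests every pair/triple against the four criteria holds on
random tables of ≤ 50 peaks. Threshold monotonicity holds at the
*criteria* level — any envelope accepted under tightened thresholds also
passes the looser ones — but not at the set level: a $[M+1]$ freed when a
tighter ratio threshold dissolves its envelope may legitimately head its
own smaller envelope, a direct consequence of greedy disjoint
assignment.

## Differential mining

Genotype medians are the unit of replication throughout: clonal
replicates are technical repeats of one genetic individual, and treating
injections as independent would pseudo-replicate both the clonal and
the batch structure.

The population test is a moderated one-way F. Per peak, the
between-population mean square on log genotype medians is divided by a
posterior residual variance
$\tilde{s}^2 = (d_0 s_0^2 + d\,s^2)/(d_0 + d)$, where the prior
degrees of freedom $d_0$ and scale $s_0^2$ are estimated by moment
equations on the observed residual variances (`limma::fitFDist`);
$p$-values come from $F(k-1,\,d_0+d)$ and are Benjamini–Hochberg
adjusted. `priorDf = 0` recovers the classical ANOVA exactly and
`priorDf = Inf` tests against the common prior variance — both exposed
as arguments and used as limiting-case oracles in the tests.

Ranking for annotation first gates to intense peaks (mean raw intensity
above $10^5$, where spectra are informative), then orders by moderated F
with ties broken by peak id, returning the top 50. The gate-then-rank
statistic is this package's choice of a fully specified ranking; the
output records it in a `ranking_statistic` column so downstream users
know exactly what ordered the list.

**Population profiles and clustering.** A population's profile is the
median across its genotypes of the genotype medians — a median of
medians, robust to a single extreme genotype. Profiles are clustered
with UPGMA (average linkage on Euclidean distances), on raw intensity by
default because presence/absence contrast between populations is the
dominant signal; a `log` switch is provided. Trees are ultrametric with
two populations at distance $d$ joining at height $d/2$, verified
against a brute-force agglomeration oracle, and export to Newick.

**Isobaric aggregation.** When retention-time drift has split one
metabolite across several rows, per-row statistics are unreliable; all
rows within a ppm window (optionally an RT interval) are summed per
sample, with missing cells contributing zero so the aggregate is exactly
the sum of its members. The across-population F-test on the aggregate is
computed on log genotype medians for the same pseudo-replication reason
as above; per-member tests are reported alongside so the user can see
the spurious row-level differences the aggregate resolves.

## Annotation

Flavonoid glycosides fragment in-source by losing sugar and acyl
moieties, so annotation is rule-based arithmetic over two small
libraries: aglycone cores (kaempferol K, luteolin, quercetin Q,
isorhamnetin I, thesinine, chlorogenic acid, perloline) and neutral
losses (hexose 162.0528, deoxyhexose 146.0579, acetylhexose 204.0634,
malonylhexose 248.0532, feruloylhexose 338.1002 Da). Masses are CODATA
monoisotopic values; adducts use the proton mass 1.007276 Da, which
reproduces the standard reference m/z values (e.g. kaempferol
[M+H]^+^ 287.0550) to all four printed decimals.

Three evidence criteria are evaluated per peak: an isotopic partner at
+1.00336 Da whose retention time falls inside the target's
[rtmin, rtmax]; the co-eluting group (apex within 0.05 min, Pearson
r > 0.9) supplying fragment candidates; and greedy neutral-loss
decomposition. The decomposition prefers losses directly evidenced by
differences between successive observed ions; only when the observed
chain is incomplete does it fall back to the smallest moiety multiset
(ties lexicographic) explaining parent − aglycone, and when no observed
ion matches an aglycone it hypothesises each library aglycone and keeps
the most parsimonious decomposition. Every returned name must recompose
the parent m/z within the ppm tolerance, or the peak is reported
unannotated with its partial evidence.

Deliberate limits: glycosylation positions and inter-glycosidic
linkages are never inferred; hexose is reported as glucose and
deoxyhexose as rhamnose by field convention, with the assumption
recorded in the evidence table; kaempferol and luteolin share a formula
and are always reported as an ambiguous pair; and with a 20 ppm window
on large parents distinct aglycone + moiety combinations can be
isobaric (e.g. isorhamnetin + acetylhexose + feruloylhexose vs
kaempferol + 2 hexose + malonylhexose differ by ~1.8 mDa), so
fragment-evidenced chains always outrank mass-only hypotheses. Two
library quirks are surfaced rather than resolved: perloline is stored
by its reference calculated m/z (333.1234, no formula), and the
chlorogenic-acid formula value (C16H18O9, [M−H]^−^ 353.0878) differs
from the commonly quoted calculated 353.0867 by ~3 ppm — the library
carries both and reports the discrepancy. Annotated spectra round-trip
through the NIST MSP text format.

## The synthetic-data generator

The generator is the test bed for everything above. Its default
("fast") design is 10 populations × 6 genotypes × 5 clonal replicates in
12 randomized batches with 2 bulk controls per batch; a "full" preset
reproduces a 23-population / 233-genotype / 36-batch survey. The
compound panel mixes named flavonoid glycosides and alkaloids with
population patterns that exercise each downstream claim — compounds
absent from the first two populations, compounds exclusive to one
population, a rhamnoside isomer pair 0.22 min apart whose rows are
fractured by per-batch retention drift, a compensating isomer trio whose
per-population shares vary while the total is invariant — plus 130
uniform (null) fillers, 15 strongly differential fillers and 5
control-enriched markers.

Noise choices, once for all analyses:

* Replicate noise is multiplicative log-normal with
  $\sigma = \sqrt{\log(1 + \mathrm{cv}^2)}$ so the target cv (default
  0.2, a typical untargeted-LC-MS replicate cv) is directly
  parameterised.
* Genotype (clonal) biological variation is log-normal with sd 0.4,
  giving within-population biological spread comparable to the
  technical noise.
* Batch location shifts are normal with sd 0.5 log-units around
  per-batch means (plus sd 0.15 per-peak deviations) and batch scale
  factors are log-normal sd 0.15 — strong enough that a one-way batch
  ANOVA detects them with power > 0.9 before correction, as the
  predominant pre-correction variance component should be.
* Per-batch retention drift is uniform on ±0.25 min, enough to
  interleave isomers ~0.2 min apart across batches; detections of
  drift-affected isomers are re-clustered into rows by complete-linkage
  clustering with a 0.1 min diameter, mimicking density-based peak
  grouping. With 12 batches this renders the isomer pair as ~6 rows.
* Absent metabolites are rendered at a positive baseline floor
  (default $10^3$ counts) with truncated noise (never above 2× the
  floor), because fill-peaks-style processing reports noise, not zero;
  batch location shifts are only applied to real signal.
* Detected m/z carries a uniform ±5 ppm error per row, well inside the
  20 ppm matching window.
* Isotope envelopes follow the binomial ^13^C model: $[M+1]/[M] =
  C\,p/(1-p)$, $[M+2]/[M+1] = \tfrac{C-1}{2}\,p/(1-p)$ with $p =
  0.0107$; $[M+2]$ rows are emitted only above twice the floor.
* Forty replicate outlier cells (×8) and six duplicate detections are
  injected for the outlier and merge stages to find.

Everything is driven by the design seed: identical spec and seed give
bit-identical tables.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: raw chromatograms and peak
detection itself; electrospray adduct diversity beyond [M+H]^+^ /
[M−H]^−^ (no sodium adducts, dimers or multiple charging); within-batch
run-order drift; correlated (compound-class) batch responses; matrix
effects and ion suppression; and real fragmentation spectra (fragment
rows are rendered proportional to their parent). Recovery rates measured
here are upper bounds for field data.

## Numerical conventions

Log transforms use natural log with a +1 offset. Missing values are
excluded pairwise everywhere and never imputed. Degenerate inputs have
defined outcomes: constant peaks give $p = 1$ (retained by the batch
filter, removed by the invariance filter, F = 0 in the population test);
mad = 0 gives all-zero Z-scores; an empty aggregation window is a notice,
not an error. All orderings that could tie (ranking, greedy envelope
assembly, merge representatives) break ties by peak id or ascending m/z
so outputs are deterministic. The acceptance checks run the fast preset
(~480 rendered peak rows, 324 samples), 100 random 50-peak de-isotoping
tables and 100 random 4–8-leaf trees; these sizes were chosen to make
every property measurable in seconds while leaving the statistics
well-powered.

## Limitations

The pipeline starts from an aligned peak table; detection, alignment and
gap-filling quality are upstream concerns it inherits. The EB batch model
assumes log-scale additivity and roughly normal peak-level effects;
gross nonlinear batch artefacts would need control-based signal
correction, which is out of scope (controls are used for PCA diagnostics
only). Annotation is accurate-mass arithmetic with in-source fragments —
MSI level 2 at best — and cannot distinguish stereoisomeric sugars or
positional isomers. The moderated test assumes a common one-way design
across peaks; unbalanced missingness is handled per peak but strong
mean–variance trends would call for precision weights.
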