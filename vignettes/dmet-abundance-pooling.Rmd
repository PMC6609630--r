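---
title: "Pooling DMET protein abundance across laboratories and deriving PBPK inputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling DMET protein abundance across laboratories and deriving PBPK inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmetpool)
```

## The problem

Absolute abundances of drug-metabolizing enzymes and transporters (DMET) in
human liver microsomes — UGTs, CESs, FMOs and their relatives — are scattered
across small targeted-proteomics and immunoquantification studies. Any one
study reports a mean, an SD and a handful of donors; different laboratories
disagree by factors that often exceed the biological spread between donors.
A physiologically based pharmacokinetic (PBPK) model, however, needs a single
defensible abundance per isoform, an honest statement of its variability, and
a route from that abundance to enzyme-kinetic model inputs.

`dmetpool` implements that chain: a curated-repository data model with an
explicit inclusion filter, a two-track meta-analysis per protein, a
well-stirred-liver IVIVE (in vitro–in vivo extrapolation) cascade, and
multiplicative scale factors for variability bounds and special populations.

## The repository and the inclusion filter

Records follow a flat schema (`repository_columns()`): one observation of one
protein in one tissue, with mean/median abundance, SD, range, %CV, unit,
donor count, pooled-sample flag, analytical method, quantification mode,
demographics and a citation key. `filter_for_meta()` applies four criteria
before pooling:

1. individual donor samples only (pooled preparations average away
   inter-individual variability);
2. absolute quantification by LC-MS/MS or Western blot (relative, mRNA and
   activity data are not abundances);
3. canonical units — pmol per mg microsomal protein, with power-of-ten
   variants (fmol/µg, pmol/µg, fmol/mg) rescaled and everything else
   excluded rather than converted heuristically (a unit like ng/mg would
   need a molar mass assumption we refuse to make silently);
4. at least two distinct citation sources per protein and tissue, because a
   single laboratory cannot exhibit inter-laboratory variability.
   "Different laboratories" is operationalized as distinct citation keys;
   the literature does not provide a finer laboratory identifier.

Each excluded record is attributed to exactly the first criterion it fails,
so retained plus per-criterion counts always equal the input count — a
bookkeeping invariant the tests enforce. Median-reported studies are pooled
like mean-reported ones (excluding them would silently change the study
count); the `stat_kind` flag preserves provenance. Records without an SD
pass the filter and are dropped only by the individual estimators that need
an SD, with per-method `k_used` reported alongside `k`. Studies reporting
only a range (no SD, no CV) likewise remain in the sample-size track and are
absent from the variance track; the fit's availability flags make the
distinction visible rather than silent.

## The two-track meta-analysis

`dmet_meta()` fits both tracks and returns a classed object with `print`,
`summary`, `coef`, `confint` and `plot` (forest) methods.

**Inverse-variance track.** Fixed-effect weights are the inverse of the
reported *total* study variance, \(w_j = 1/SD_j^2\). This is deliberate and
follows the abundance-pooling convention this package implements: the
reported SDs describe inter-individual spread, and the question the
heterogeneity test answers is whether laboratories disagree by more than
that spread — not whether study *means* are estimated precisely. With
\(\mu_F = \sum w_j X_j / \sum w_j\), Cochran's statistic is
\(Q_F = \sum w_j (X_j - \mu_F)^2\) on \(df = k-1\). The between-study
variance uses the method-of-moments estimator
\[
\hat\tau^2 = \frac{Q_F - df}{\sum w_j - \sum w_j^2 / \sum w_j},
\]
set to zero whenever \(Q_F \le df\) (the tie is treated as the
zero branch), in which case the random-effects model collapses exactly onto
the fixed-effect one. Random-effects weights are
\(w_j^* = 1/(w_j^{-1} + \hat\tau^2)\). Heterogeneity is summarized by
\(H^2 = Q/df\), \(I^2 = \max(0, (H^2-1)/H^2) \cdot 100\%\), and the
upper-tail \(\chi^2\) probability of \(Q\). Classes are anchored at the
conventional 0/25/50/75% landmarks and split at their midpoints: `none`
only at \(I^2 = 0\), `low` below 37.5%, `medium` below 62.5%, `high`
above. \(H^2\) concern labels: `considerable` above 1.5, `little` below
1.2.

**Sample-size track.** The headline pooled abundance is the
sample-size-weighted mean \(WM = \sum n_j X_j / N\), deliberately free of
SD-based weights so that imprecise studies with many donors still count.
Three pooled %CV estimators accompany it:

* **Method I** uses only between-study spread:
  \(\nu = \sum n_j (X_j - WM)^2/N\), %CV \(= 100\sqrt{\nu}/WM\).
* **Method II** adds within-study variance through the overall sum of
  squares \(\sum[(SD_j^2 + X_j^2) n_j] - N\,WM^2\). Because this equals
  \(N\nu + \sum n_j SD_j^2\), method II can never fall below method I —
  an identity the tests verify against a brute-force oracle that expands
  every study into pseudo-individuals. Method II is the default %CV for
  PBPK bounds: it is the only method whose interval reflects both
  variance components, and it is the least sensitive to a small number of
  studies.
* **Method III** is the sample-size-weighted mean of the within-study CVs —
  informative about typical biological spread, blind to lab-to-lab offsets.

Confidence intervals are geometric,
\(\exp[\ln WM \pm z\,\sigma/\sqrt k]\) with
\(\sigma = \sqrt{\ln[(\%CV/100)^2 + 1]}\): abundances are
positive and right-skewed, and a lognormal interval cannot cross zero. The
headline intervals use the all-study `WM`, each method's %CV and the full
`k`, so a printed (WM, %CV, k) triple reconstructs them exactly even when
method II internally ran on the SD-bearing subset. `z` defaults to 1.96;
`acceptance_range()` reuses the same formula with `z = 4.26` — the wide
(99.998%) interval used to judge whether a simulated exposure parameter is
acceptably close to an observed clinical value, with `k` taken as the
number of subjects behind the clinical mean, since per-subject variability
is what a clinical %CV describes.

Per-study forest-plot intervals are drawn as mean \(\pm z\,SD_j/\sqrt{n_j}\)
on the arithmetic scale. These are presentation-only and never enter any
pooled quantity; the pooling literature rarely states a per-study interval
convention, and the standard error of the mean is the least surprising
choice.

## IVIVE: from clinical clearance to Vmax

`ivive_fit()` runs the cascade for a drug (packaged example: lamotrigine,
a UGT1A4-dominated glucuronidation substrate) against a physiology:

1. split systemic clearance: \(CL_R = f_{CL,renal} \cdot CL_{IV}\),
   \(CL_H = (1 - f_{CL,renal}) \cdot CL_{IV}\);
2. back-calculate unbound intrinsic hepatic clearance with the well-stirred
   liver model,
   \(CLu_{int,H} = Q_{H,B} CL_H / [fu_p (Q_{H,B} - CL_H/B\!:\!P)]\);
3. partition across isoforms:
   \(CLu_{int,DME_j} = f_{m,DME_j} CLu_{int,H} / (1 - f_{CL,renal})\);
4. convert to microsomal scale:
   \(CL_{int} = CLu_{int,DME_j}/(MPPGL \cdot LW \cdot 60 \cdot 10^{-6})\)
   in µL/min/mg — the \(60 \cdot 10^{-6}\) factor appears exactly once in
   the package, here (and inverted in `scaled_cluint()`);
5. derive \(V_{max} = CL_{int} K_m fu_{mic} / (abundance \cdot ISEF)\) in
   pmol/min/pmol enzyme.

The packaged adult physiology sets \(Q_{H,B} = 81.8\) L/h. This is a
calibration, not a physiological claim: it is the unique flow that makes
step 2 return the reference \(CLu_{int,H} = 4.09\) L/h from
\(CL_H = 1.8\), \(fu_p = 0.45\), \(B\!:\!P = 1\), keeping the packaged
parameter set self-consistent. Users with a preferred hepatic blood flow
supply their own physiology file; the field is mandatory, never defaulted.
Isoform-level metabolized fractions may be given flat or nested
(family total with percentage splits, e.g. glucuronidation 0.86 split
10/90 between UGT1A3 and UGT1A4); nested forms are normalized to absolute
fractions at read time.

## Scale factors

All adjustments are multiplicative, so factors compose and `SF = 1` is
always the identity:

* `sf_ci()` — ratio of a pooled CI bound to the pooled mean, producing the
  lower/upper Vmax variants that propagate inter-laboratory uncertainty
  into a PBPK model;
* `sf_population()` — abundance and MPPGL ratios for paediatric or
  hepatically impaired populations. Aetiologies are never conflated: the
  packaged Child-Pugh C files keep alcoholic cirrhosis (12-fold UGT1A4
  reduction) and HCV cirrhosis (4-fold) as separate specs with mandatory
  provenance strings;
* `scaled_cluint()` — forward IVIVE with the population's liver weight and
  MPPGL; at `SF = 1` it inverts the adult chain to 1e-9 relative, a
  round-trip the tests enforce;
* `scale_clr()` — renal clearance scaled by the \(fu \times GFR\) ratio,
  with unit tags checked rather than assumed.

Population files carry explicit `fu_p`, `GFR` and `MPPGL` values — there
are no silent defaults. The packaged paediatric and hepatic-impairment
files pre-fill only the age-specific liver weights (592.12 g at 4 y,
726.23 g at 7 y, 906.24 g at 9 y, 867.97 g for Child-Pugh C) and flag every
other field as a synthetic placeholder equal to the adult value, to be
replaced before quantitative use. `population_sheet()` covers the isoforms
a population spec actually describes; isoforms absent from the spec are
omitted from that sheet rather than silently carried over.

## The synthetic-data generator

`generate_study_set()` emulates the structure the pipeline assumes:
individual donor abundances are lognormal (matching the geometric-CI
construction), a study's laboratory multiplies them by a shared lognormal
bias \(b_j\) with log-scale SD `bias_sd_log`, and the study reports its
sample mean, sample SD and donor count. Per-study substreams are derived
from the seed by a counter, so enlarging `k` never rewrites earlier
studies.

Defaults define the emulated regime: geometric mean 40 pmol/mg, 20–30
donors per study, and a within-study geometric CV of 0.25. The 0.25
represents the purely biological inter-individual component; the larger
pooled CVs seen in curated liver-microsome corpora are attributed to the
inter-laboratory term, which is modelled separately and switched on
explicitly. This decomposition matters because of the \(1/SD_j^2\)
weighting: \(I^2\) compares laboratory disagreement against
individual-level spread, so heterogeneity detection power is a function of
the ratio `bias_sd_log` to \(\sqrt{\ln(gcv^2+1)}\). With the default
within-CV, zero bias yields mean \(I^2\) essentially 0 and a log-bias SD
of 0.5 yields mean \(I^2\) around 65% over 500 replicates — the regimes
the acceptance checks probe. Had the within-CV been set near 0.5, the same
bias would sit near \(I^2 \approx 10\%\): detection claims are only
meaningful relative to the stated within-study component.

What the generator does **not** emulate: peptide-level measurement error,
digestion efficiency, calibration-curve nonlinearity, covariate structure
(age, genotype, disease) and non-lognormal outliers. Passing the recovery
checks therefore shows the estimators are correct under the stated model,
not that real corpora satisfy that model.

## Numerical choices and edge cases

* `Q_F = df` ties take the \(\hat\tau^2 = 0\) branch, so the RE model never
  divides by the (then possibly non-positive) moment denominator.
* `I^2` is floored at zero; `Q = 0` with `df ≥ 1` yields `H2 = 0`,
  `I2 = 0`, class `none`.
* A single usable study gives a valid FE fit (`Q = 0`, `df = 0`) but no
  heterogeneity indices — asking for them is an explicit error, not an NA.
* The method II sum of squares is clipped at zero to absorb floating-point
  negatives in the all-zero-SD case.
* Reported %CVs are cross-checked against `100·SD/mean` (0.5 percentage
  points at the record level, 0.5% relative at the study level) — rounded
  literature values pass, transcription errors warn.
* Comparisons against printed reference values in the tests use a
  tolerance of one unit in the last printed decimal or 0.5% relative,
  whichever is larger, because published tables chain rounded
  intermediates.
* Monte-Carlo problem sizes in the tests and the acceptance script — 500
  replicates for the heterogeneity-power and CV-recovery checks, 60–300
  replicates for slower pipeline-level recovery — were chosen to keep
  Monte-Carlo error well inside the asserted margins while the whole suite
  runs in well under a minute.

## Worked example

```{r}
cfg <- synth_config(true_gm = 40, gcv_within = 0.25, bias_sd_log = 0.5,
                    k = 8, seed = 7)
ss <- generate_study_set(cfg, protein = "UGT1A4")
fit <- dmet_meta(ss)
fit
coef(fit)
confint(fit)
```

```{r}
ivive <- ivive_fit(read_drug_params(dmetpool_example("lamotrigine.yaml")),
                   read_physiology(dmetpool_example("adult_physiology.yaml")),
                   read_enzyme_table(dmetpool_example("enzymes_lamotrigine.csv")))
ivive
```

```{r, fig.width = 6, fig.height = 4}
plot(fit)
```

## Known limitations

* The inverse-total-variance weighting is a convention of this abundance
  literature; effect-size meta-analysis weighting by inverse squared
  standard error is intentionally not offered, and neither are REML/ML
  \(\tau^2\) estimators, Hartung–Knapp adjustments, meta-regression or
  publication-bias diagnostics.
* Unit handling rescales only power-of-ten variants of pmol/mg; molar
  conversions are out of scope by design.
* No absorption or whole-body simulation exists here: the outputs are
  parameter sheets for a PBPK simulator, not concentration–time profiles.
* Criterion iv's "distinct sources" proxy for "different laboratories"
  undercounts heterogeneity when one group publishes twice under different
  keys.
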