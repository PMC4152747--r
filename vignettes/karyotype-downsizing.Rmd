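---
title: "Karyotype constancy and genome downsizing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype constancy and genome downsizing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoploid)
```

## The scientific problem

Bimodal karyotypes — complements with two sharply distinct chromosome size
classes and no gradual transition — are a recurring feature of several
monocot lineages, including *Hippeastrum* (Amaryllidaceae), whose species
carry a basic number of x = 11 with four short near-metacentric and seven
long chromosomes. Two questions drive the analyses this package
implements:

1. **Genome downsizing.** When polyploids form, does the DNA amount per
   basic genome (1Cx = 2C / ploidy) shrink, and at what rate per added
   genome copy?
2. **Karyotype constancy.** Do the proportions and morphology of the
   complement — the bimodal split, the centromeric indices of each size
   class, the asymmetry indices — persist across large changes in genome
   size and ploidy?

Both questions reduce to reproducible arithmetic on two kinds of raw data:
per-metaphase chromosome arm measurements, and Feulgen densitometry
readings calibrated against an internal standard of known DNA amount.

## From arm measurements to a karyotype

A measurement table gives, per metaphase plate, one (short arm, long arm)
pair per chromosome. `average_karyotype()` condenses `k` plates of a
`ploidy * x` complement into one haploid-complement idiogram:

1. arms are canonicalised so S ≤ L (input column order is never trusted —
   this is what keeps every centromeric index in (0, 50]);
2. within each plate, chromosomes are sorted by decreasing total length
   and the plate is rescaled to unit total length. The rescaling removes
   condensation-stage differences: metaphases differ substantially in
   overall contraction, but relative lengths are stable;
3. arms are position-averaged across plates (homologs are unlabelled in
   real tables, so pairing is by length rank, the convention of
   MicroMeasure-style software), then runs of `ploidy` consecutive ranks
   are averaged into the x haploid-complement chromosomes;
4. relative lengths are normalised to sum to exactly 100.

Arms are averaged first and the centromeric index CI = 100·S/(S+L) derived
from the averaged arms; averaging per-plate CIs instead would weight small
plates' measurement error more heavily. This ordering was a genuinely open
choice; it is deterministic and documented here so results are exactly
reproducible.

## Karyotype parameters

For a haploid complement with arms (S_i, L_i), total lengths t_i and arm
ratios r_i = L_i/S_i:

* **CI_S, CI_L** — unweighted mean CI over the short and long subsets.
* **A1** = 1 − mean(S_i/L_i) (intrachromosomal asymmetry, in [0, 1)).
* **A2** = sd(t)/mean(t) (interchromosomal asymmetry; sd uses the n−1
  denominator, the common karyological convention — fixed here so oracle
  tests are exact).
* **CV_CL** = 100·A2, by construction — the package computes one from the
  other, and tests verify the identity on every input.
* **M_CA** = 100·mean((L_i−S_i)/(L_i+S_i)) (mean centromeric asymmetry).
* **CV_S** — summed short-set length as a percentage of total complement
  length. Published table captions call this a *volume* fraction, but the
  measurement source provides lengths only, so length is the size proxy.

Per chromosome, (L−S)/(L+S) = (r−1)/(r+1) and 1−S/L = (r−1)/r; the test
suite cross-checks both routes to 1e-12, so the indices cannot drift apart
through refactoring.

**Levan classes.** The arm-ratio ranges are m (1.0–1.7), sm (1.7–3.0),
st (3.0–7.0), t (> 7.0). Published formulae also contain *compound*
classes (m–sm, sm–st, st–t) without a stated rule. `classify_levan()`
assigns a compound label when r lies within a relative band around a
boundary, `|r − b| ≤ tol·b`, default `tol = 0.05` (so the sm–st band is
3.0 ± 0.15). A band is the simplest deterministic rule that reproduces
compound labels; the tolerance is configurable because it is a convention,
not a measurement. Classification is monotone in r by construction, and r
(not CI) is the single source of truth, avoiding edge disagreements
between the two equivalent parameterisations.

**Bimodal partition.** Default `fixed_count(4)` when x = 11 (the
genus-typical 4 + 7 structure); otherwise the split at the largest
adjacent gap in sorted lengths. The largest-gap method needs genuinely
bimodal data: simulations show complete recovery of cluster membership
once clusters are separated by about 9–10 within-cluster standard
deviations (and, for the structured 11-chromosome template, at 3 %
multiplicative length noise); at 5 SD separation misassignment is common
(~20 %). The fixed-count default is therefore the right choice whenever
the complement structure is known.

## Feulgen calibration and downsizing

`calibrate_2c()` converts arbitrary absorbance units to picograms through
the ratio of sample to standard means, with *Allium cepa* 'Ailsa Craig'
(2C = 33.55 pg) as the default standard. The standard error is the delta
method applied to the sample mean only; the standard mean is treated as a
fixed calibration constant, matching how per-accession SEs are reported in
practice. The simulation suite verifies the consequences honestly: with a
large standard batch the ±1.96 SE interval covers the truth at the nominal
rate (93–97 % over 1000 seeds), while a small standard batch adds
calibration error the reported SE deliberately excludes.

`one_cx()` reports 2C/ploidy at 2 decimals with half-away-from-zero
rounding (the convention of C-value tables; note that published tables
round exact halves inconsistently, so exact-half cases are excluded from
comparisons). `downsizing_table()` takes unweighted per-ploidy species
means of 1Cx and the percent decrease between consecutive levels —
unweighted because that is the arithmetic that reproduces the printed
consecutive-level decreases from printed values.

## The 2C-on-ploidy model

`fit_2c_on_ploidy()` fits 2C = a + b·x by weighted least squares, one
point per accession. Weighting by nuclei measured is supported, but the
default is equal weights: per-accession nucleus counts are generally not
published, and with equal weights the published slope is reproduced at
1 decimal (8.9 pg per genome copy on the packaged 18-accession fixture).
The weighted R² is 1 − SSE_w/SST_w about the weighted mean, the standard
WLS convention. Rearranging gives the 1Cx hyperbola
`1Cx(x) = a/x + b` (`hyperbola_from_fit()`): for a > 0 it decreases
monotonically to the asymptote b, the per-copy DNA amount at high ploidy —
downsizing levelling off. The no-downsizing reference
(`extrapolated_diploid_line()`) is the line through the origin with slope
equal to half the diploid mean 2C; the fitted slope being strictly gentler
than that reference is the regression's downsizing signature.

## Group contrasts

Replicate 1Cx values are compared by fixed-effects one-way ANOVA
(`anova_oneway()`, computed through `lm`), unprotected Fisher LSD
pairwise contrasts (`fisher_lsd()`) and an insert-and-absorb compact
letter display (`compact_letter_display()`). Although mixed models are
sometimes mentioned for such designs, a single F statistic plus LSD
letters is a fixed-effects analysis, and that is what is implemented — no
random-effect structure is identifiable from a published letter column.
The letter algorithm guarantees its contract — two groups share a letter
iff they are not significantly different — and the test suite re-verifies
the contract exhaustively on every output rather than trusting the
algorithm. Ties in means are broken by group label, making the display
deterministic. All tests are two-sided with default alpha 0.05.

Degenerate inputs are defined, not left to floating-point chance: if all
observations are identical, F = 0 and p = 1 (an `lm`-based F on a
numerically perfect fit is noise); zero within-group variance with
distinct means gives F = Inf, p = 0.

## What the generators simulate — and what they do not

`hippeastrum_template()` encodes the canonical complement: 4 short
chromosomes at CI 45 holding ~24 % of complement length, 7 long
chromosomes whose mean CI is ~26 / ~23 / ~20 at the low / mid / high
asymmetry levels, spanning the observed diploid range.
`simulate_metaphases()` applies a lognormal per-plate condensation factor
(default sigma 0.1) and multiplicative per-arm noise (default CV 3 %;
3–5 % makes the published SEs plausible — the true measurement CV is not
derivable from published tables). Noise is multiplicative because
microscopy measurement error scales with length, and because it preserves
proportional-change structure. `simulate_densitometry()` draws normal
readings with fractional SD `cv` around means proportional to the true 2C
(25–50 nuclei per accession is the realistic design);
`simulate_study()` draws normal 1Cx replicates around recorded species
means. All generators are pure functions of (parameters, seed).

What passing simulation tests show is that the *pipeline arithmetic* is
correct and stable under the stated noise model. They do not show that
real chromosome measurements have independent multiplicative errors, that
real Feulgen readings are normal, or that staining artefacts are absent —
karyotype-level systematic errors (condensation gradients within a plate,
overlapping chromosomes, stoichiometric staining error) are outside the
noise model.

## Problem sizes and determinism

The shipped tests use 3–10 plates per simulated accession, 25–40 nuclei
per densitometry batch, 100-seed letter-stability loops, a 1000-seed
coverage loop and 200-replicate partition oracles; the full suite runs in
a few seconds. Every stochastic test fixes its seed; the report pipeline
is byte-deterministic under a fixed configuration.

## Known discrepancies in the packaged summary

The packaged 18-accession fixture preserves printed values verbatim,
including their internal inconsistencies, which are flagged rather than
corrected:

* *H. cybister* (5x): printed 2C/ploidy = 56.35/5 = 11.27 pg ≠ printed
  1Cx 11.20 pg (`c1x_consistent = FALSE`; the other 17 rows agree within
  0.01 pg).
* *H. machupijchense*: printed A2 = 0.30 vs CV_CL = 30.56 — 0.01 beyond
  2-dp rounding slack; the other 13 printed pairs agree within slack.
* The published regression intercept (13.6) and R² (95 %) presumably used
  nucleus-count weights that are not published per accession; equal
  weights reproduce the slope (8.9) but give intercept 12.79 and R² 0.97.
  Only the slope is treated as reproducible.
* The published diploid-to-triploid downsizing of 16.77 % implies a
  diploid mean 1Cx of ~15.50 pg, not recoverable from the nine tabulated
  diploid 1Cx values (which give 15.27 pg and a 15.53 % decrease); the
  diploid set behind the printed figure evidently included accessions
  whose values are not tabulated. The package reports the
  table-derived value.
* The published F = 427.44 for the 1Cx ANOVA depends on raw replicate
  values that are not published; it is documented here, not asserted.

## Worked example

```{r example}
sp <- hippeastrum_species()
fit <- fit_2c_on_ploidy(sp$ploidy, sp$c2_pg)
fit
downsizing_table(sp)

tpl <- hippeastrum_template("mid")
plates <- simulate_metaphases(tpl, ploidy = 2, k_plates = 10,
                              arm_cv = 0.03, seed = 1)
karyotype_metrics(average_karyotype(plates, ploidy = 2, x = 11))
```

## Limitations

* Chromosome segmentation from micrographs is out of scope; the pipeline
  starts at measurement tables.
* One point per accession in the regression: accession-level replicate
  structure (multiple plants, plates) is not modelled.
* No phylogenetic correction: accessions are treated as independent
  points, which overstates precision when related taxa share history.
* The compound-class band is a convention; different tolerances can move
  boundary chromosomes between e.g. sm and sm–st without any change in
  the data.
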