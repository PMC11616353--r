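---
title: "Isolating X-borne familial risk from sex-by-lineage proband counts"
author: "XLinkRisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating X-borne familial risk from sex-by-lineage proband counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(XLinkRisk)
```

## The problem and the model

Familial aggregation of a late-onset disease such as Alzheimer's disease
tells us that risk is transmitted within families, but not on which
chromosomes it travels. XLinkRisk implements a design that uses nothing
more than the sex of affected probands and the side (paternal vs.
maternal) of their unilateral family history to isolate the component of
lineage-borne genetic risk carried by the X chromosome.

The logic is Mendelian bookkeeping. Every proband inherits the 22
autosomes from both parents, so autosomal risk flows through every cell of
the sex-by-lineage cross-classification. A female proband receives an X
chromosome from each parent, so X-borne risk reaches her from either side.
A male proband receives his single X from his mother: X-borne risk cannot
reach him through a paternal family history. The male/paternal cell is
therefore the one cell closed to the X channel (and the only cell open to
father-to-son Y transmission). `openChannels()` encodes exactly this map.

Writing $a, b$ for affected female probands with paternal and maternal
lineage and $c, d$ for the male counterparts, the package's core statistic
is the odds ratio

$$\mathrm{OR} = \frac{a/b}{c/d},$$

and the estimated proportion of lineage-borne genetic risk residing on the
X chromosome is

$$\frac{\mathrm{OR} - 1}{\mathrm{OR}} \times 100\%.$$

An OR of 1 means no X-borne signal; 1.2 puts 17% of the risk on the X;
1.33 puts 25% there. Values below 1 are reported signed, flagged
"no X-mediated risk detected", rather than clamped: a deficit is read as a
null result, not an impossibility.

Why a ratio of ratios? Anything that multiplies an entire row (a
sex-specific ascertainment rate, the higher background prevalence in
women) or an entire column (a lineage-side reporting bias, a maternal
mitochondrial or gestational effect hitting both sexes) cancels between
numerator and denominator. This cancellation is an algebraic fact about
the statistic; whether real confounders act multiplicatively on cells is
an assumption, and the simulator below exists to state it precisely and
test its consequences.

### Assumptions

* **Rare disease.** The odds ratio approximates a relative risk only when
  per-cell affection probabilities are small.
* **Unilateral lineage.** Each proband has disease history on exactly one
  parental side. The type system enforces this: records carry one
  `lineage`, and the CSV reader rejects rows labelled anything else
  (including "both"). Where a data source cannot exclude bilateral
  histories, their inclusion dilutes the contrast and biases the OR toward
  1; the package cannot correct this, only document it.
* **Negligible Y-borne risk.** The male/paternal cell is treated as closed
  to sex-chromosome risk. If the Y in fact carries risk `rrY`, the
  estimand shifts from `rrX` to `rrX/rrY` (see the simulator's closed
  form); the Y-violation experiment below shows the bias direction.
* **Counts are proband-constellation pairs.** A proband may appear under
  several family-history constellations; no deduplication is attempted,
  matching how the source tables are published.

## Inference choices

**Odds ratio.** The Wald interval on the log odds ratio:
$se = \sqrt{1/a + 1/b + 1/c + 1/d}$, bounds
$\exp(\log \mathrm{OR} \pm z_{\alpha/2}\, se)$, two-sided p from the
normal tail of $z = \log \mathrm{OR} / se$. This reproduces the published
intervals and p-values for both replication tables (0.54–1.91, p = 0.96
at 2 dp for the 175-proband table; 0.77–1.13, p = 0.48 for the
1850-proband table). One rendering caveat: the 175-proband point estimate
is $(37/67)/(25/46) = 1.0161$, which rounds to 1.02 while the source
prints 1.01 — consistent with truncation in the original calculator
display. The package always reports full precision in JSON and
conventional rounding (2 dp) in rendered views.

**Zero cells.** A zero cell makes the Wald log-OR undefined. The default
is a hard error; `correct = TRUE` opts into the Haldane–Anscombe +0.5
correction and flags the result, because silently shifting counts changes
the estimand.

**Observed/expected relative risk.** Cohort rates are per-death
proportions (disease deaths over all deaths in a sex x 5-year birth band x
birthplace stratum), not person-year rates — expected counts standardize
against a death-certificate population, which differs from a conventional
SIR and is documented on `cohortRates()`. The interval treats the observed
count as Poisson and uses the exact (Garwood) interval from chi-square
quantiles, divided by the expected count. The upstream source attributes
its intervals to Agresti without naming a specific construction; the
Garwood interval was adopted because it reproduces the published bounds at 2 dp
for ten of the twelve rows, including every row used in the acceptance
checks (e.g. 1.02–1.21 for 582/523.37, 1.11–2.74 for 21/11.7); the
remaining two (26/25.0 and 17/15.5) differ by one unit in the last printed
digit of the upper bound, and one published row (25/17.04, RR printed
1.44) is arithmetically inconsistent with its own observed/expected pair.
The p-value is the exact Poisson two-sided test (summing probabilities of
outcomes no more likely than the observed count); `pMethod = "midp"` and
`"normal"` ($z = (O-E)/\sqrt E$) are provided for sensitivity analysis
because the upstream p-values are reproducible only approximately.

**Numerics.** Equal-probability ties in the exact test are detected with
a relative tolerance of 1e-7 so the test is exact at the null
(observed = expected gives p = 1). Degenerate inputs fail loudly:
expected <= 0, negative or fractional counts, zero-death strata that a
constellation references.

## The synthetic population generator

`SimConfig`/`simulatePopulation()` generate the one data structure the
estimator assumes: probands with exactly one risk-bearing lineage side.
Each record draws sex ~ Bernoulli(`pFemale`), lineage ~
Bernoulli(`pMaternal`) and an affected flag with probability

```
baselineRate x rrAutosomal
            x rrX   (where the X channel is open)
            x rrY   (male/paternal only)
            x maternalEffect (maternal-lineage cells)
```

The central closed form — proved in `cellProbabilities()` and tested over
random configurations — is that the odds ratio of the four cell
probabilities equals `rrX/rrY` exactly, independent of the priors, the
baseline rate, the autosomal component and the maternal multiplier. That
makes the estimand explicit: the lineage OR estimates `rrX` only under
the negligible-Y assumption, and `rrX/rrY` otherwise.

Defaults were chosen once as the regime the method targets: a rare
disease (`baselineRate = 0.01`), a real familial autosomal component
(`rrAutosomal = 2`), sex- and lineage-balanced sampling
(`pFemale = pMaternal = 0.5`), no X or Y effect (`rrX = rrY = 1`), and
`nProbands = 2e5` — large enough that a typical replicate has a few
hundred affected probands per cell, the scale of the larger replication
table. The seed is mandatory and fully determines the output;
`recoveryExperiment()` derives replicate seeds as master seed + replicate
counter, so experiments are reproducible and trivially parallelizable.
Replicates that land a zero cell are excluded and their rate reported.

What the generator does *not* emulate: pedigree structure (lineage is
assigned, not derived from simulated genealogy), diploid genotypes,
X-inactivation, imprinting mechanics, mosaic Y loss, age structure,
competing mortality and ascertainment through death certificates. Passing
recovery tests therefore show that the estimator is consistent and its
intervals calibrated *under the multiplicative channel model* — they say
nothing about incidence-vs-prevalence distortions in real registry data,
which is precisely the kind of limitation a null replication in a
deceased population cannot escape.

## Experiments the package ships as tests

* **Parameter recovery.** `rrX = 1.25`, 200 replicates of 200,000
  probands: the median OR lands within Monte-Carlo error of 1.25 and the
  nominal 95% interval covers at the binomial-error rate. The problem
  sizes were picked so a typical cell holds hundreds of affected probands,
  matching the replication-table scale while keeping the full suite fast.
* **Y-assumption violation.** `rrX = 1, rrY = 1.3`: the median OR
  concentrates on $1/1.3 \approx 0.77$ — a real Y-borne risk masquerades
  as an X deficit, the documented bias direction.
* **Oracle equivalence.** The chi-square-quantile Poisson interval equals
  direct CDF inversion (uniroot on `ppois`) to 1e-6 for observed counts
  1..500; Wald p-values equal numerically integrated normal tails to
  1e-10.

## Worked example

```{r example}
sdr <- readCountTable(xlinkFixture("table4_sdr.csv"))
sdr
oddsRatio(sdr)
res <- oddsRatio(readCountTable(xlinkFixture("table5_tdr.csv")))
round(xProportion(res))
relativeRisk(582, 523.37, label = ">=1 maternal first cousin (female)")
```

## Known limitations

* The OR confidence interval is the large-sample Wald interval; with very
  sparse cells it is anti-conservative, and no exact (conditional)
  alternative is offered because the replication target used the Wald
  form.
* No pooling across tables is provided: combining analyses of very
  different sizes was deliberately declined in the source analysis, and
  meta-analysis is out of scope.
* The familial-RR machinery takes published cohort counts at face value;
  it cannot detect internal inconsistencies in a source table beyond
  flagging that observed/expected disagrees with a printed ratio.
* No multiple-testing adjustment across constellations — the published
  intervals are unadjusted, and the package mirrors that.
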