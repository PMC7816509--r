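---
title: "Scoring the resistance to damage of insecticidal nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the resistance to damage of insecticidal nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llindur)
```

## The problem

Long-lasting insecticidal nets (LLINs) fail in the field mostly through
mechanical damage: yarns snag on rough objects and break, the fabric bursts
when pulled over a small contact area, abrasion wears it through, and an
initial yarn break can enlarge into a large hole by laddering (a run of
dropped loops), unravelling, or tearing. A suite of four laboratory textile
tests quantifies these mechanisms for a new product: mean bursting strength
(kPa), mean snag strength (N), abrasion endurance (rubs to failure), and a
hole-enlargement test whose outcome is a final hole size (mm) plus the type
of secondary damage observed. `llindur` condenses the four values into one
resistance-to-damage (RD) score on a 0–100 scale, computable before a single
net is distributed.

## The two scoring algorithms

**Method 1 (proximity to aspirational values).** Each parameter contributes
a quarter of the scale in proportion to its aspirational target:

$$\mathrm{RD} = \frac{\lambda_B}{\eta_B}\cdot 25 +
               \frac{\lambda_S}{\eta_S}\cdot 25 +
               \frac{\lambda_A}{\eta_A}\cdot 25 +
               \frac{\sigma_H}{4}$$

where $\lambda$ are the measured values, $\eta$ the aspirational values, and
$\sigma_H \in (0, 100]$ the hole-enlargement resistance score. The score is
deliberately *not* clamped: a product that exceeds a target scores above 100
on that term, which rewards innovation beyond the targets.

$\sigma_H$ is a strict product of a base score for the end-hole-size band
(100 for at most 5 mm, 80 for 6–20 mm, 40 for 21 mm and larger) and a
damage-type multiplier (none 1.0, laddering 0.8, unravelling 0.5, tearing
combined with laddering or unravelling 0.4). The multiplicative form
reproduces all twelve cells of the published lookup table and makes the
monotonicity of the score in both coordinates structural rather than
incidental.

**Method 2 (KPI score matrix).** Each numeric parameter is binned into a
tier of a score matrix; bursting and snag strength have eleven tiers scored
$1, 2.5, 5, \dots, 25$, abrasion nine tiers scored
$1, 3, 6, 9, 13, 16, 19, 22, 25$. The hole-enlargement term is a banded
score (25 / 20 / 10 for the three end-size bands) minus a secondary-damage
penalty $\rho_H = \text{penalty} \times \sigma_H / 100$ with penalties 10
(laddering), 20 (unravelling), 30 (tearing combined):

$$\mathrm{RD} = \sigma_B + \sigma_S + \sigma_A + (\sigma_H - \rho_H).$$

The maximum attainable total is exactly 100; the minimum over valid inputs
is $1 + 1 + 1 + (10 - 3) = 10$. Because tier scores are flat within a tier,
Method 2 cannot distinguish, say, 40 N from 59 N of snag strength — one
reason Method 1 is the recommended default, with Method 2 retained for
KPI-style reporting.

### Aspirational values and their human-factors basis

The default targets are $\eta_B = 700$ kPa, $\eta_S = 200$ N,
$\eta_A = 400$ rubs, and a hole-enlargement score of 100 (final hole at most
5 mm, no secondary damage). They derive from what users can physically exert
on a net. The packaged reference tables (`reference_forces()`,
`body_weights()`) hold the maximal isometric forces by activity (e.g. 75 N
for a seated one-arm downward pull, professional population) and the
explosive pulling forces (up to 308 N overhand for males aged 21–60,
measured on a population heavier than typical net users). Mapping forces to
the bursting scale uses the standard 7.3 cm² burst diaphragm:
`force_to_pressure(308, 7.3)` ≈ 422 kPa, `force_to_pressure(500, 7.3)` ≈
685 kPa, and the same 308 N over a 1 cm² corner exceeds 3000 kPa — hence an
aspirational bursting strength of 700 kPa rather than the 274 kPa that a
200 N pull over the full diaphragm would suggest. Conversions return full
precision; published reference figures mix nearest-integer rounding and
truncation, so comparisons in the tests use a ±1 kPa tolerance.

### Tier-boundary conventions

The published score matrix prints integer-closed ranges ("250–299",
"300–349"). To score real-valued inputs, tiers are implemented as
contiguous half-open intervals $[\ell_k, \ell_{k+1})$ on the lower edges
(bursting: 250, 300, …, 700 kPa; snag: 20, 40, …, 200 N), values below the
first edge taking the minimum score 1. The abrasion row is printed with
gaps ("25–50", "75–100", …, then bare edges 250, 300, 350): the only
gap-free monotone reading is a greatest-lower-bound rule, so the lower
edges are 25, 75, 125, 175, 250, 300, 350, 400 and a value inside a printed
gap (e.g. 60 rubs, or 249 rubs) takes the score of the tier below it. The
end-hole bands are $\le 5$ mm, $(5, 20]$ mm, $> 20$ mm, consistent with the
WHO convention of recording holes from 5 mm.

## The WHO proportionate hole index

Field physical integrity uses the WHO four-band hole census: size 1
(0.5–2 cm diameter), size 2 (to 10 cm), size 3 (to 25 cm), size 4 (larger;
assumed diameter 30 cm). The hole index is the weighted count sum

$$H = 1\cdot N_1 + 23\cdot N_2 + 196\cdot N_3 + 576\cdot N_4 ,$$

the weights being each band's assumed hole area relative to a size-1 hole.
Two conventions matter and are fixed here:

- **Weights use the exact radius ratio** $(r_k / r_1)^2$, not the printed
  rounded area divided by the printed size-1 area: $706.95 / 1.23 = 574.8$
  would give 575, while $(15/0.625)^2 = 24^2 = 576$ matches the published
  weight exactly (and $14^2 = 196$ for size 3; size 2 rounds from 23.04).
- **Areas are reported with $\pi = 3.142$** by default, which reproduces the
  conventionally printed values (28.28, 240.56, 706.95 cm²); exact $\pi$ is
  available via the `pi_value` argument and affects reported areas only,
  never the weights.

Printed band boundaries leave small gaps (a 2.3 cm hole falls between
"0.5–2" and "2.5–10"); classification uses half-open intervals
$(2, 10]$, $(10, 25]$, $(25, \infty)$ so every diameter at or above the
0.5 cm recording threshold classifies uniquely. Holes below 0.5 cm are a
validation error, not silently dropped.

Per-net indices are aggregated to brand level by the arithmetic mean
(`phi_summary()`); the aggregation level is a package choice — the method's
description does not fix one — and the mean is the natural unbiased choice
for comparing brands surveyed with different numbers of nets. Attribution
of holes to mechanical (versus cut, rodent, thermal) damage is upstream
forensic work: this package never filters hole records.

## Association statistics

`pearson_association()` relates lab RD to field hole index: squared Pearson
correlation, the two-sided p-value from the correlation t-test on $n-2$
degrees of freedom (identical to the regression-slope test in simple
regression), and the OLS line of PHI on RD. Raw values are used — no
transform — since the relationship of interest is the reported scatterplot
association. `method_agreement()` additionally reports the Spearman rank
correlation between Method 1 and Method 2 totals, the natural measure of
"do the two algorithms order products the same way".

## The synthetic-data generator

No per-net laboratory values or field hole censuses are published alongside
the scoring method, so the package carries a first-class generator
(`synthetic_config()`, `generate_lab_panel()`, `generate_field_phi()`) that
emulates the study conditions: a 16-product panel (the size of the original
laboratory panel) with parameter values drawn uniformly over the score
matrix's full ranges — bursting 100–900 kPa, snag 10–250 N, abrasion 10–450
rubs — and hole-enlargement outcomes uniform over the 12 band-by-damage
cells. Field data follow a decreasing linear link from the Method 1 score,

$$\mathrm{PHI}_i = \max(0,\; a + b\,\mathrm{RD}_i) + \varepsilon_i,\qquad
  \varepsilon_i \sim N(0, \sigma^2),$$

with defaults $a = 800$, $b = -8$ (hole indices of a few hundred after 1–3
years of use, falling to near zero for the most robust products) and
$\sigma = 60$, which puts the generating $r^2$ near 0.8 for the default
panel spread — the order of magnitude of reported lab–field associations.
`noise_sd_for_r2()` computes the $\sigma$ that realises any target
generating $r^2$ for a given panel. The continuous PHI target is realised
as a band census by greedy decomposition, largest weight first with the
remainder in size-1 holes (`decompose_hole_index()`), which is exact after
integer rounding and mirrors the dominance of small holes in real surveys.
Months in use are drawn uniformly on 12–36.

Randomness is fully seed-driven: generation runs under a preserved-seed
scope, so the global RNG state is never touched, and the field-noise stream
uses `seed + 1` so lab and field draws are independent but jointly
reproducible. What the generator does **not** emulate: correlation between
the four lab parameters within a product (real fabrics are correlated
across tests), attrition and time-dynamics of damage accumulation, survey
measurement error in hole sizing, and non-mechanical damage. Passing tests
therefore demonstrate the correctness and calibration of the scoring
pipeline, not field validity of the RD–PHI link for any particular product.

## Numerical choices and degenerate inputs

- Scores are carried at full precision throughout; rounding (RD to one
  decimal place, hole indices to the nearest integer) happens only in
  `write_report()`, which writes byte-identical files for identical inputs.
- Tier lookups use `findInterval`, so a value exactly on a tier edge takes
  that tier's score; end-hole bands are closed on the right
  ($\le 5$, $\le 20$).
- Readers validate rather than coerce: a non-numeric cell, a negative
  count, an unknown damage label, or a hole diameter below 0.5 cm is an
  error naming the row and field. Secondary-damage labels are parsed
  case-insensitively, and "tearing+laddering" / "tearing+unravelling"
  collapse to the single tearing-combined category.
- Correlation requires $n \ge 3$ and non-constant inputs; both are errors
  otherwise, never `NA`s.
- A replicate protocol for abrasion (pass/fail out of 15 specimens) exists
  in field practice but has no defined mapping to a single rub count; the
  package takes one summary value per net and leaves replicate aggregation
  to the caller.

## Problem sizes in the test suite

Unit and property tests run on panels of 3–16 nets; calibration checks use
$n = 200$ (r² recovery within 0.08 of a generating 0.8) and 100 Monte-Carlo
replicates of 200-net panels for slope-recovery bias (|relative bias| <
15 %). These sizes give stable statistics while keeping the full suite
around a minute.

## Known limitations

- The tier-gap conventions (abrasion row, hole-band boundaries) are
  documented choices where the printed tables are ambiguous; scores for
  values inside printed gaps depend on them.
- Method 1 totals above 100 are meaningful ("exceeds aspiration") but not
  comparable to Method 2 totals, which are capped; compare rankings, not
  raw totals, across methods.
- The packaged human-factors constants are reference values for adult
  populations; they parameterise the default aspirational values and are
  not a biomechanical model.
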