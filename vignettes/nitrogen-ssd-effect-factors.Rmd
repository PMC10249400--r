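---
title: "Nitrogen SSDs and effect factors: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nitrogen SSDs and effect factors: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroSSD)
```

## The problem

Excess nitrogen stresses freshwater fish communities through
eutrophication-driven hypoxia and direct toxicity. Life-cycle impact
assessment (LCIA) summarises such stress in an *effect factor* (EF,
PDF·m³·kg⁻¹): how much of the regional species pool is potentially lost
per unit of nitrogen added to a water volume. nitroSSD derives these
factors from occurrence data: species sightings are matched to gridded
total-N concentrations, regional *species sensitivity distributions*
(SSDs) are fitted, and EFs are mapped at 0.5° resolution.

## The model

**Tolerance thresholds.** A species is assumed tolerant to nitrogen up
to the highest concentration at which it has been observed within an
ecological unit. The unit is a freshwater ecoregion, or — when an
ecoregion's data cannot support a regression — a coarser
realm–major-habitat-type (realm-MHT) unit. Thresholds at the coarser
level are re-derived by pooling the matched occurrences, not by
aggregating ecoregion thresholds, so a species seen in two ecoregions of
one realm-MHT contributes a single pooled maximum. Only the upper
tolerance threshold is modelled; a lower (nutrient-starvation)
threshold would imply a functionally different reference ecosystem and
is deliberately out of scope.

**Disappeared fractions.** For a region with $SR_{max}$ species, the
surviving richness at concentration level $C_j$ counts the species with
threshold $\ge C_j$, and the potentially disappeared fraction is
$PDF_j = 1 - SR_j / SR_{max}$. The levels are the region's sorted unique
thresholds, so the PDF at the smallest level is always 0 and the curve
is a non-decreasing step function (`build_pdf_points()`).

**The SSD.** A logistic in untransformed concentration is fitted by
least squares:
$$PDF(C) = \frac{1}{1 + e^{-(C - a)/b}},$$
where $a$ (mg/L) is the concentration at which half the species pool
has disappeared and $b$ (mg/L, $> 0$) controls the slope. The linear-
concentration parameterisation follows directly from reading $a$ as a
concentration; a `log10` switch fits on $\log_{10} C$ instead for
sensitivity analysis and is off by default. Regions with three or fewer
PDF–concentration pairs are recorded as `insufficient_data` and never
fitted.

**Diagnostics.** Fits are screened with the Cox–Snell pseudo-$R^2$
(likelihood ratio against an intercept-only null; under Gaussian
likelihoods with ML residual variance it reduces algebraically to
$1 - RSS_1/RSS_0$) and the NRMSE (RMS residual over the mean observed
PDF). A fit is *good* when pseudo-$R^2 > 0.5$ and NRMSE $< 1$. Poor
fits stay in the fit table — they are flagged, not deleted — but only
good fits feed the EF stage.

**Effect factors.** At each 0.5° cell the marginal EF is
$1000 \cdot dPDF/dC$ at the current state (year 2010), which for the
logistic is $1000 \cdot PDF(1-PDF)/b$; the factor 1000 converts L/mg to
m³/kg. The average EF is the secant against a reference state
(year 1900):
$$EF_{avg} = 1000\,\frac{PDF(C_{2010}) - PDF(C_{1900})}{C_{2010} - C_{1900}}.$$
Because the logistic is strictly increasing, the secant is positive for
either ordering of the two states. When the states differ by less than
a tolerance (default $10^{-12}$ mg/L) the analytic limit — the marginal
EF — is returned rather than an ill-conditioned quotient. Cells whose
current concentration is below the zero cutoff of $10^{-4}$ mg/L carry
no EF (reason `zero_N`); cells without a usable SSD at either hierarchy
level carry none either (`no_ssd`), and a missing reference field
blanks only the average EF (`undefined_ref`). The three reasons are
encoded separately rather than collapsed into one "no value"
convention, so users can distinguish a truly nitrogen-free cell from a
data gap.

**Hierarchical fallback.** The ecoregion-level fit is used when it is
both fitted and good; otherwise the realm-MHT fit is tried under the
same conditions. Extending the fallback to *poorly fitting* (not just
missing) ecoregion SSDs is a robustness choice: a regression that fails
its own screen is no better evidence than no regression.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| analysis window | 1970–2010 | years | period with both occurrence and concentration coverage |
| current-state year | 2010 | year | most recent modelled concentration field |
| reference year | 1900 | year | near-pristine nitrogen state |
| zero cutoff | 1e-4 | mg/L | measurement/model noise floor; below it a cell counts as nitrogen-free |
| eligibility | > 3 pairs | count | minimum information for a two-parameter fit |
| good fit | pseudo-R² > 0.5, NRMSE < 1 | — | regression screen before EF use |
| reference tolerance | 1e-12 | mg/L | switch to the analytic secant limit |

## The synthetic world

`generate_world()` fabricates the study's inputs with known truth so
every stage is testable offline. Per region, species thresholds are
drawn from the true logistic by inverse-CDF sampling
($T = a + b\,\ln(u/(1-u))$), redrawn when non-positive — conditional on
positivity the law stays logistic, with negligible distortion when
$a \gg b$. Each species gets one pixel-year inside its region's block
whose concentration equals its threshold exactly, and a sighting there,
so the max-observed rule recovers the truth by construction; extra
sightings (Poisson, mean 2 by default) land only where concentration
does not exceed the threshold. Ten percent of species are emitted under
synonyms and ten percent of records lack year or coordinates or fall
before the window, exercising the cleaning stage. Cells outside region
blocks carry zero concentration, exercising the `zero_N` semantics.

What the generator does **not** emulate: real spatial autocorrelation
of nutrient fields, observation bias toward accessible waters, range
shifts over time, taxonomic ambiguity beyond a clean synonym table, and
violations of the tolerance assumption itself (a species may simply
never have been observed near its true limit). Passing tests therefore
demonstrate correctness of the computational chain, not validity of the
max-observed-concentration tolerance model for real data.

## Numerical choices

* Least-squares start values: $a_0$ = the level whose observed PDF is
  nearest 0.5 (median level as fallback), $b_0$ = level range / 4;
  $b$ is bounded below by $10^{-9}$.
* The primary optimiser is Levenberg–Marquardt (`minpack.lm::nlsLM`);
  if it errors on degenerate or clipped step data the same SSR is
  minimised by Nelder–Mead on $(a, \log b)$. Optimiser failure is a
  recorded status, never an exception, so batch fitting always
  completes.
* Grid indexing is 0-based with half-open cells anchored at
  (−180°, +90°); the closed +180°/−90° edges clamp into the last cell.
  Pixel registration is a convention the package states rather than
  inherits, and tests pin it.
* Deduplication keys on (species, year, cell): exposure matching is at
  pixel-year resolution, so finer duplicates are information-free.
* Unmatched raw names are kept as their own accepted name; dropping
  them would silently shrink regional richness.
* Occurrences in zero-N pixels are excluded from threshold derivation:
  a zero threshold would contradict the tolerance logic.
* Rasters are read and written as plain-text ESRI ASCII grids, with
  explicit NODATA, so artifacts diff cleanly and need no binary I/O.

## Problem sizes

The test suite and worked examples run worlds of 1–3 regions with
50–500 species on grids of 12×12 to 24×24 cells over the 1970–2010
window, and one full 360×720 global grid for the zero-cutoff check —
sizes at which parameter recovery is already within 10% and the whole
suite completes in well under a minute. Parameter-recovery replication
uses 20 seeds at 500 species per region.

## Known limitations

* One concentration value per pixel-year is assumed; if the source
  fields represent another temporal statistic (annual means, maxima),
  thresholds inherit that meaning.
* No bootstrap confidence intervals on $(a, b)$, no alternative SSD
  forms (log-normal, Burr III), no hump-shaped lower-threshold
  response.
* EFs are one component of characterization factors; fate and exposure
  are out of scope, as are marine systems and phosphorus co-limitation.
* Records with valid data but years outside the window are clipped by
  the window rather than assumed absent from the source query.
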