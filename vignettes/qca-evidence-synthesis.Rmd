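---
title: "Configurational synthesis with qcasynth: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Configurational synthesis with qcasynth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcasynth)
```

## Why configurational analysis in a systematic review

When a review covers complex, rarely-replicated interventions, the question
is usually not "does it work on average" but "which combination of
components is sufficient for it to work well". Qualitative comparative
analysis (QCA) treats each study as a *case* described by *conditions*
(crisp 0/1 or fuzzy $[0,1]$ memberships) and asks which conjunctions of
conditions are (quasi-)sufficient for an outcome set, allowing several
distinct recipes to be sufficient at once. `qcasynth` implements the full
pipeline at review scale: calibration of effect sizes into an outcome set,
truth-table construction with fuzzy sufficiency consistency, contradiction
and remainder diagnostics, exact Boolean minimisation, and
coverage/consistency metrics, with a twelve-study breastfeeding-promotion
data set bundled as the worked example.

## Calibrating effect sizes into an outcome set

Review outcomes arrive as effect sizes, here odds ratios. The default
`calibration_scheme()` maps the logged OR onto four membership levels in
the set of *highly effective interventions*:

* full membership 1.0 when $\log \mathrm{OR} > 0.7$;
* more in than out, 0.666, when $0.4 < \log \mathrm{OR} \le 0.7$;
* more out than in, 0.333, when $0 < \log \mathrm{OR} \le 0.4$;
* fully out, 0.0, when $\log \mathrm{OR} \le 0$.

Boundary values belong to the lower level (the inequalities above are the
implemented ones); a tolerance of $10^{-9}$ on the log scale keeps values
that are analytically on a threshold from being pushed over it by floating
point. The log base is natural by default and configurable
(`"base10"`) for sensitivity analysis: natural log reproduces eight of the
twelve published outcome memberships of the bundled data set from their raw
ORs, more than any alternative, and the four remaining rows are consistent
with cluster-adjusted effect sizes that were never published — which is why
the bundled table stores the published fuzzy outcome column verbatim
instead of re-deriving it (see `?load_breastfeeding`). Membership levels
are deliberately discrete; the continuous logistic ("direct") calibration
method is out of scope. The crossover 0.5 is reserved: a case may never sit
exactly on it (see below).

```{r}
calibrate_effect(c(8.458, 0.463, 1.927))
```

## Set semantics and notation

Configurations use standard fuzzy-set semantics: conjunction is the
minimum over literals, negation is $1 - m$, disjunction is the maximum over
terms, and the empty conjunction is the universal set. Labels follow the
field's conventions — `*` for AND, `+` for OR, `~` for NOT — and always
print literals in declared condition order so reports are deterministic;
`parse_label()` inverts `format_label()`. (Published materials occasionally
misprint `*` for "or" in prose; the notation here is fixed as above.)

## The truth table

`build_truth_table()` enumerates all $2^k$ corners of the selected
conditions. A fuzzy case is assigned to the corner it is *more in than out*
of (membership $> 0.5$ per condition); a membership of exactly 0.5 is
undecidable and raises an error naming the case and condition, because no
calibration should leave a case on the crossover.

Row consistency is the fuzzy sufficiency measure
$$\mathrm{incl}(X \rightarrow Y) = \frac{\sum_i \min(x_i, y_i)}{\sum_i x_i},$$
computed over **all** cases, not only those assigned to the row: a case can
hold partial membership in a corner configuration it is not crisply
assigned to, and that partial membership legitimately dilutes or supports
the row's claim to sufficiency. This is the only formula that reproduces
the worked example's published consistency 0.923 for the
intensity-and-quality row, where one study assigned to a neighbouring
corner contributes 0.333. (Verbal definitions of consistency sometimes
given in the field — counting configuration-members among outcome-members —
actually describe necessity; the implemented denominator is
$\sum x_i$, which is the sufficiency reading and the one the published
numbers presuppose.) For crisp conditions and outcomes the formula reduces
to the familiar proportion of member studies showing the outcome.

Rows are classified in this order:

1. **remainder** — no case assigned; consistency undefined;
2. **positive** — consistency at or above the cutoff (default 0.75, the
   conventional floor below which sufficiency claims are hard to defend)
   and at least `frequency_cutoff` member cases (default 1: in a review
   every study counts);
3. **contradiction** — member cases straddle the 0.5 outcome crossover;
4. **negative** — otherwise.

Two deliberate choices sit here. First, graded memberships on the *same*
side of 0.5 are never a contradiction: a row holding members at 1.0 and
0.666 is a set of effective interventions of varying strength, not a
disagreement. Second, a straddling row that nevertheless clears the
consistency cutoff stays positive but is *flagged* in the `contradiction`
column (and in `quality_report()` warnings) rather than demoted. Demoting
it would let a single recalibrated borderline study silently rewrite the
solution; keeping the flag surfaces the tension while leaving the
consistency threshold — the field's actual gate — in charge.
`resolve_contradictions()` then offers the two computable resolutions
(recode-to-negative, or vote counting with ties conservatively negative);
the substantive resolutions (re-theorising conditions, re-coding studies)
are analyst moves that the diagnostics are designed to prompt.

`quality_report()` summarises limited diversity: the remainder fraction
(warning above 0.5, when the analysis risks describing individual studies),
whether both positive and negative rows exist, the maximum row occupancy,
and whether more than one row passes the cutoff.

## Minimisation

Positive rows are reduced with an exact Quine–McCluskey routine:
iterative merging of corners differing in one position yields all prime
implicants; essential primes are selected first and the residual cover is
solved by exhaustive (Petrick-style) search minimising the number of terms,
then total literals, with a lexicographic tie-break — so equal-cost
solutions are reported deterministically. Exactness is affordable because
$k$ is small in evidence synthesis (the worked example uses $k = 2$ and
$3$); the hard cap is $k \le 8$ (256 rows), which also keeps truth-table
reports readable.

Two remainder policies are provided. The **conservative** default treats
unobserved corners as false, so the solution is logically equivalent to the
positive-row set — the right default for reviews, where imputing outcomes
for intervention types nobody has trialled should be an explicit,
theory-driven act. The **parsimonious** policy admits remainders as
don't-cares, which can only shorten the solution; theory-guided
intermediate solutions with directional expectations are not implemented.

## Coverage and consistency of solutions

For solution membership $s_i$ and outcome $y_i$:
$$\mathrm{coverage} = \frac{\sum_i \min(s_i, y_i)}{\sum_i y_i}, \qquad
  \mathrm{consistency} = \frac{\sum_i \min(s_i, y_i)}{\sum_i s_i},$$
with the duality $\mathrm{cov}(X \rightarrow Y) =
\mathrm{incl}(Y \rightarrow X)$. Per component, `component_coverages()`
reports **both** raw coverage (the component alone against the outcome) and
unique coverage (the drop in solution coverage when the component is
removed). They are never merged into one column: when components overlap on
several studies — as the worked example's intensity and quality recipes do —
raw and unique coverage differ substantially, and a single mislabelled
column invites over-reading.

## The worked example and its documented discrepancies

```{r}
bf <- load_breastfeeding()
tt <- build_truth_table(bf, c("Intensity", "Quality"))
tt
minimise_truth_table(tt)
```

Several published analysis values for this data set are not reproducible
from the published case memberships under any standard consistency formula
(the pattern is consistent with some outcome memberships having been
revised between the data table and the analyses). The package computes, and
its tests assert, the values implied by the published memberships;
`breastfeeding_errata()` ships every affected quantity with the published
value, the recomputed value and the arithmetic. Two consequences are worth
flagging. First, the one-study corner (Intensity = 0, Quality = 1)
recomputes to 0.666 — below the 0.75 cutoff — so the full pipeline on the
as-published memberships returns the single-recipe solution `Intensity`;
the celebrated two-recipe solution `Intensity + Quality` arises from
`minimise()` on the three configurations that pass under the revised
(unpublished) memberships, and is tested in that form. Second, two corners
of the community-engagement model recompute to 0.800 and 0.777, above the
cutoff, so that model has three passing rows rather than the published one.

`sensitivity_recalibrate()` operationalises the borderline-study check: it
re-runs the whole analysis with one case's outcome moved (say from 0.666 to
0.333), and reports the per-corner consistency deltas, whether the solution
expression changed, and the coverage/consistency deltas. On the worked
example, moving the borderline study down leaves the solution unchanged
while strictly decreasing both solution coverage and consistency.

## The synthetic generator

`generate_studies()` emulates a review-sized study set with known
configurational structure: condition corner bits are independent
Bernoulli(0.5) (optionally with all $2^k$ corners laid down first, for
recovery tests); with probability `fuzziness` a bit is displayed as the
graded level on its own side of the crossover (1 → 0.666, 0 → 0.333); the
outcome is the case's membership in a generating DNF, flipped across 0.5
with probability `consistency_noise`. Defaults are noise-free and crisp.
Generation is deterministic given the spec's seed and leaves the caller's
RNG state untouched.

What the generator does *not* emulate: sampling error in effect estimates
(the pipeline consumes calibrated memberships, not standard errors),
correlated conditions, systematic missingness, or the selection processes
that shape which interventions ever get trialled. Passing recovery tests
therefore show that the algorithms are correct on their own terms, not that
real review data will be as well behaved; limited diversity and
contradictions in real data are the norm, which is why the diagnostics
exist.

## Numerical and testing choices

* All metrics are kept at full double precision internally; the display
  layer (reports, exports) rounds half-up to 3 decimals, matching the
  field's reporting convention.
* Truth-table rows are ordered by descending consistency, then descending
  case count, then corner bits, remainders last — a fixed order, since
  published tables are not consistent about ties.
* Missing memberships are rejected outright, never imputed: a silent
  imputation would corrupt every consistency sum downstream.
* The test suite checks minimisation against brute-force corner evaluation
  on 200 random tables ($k \le 5$), cover selection against exhaustive
  subset search, calibration against an interval-scan oracle on 1,000
  random ORs, and DNF recovery on 50 noise-free generated study sets —
  sizes chosen to exercise every code path at desk scale.

## Known limitations

PRI consistency and XY plots are not computed; necessity analysis is
deliberately absent (in a review one can rarely argue that no unobserved
path to the outcome exists); multi-value and temporal QCA variants and
coincidence analysis are out of scope; and truth-table analysis is capped
at eight conditions — beyond that, a review is better served by reducing
conditions than by a larger table.
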