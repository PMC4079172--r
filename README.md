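# qcasynth

Crisp- and fuzzy-set **qualitative comparative analysis (QCA)** for
systematic-review evidence synthesis.

When a review covers complex, multi-component interventions, meta-analytic
averages often cannot say *which combination of intervention components is
sufficient for a strong result*. QCA treats each study as a case with
memberships in condition sets (crisp 0/1 or fuzzy [0,1]) and searches for
configurations — conjunctions of conditions — that are (quasi-)sufficient
for an outcome set, allowing several distinct "recipes" to work at once.
`qcasynth` implements the whole pipeline for review-scale data:

* **Calibration** of raw odds ratios into a four-level fuzzy outcome set
  (full membership when log OR > 0.7; 0.666 when 0.4 < log OR ≤ 0.7;
  0.333 when 0 < log OR ≤ 0.4; fully out when log OR ≤ 0).
* **Fuzzy set algebra** with the field's notation (`*` = AND as minimum,
  `+` = OR as maximum, `~` = NOT as 1 − m), with label parsing/formatting.
* **Truth tables** over all 2^k configurations, scored with the fuzzy
  sufficiency consistency incl(X→Y) = Σᵢ min(xᵢ, yᵢ) / Σᵢ xᵢ, with
  contradiction and remainder (limited-diversity) diagnostics.
* **Exact Boolean minimisation** (Quine–McCluskey prime implicants with
  essential-prime/Petrick exact cover), conservative or parsimonious
  remainder policy.
* **Solution metrics**: coverage Σ min(s, y)/Σ y and consistency
  Σ min(s, y)/Σ s, with per-component raw *and* unique coverage.
* A bundled 12-study **breastfeeding-promotion worked example**, a
  **synthetic study-set generator** with known configurational structure,
  a **sensitivity re-run utility** for borderline calibrations, and a
  `qca` **command line** (`exec/qca`: `run`, `sensitivity`, `generate`).

## Worked example

```r
library(qcasynth)

bf <- load_breastfeeding()
calibrate_effect(c(8.458, 0.463, 1.927))
#> [1] 1.000 0.000 0.666

tt <- build_truth_table(bf, c("Intensity", "Quality"))
tt
#> Truth table: 2 conditions (Intensity, Quality), 4 rows, cutoff 0.75
#>   Intensity Quality n_cases consistency contradiction outcome_class
#> 1         1       0       1       1.000         FALSE      positive
#> 2         1       1       4       0.923         FALSE      positive
#> 3         0       1       1       0.666         FALSE      negative
#> 4         0       0       6       0.500          TRUE contradiction

minimise_truth_table(tt)
#> Solution (conservative policy): Intensity
#>  component raw_coverage unique_coverage consistency
#>  Intensity        0.560           0.560       0.933
#> Solution coverage 0.560, solution consistency 0.933
```

Reading the truth table: each row is one corner of the
intensity-by-quality space; a fuzzy case belongs to the corner it is more
in than out of (the study with quality 0.333 sits in corner (1,0) while
still contributing 0.333 membership to `Intensity*Quality`, which is why
that row's consistency is 0.923 rather than 1). Rows at or above the 0.75
consistency cutoff are positive and enter minimisation; the bottom row
mixes studies above and below the outcome crossover and is flagged
contradictory.

The two-recipe solution reported for this data set arises from the three
configurations that pass under the revised outcome memberships used in the
original analyses:

```r
pos <- rbind(c(1, 0), c(1, 1), c(0, 1))
colnames(pos) <- c("Intensity", "Quality")
format_label(minimise(pos)$expression, c("Intensity", "Quality"))
#> [1] "Intensity + Quality"

iq <- parse_label("Intensity + Quality", bf)
round(c(coverage    = solution_coverage(bf, iq),
        consistency = solution_consistency(bf, iq)), 3)
#>    coverage consistency
#>       0.640       0.889
```

Several published analysis values are not reproducible from the published
case memberships; `breastfeeding_errata()` documents every affected
quantity (published value, recomputed value, arithmetic). The package
computes and tests the recomputed values. See the vignette
`vignettes/qca-evidence-synthesis.Rmd` for the full account of the model,
the classification rules, and the design choices.

Borderline-calibration sensitivity:

```r
cfg <- run_config(bf, conditions = c("Intensity", "Quality"))
sensitivity_recalibrate(cfg, "Pugh (2002)", 0.333)
#> Sensitivity: Pugh (2002) outcome 0.666 -> 0.333
#> Solution: Intensity -> Intensity (unchanged)
#> Coverage delta -0.018, consistency delta -0.067
#> Row consistency changes:
#>  Intensity Quality original  altered     delta
#>          1       1 0.922917 0.846065 -0.076852
```

## Command line

```sh
Rscript exec/qca run --data studies.csv --schema schema.yaml \
    --conditions Intensity,Quality --cutoff 0.75 --out results/
Rscript exec/qca sensitivity --data studies.csv --schema schema.yaml \
    --conditions Intensity,Quality --case "Pugh (2002)" --set-outcome 0.333
Rscript exec/qca generate --k 3 --n 24 --dnf "A + B*~C" --seed 7 --out synth.csv
```

`run` writes a report bundle (data-table echo, truth table CSV, quality and
contradiction diagnostics, solution with metrics, a versioned JSON carrying
every reported number, and a timestamped run log); its exit status
distinguishes "solution found" (0) from "no row passed the cutoff" (3).

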