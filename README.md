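# regenscan

Detecting historic limb loss and quantifying the energetic trade-offs of
limb regeneration in crabs, from cross-sectional morphometric data.

## The problem

Crabs autotomize limbs to survive predation and regrow them gradually over
several molts. Missing limbs and limb buds are easy to count, but a limb
that was lost months ago and is, say, 60% regrown looks like an ordinary
limb — unless you weigh it. Most of the energy already spent on
regeneration hides in exactly those limbs. `regenscan` finds them and asks
what that spending costs the rest of the animal.

The core method, per limb position (1 = right claw, clockwise to 10 = left
claw):

1. fit the allometry `mass = a * CW^b` to present limbs by nonlinear least
   squares (`CW` = carapace width, mm);
2. flag limbs whose mass-scale residual falls below a negative cutoff
   (default −0.01 g; an automated largest-gap rule is also provided) as
   historically regenerating;
3. sum flagged limb masses into a per-crab **regeneration index** — a
   proxy for energy already allocated, justified by a linear energy–mass
   calibration of limb tissue (~20 kJ/g dry mass).

Trade-offs are then inferred with Gaussian additive models (mgcv):

```
organ mass ~ n_missing + bud_resid + regen_mass + s(CW) + s(julian_day)
```

where `bud_resid` is the bud count decorrelated from the missing count by
Poisson regression, the smooths absorb nonlinear size and season effects,
and optional squared terms are compared by AIC. Responses: ovary
(reproduction), hepatopancreas (energy storage), cardiac stomach (recent
feeding), and corrected body mass (growth; rest-of-body mass plus the
expected mass of absent limbs). Robust (sandwich) standard errors are
reported alongside model-based ones because organ-mass noise grows with
body size.

A synthetic-population generator with a ground-truth table
(`generate_population()`, `truth_assessment()`) makes every stage testable
without field data.

## Worked example

```r
library(regenscan)

cfg <- generator_config(seed = 42)   # the package's stated world, n = 736
pop <- generate_population(cfg)
pop
#> Synthetic crab population: 736 crabs
#>   true limb states: intact=5562, missing=195, bud=508, partial=1095

fits <- fit_all_limb_allometry(pop$crabs)
fits[[1]]
#> Limb 1 allometry: mass = 2.506e-05 * CW^2.9726 (n = 668, converged)

a <- assess_regeneration(pop$crabs, fits)        # fixed -0.01 g cutoff
a
#> Regeneration assessment: 736 crabs
#>   missing (no bud): 195 limbs; buds: 508; regenerating: 1524
#>   regen mass per crab: 308.3 +/- 411.6 mg

bud <- residualize_buds(a$assessment$n_buds, a$assessment$n_missing)
m <- fit_tradeoff_gam(a$assessment$ovary_mass_g, a$assessment,
                      bud$residuals, response_name = "ovary")
m
#> Trade-off GAM for ovary [linear]: n = 736, AIC = -2059.0, 91.8% dev
#>          term estimate      se     t        p se_robust
#> 1 (Intercept)  0.26956 0.00337 79.87 0.00e+00   0.00499
#> 2   n_missing -0.00939 0.00416 -2.26 2.41e-02   0.00357
#> 3   bud_resid  0.00215 0.00209  1.03 3.04e-01   0.00196
#> 4  regen_mass -0.03035 0.00725 -4.19 3.18e-05   0.01393
```

Reading the output: the fitted claw allometry recovers the generator's
cubic law; 1524 present limbs sit below the residual cutoff (the 1095
truly regenerating ones plus false positives among large crabs, where
residual spread exceeds the fixed cutoff); and ovary mass falls by about
30 mg per gram of regenerated limb mass carried. The injected effect is
−53 mg/g — the detected index dilutes the coefficient because false flags
add full-mass limbs to it (errors-in-variables). Fitting on the
truth-side predictors recovers −53 mg/g within 2 robust SE; that
attenuation story, and why recovery tests use `truth_assessment()`, is in
the methods vignette (`vignettes/regenscan-methods.Rmd`).

## Pipeline and command line

```r
run_pipeline(cfg, "out_dir")                 # simulate -> detect -> model
run_pipeline("crabs.csv", "out_dir")         # same, from a CSV
```

writes per-stage CSVs (allometry fits, per-crab assessments, injury
summaries, model coefficient tables, AIC comparison, recovery against
truth when simulated), a JSON run manifest with row accounting, and a log.
Identical seed and config give byte-identical CSVs. The installed
`exec/regenscan` script exposes the same stages:

```sh
regenscan simulate --config cfg.json --out simdir
regenscan run      --input crabs.csv --out rundir --cutoff -0.01 --method fixed
regenscan detect   --input crabs.csv --out detdir
```

Foreign column layouts are adapted with `--map columns.txt`
(`canonical=source` lines), e.g. `carapace_width_mm=cw`.

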