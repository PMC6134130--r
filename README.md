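# betaclock

Coupled β-cell circadian clock and glucose–insulin dynamics in R.

Nocturnal rodents whose food access is restricted to the rest (light)
phase invert their feeding rhythm but develop metabolic symptoms —
hypoinsulinemia and hyperglycemia — instead of simply living twelve hours
out of phase. `betaclock` implements a mechanistic explanation: the
pancreatic β-cell clock receives two conflicting zeitgebers (nutrient cues
that follow the feeding schedule, SCN-driven neural cues that follow the
light–dark cycle), the conflict twists the clock — *Per* follows food
almost fully while *Bmal1* shifts only partially — and the twist
desynchronises the two gates of insulin secretion.

The model couples a 9-component transcriptional–translational clock
(mRNA + protein for *Bmal1*, *Per*, *Cry*, *Rev-Erb*, plus a PER-CRY
complex) to a glucose–insulin module and a clock-controlled exocytosis
factor EXO, 13 ODEs in all plus a 2-equation food-intake subsystem.
Insulin obeys the coincidence-gated balance

    d[Ins]/dt = k_i · f_glu(glucose) · f_exo(EXO) − d_i · [Ins]

so high secretion requires glucose availability and exocytosis capacity
*simultaneously*. The glucose cue feeds *Per* transcription (strength
`c_glu`); the SCN cue feeds *Rev-Erb* transcription (strength `cneur`,
default 1.4336).

The package provides stiff integration to the entrained limit cycle
(compiled rhs via `deSolve`), peak-phase/circular-shift/amplitude metrics,
coincidence and food-anticipation indices, architecture ablations
(`no_central_clock`, `no_clock`), feeding-inversion and cue-strength
scans, Fourier interpolation of sparse time courses, a from-scratch
Hooke–Jeeves pattern-search fitter, and a seeded synthetic-data generator
for parameter-recovery testing.

## Worked example: inverting the feeding schedule

```r
library(betaclock)

p  <- beta_params()                                  # calibrated reference set
nf <- run_condition(p, food_shift = 0)               # nighttime feeding
df <- run_condition(p, food_shift = 12)              # daytime feeding

subset(condition_shift(nf$phase, df$phase),
       variable %in% bc_clock_mrnas())
#>     variable shift_h direction signed_h
#> 1 bmal1_mRNA   7.275   advance   -7.275
#> 3   per_mRNA  11.601   advance  -11.601
#> 5   cry_mRNA   7.129   advance   -7.129
#> 8   rev_mRNA   7.151   advance   -7.151
```

*Per* shifts by 11.6 h — it follows the inverted feeding schedule — while
*Bmal1*, *Cry* and *Rev-Erb* shift by only ~7 h: the differential phase
shift caused by the unshifted SCN cue. Downstream, the twist misaligns the
secretion gates and produces the metabolic syndrome:

```r
syndrome_report(nf$trajectory, df$trajectory)
#>           quantity value_a value_b  ratio
#> peak  insulin_peak  0.9950  0.8191 0.8232   # DF insulin peak −18%
#> mean  insulin_mean  0.3727  0.3657 0.9813
#> peak1 glucose_peak  9.7304 10.9354 1.1238   # DF glucose peak +12%
#> mean1 glucose_mean  5.8268  5.8554 1.0049

coincidence_index(nf$decomposition)   # 0.867
coincidence_index(df$decomposition)   # 0.751

nf$anticipation$rupture_detected      # TRUE  — pre-meal insulin rise
df$anticipation$rupture_detected      # FALSE — anticipation lost
```

Ablations isolate the mechanism: with the SCN rhythm replaced by its mean
(`run_condition(p, "no_central_clock", ...)`) every clock gene shifts by
exactly 12 h and insulin is unchanged; with clock control of exocytosis
removed (`"no_clock"`) the metabolic variables become identical between
the two schedules up to a 12 h rotation.

A thin command-line layer wraps the same functions:

```r
betaclock_cli(c("experiment", "--name", "inversion", "--out", "out/"))
```

See the methods vignette (`vignettes/betaclock-methods.Rmd`) for the model
equations, design decisions, numerical choices, and known limitations.

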