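# motifEnrich

Decides whether a promoter region is non-randomly enriched in short,
degenerate transcription-factor binding motifs of the Churchill type
(consensus `NGGGNN`: any base, a G-triplet core, any two bases), and
whether its motifs are of higher binding quality than chance G-runs.
Intended for regulatory genomicists screening candidate target promoters
when the binding model is a small SELEX-derived position weight matrix
and the only honest baseline is the region's own base composition.

## The statistics at the core

Everything is compared against a **composition-matched null**: an
ensemble of random sequences with the same length *L* and mononucleotide
frequencies π as the region. Under that null the expected consensus
count is the closed form λ = (L − m + 1) · Π_j q_j (for `NGGGNN`,
λ = (L − 5) · p_G³). The package reports, per input sequence:

- the observed count against the simulated null: one-sample Z-test,
  z = (x − x̄)/s, with a one-sided (enrichment) headline p;
- a global enrichment test under a **compound-Poisson (Polya-Aeppli)**
  model of clumped counts — G-runs make overlapping hits arrive in
  clumps; the clump parameters are fitted to the exact finite-length
  mean and variance obtained by enumerating the pattern's self-overlap
  structure — cross-validated by a seeded Monte-Carlo tail;
- per-site quality as the log-likelihood ratio
  logL(s) = ln P(s | PWM) / P(s | π), compared between the region and the
  pooled null motifs by 1,000 replicated two-group Kruskal-Wallis rank
  tests and by a **Beta A/B test**: success = logL above the expected
  logL of a PWM-drawn site (= Σ_j KL(f_j ‖ π)); both success rates get
  Beta(0.35, 0.35)-prior posteriors and 100,000 posterior draws estimate
  P(rate_bio > rate_sim);
- a 150-nt sliding-window profile that localises enrichment peaks.

A first-class synthetic-data module generates promoter-like fixtures
with planted enrichment folds and motif clusters, so every stage is
testable without any external download.

## Worked example

```r
library(motifEnrich)

# a 4,662-bp synthetic promoter with two planted motif clusters at an
# overall enrichment fold of ~2, plus its composition and binding model
fx <- makeStudyLikePair(seed = 1)

cfg <- analysisConfig(nBackground = 2000, nKwReps = 200,
                      nAbDraws = 50000, seed = 1)
report <- runAnalysis(fx$sequence, fx$pwm, cfg)
report
```

```
EnrichmentReport for 1 sequence(s)
  synthetic_promoter: 129 hits | null 63.80 +/- 9.62 | z=6.78 (p=6.02e-12) | fold=2.00 (p_cp=1.78e-08) | P(bio>sim)=1.000
  seed: 1 | pattern: NGGGNN
```

The region carries 129 `NGGGNN` sites where its own composition predicts
~64 (null mean 63.80, SD 9.62): a 6.8-sigma excess, fold 2.00, with the
clump-corrected compound-Poisson tail at 1.8e-08. Site quality separates
too:

```r
r <- reportResults(report)[[1]]
r$threshold$value            # 3.993  (expected logL under the PWM)
r$successBio$rate            # 0.752  biological success rate
r$successSim$rate            # 0.302  pooled simulated success rate
r$windows[which.max(r$windows$count), ]
#  top 150-nt window: [4109, 4258], 12 hits, 2.01 expected
```

Three quarters of the biological sites beat the PWM-expectation logL
threshold versus ~30% of null motifs, so P(rate_bio > rate_sim) is at
the ceiling, and the densest window sits inside a planted cluster. With
`plantedFold = 1` fixtures the same pipeline stays quiet (uniform
one-sided p-values across seeds — see the test suite).

File-based inputs work the same way: `runAnalysis("region.fa",
"pwm.tsv", cfg, outDir = "out/")` writes `report.json`, a BED6 hit
track, the window-profile TSV and the null counts TSV. A small example
PWM ships in `inst/extdata/example_pwm.tsv`, and a thin command-line
wrapper in `inst/scripts/motif-enrichment.R` exposes `run`, `scan`,
`simulate-null` and `fixtures` subcommands.

## Documentation

The methods vignette (`vignettes/motif-enrichment-methods.Rmd`) gives
the full model description: null-model assumptions, the moment-matched
compound-Poisson derivation, threshold and prior choices, what the
synthetic generator does and does not emulate, and known limitations.
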