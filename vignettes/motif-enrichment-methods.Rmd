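---
title: "Promoter motif enrichment against composition-matched nulls: methods"
author: "motifEnrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter motif enrichment against composition-matched nulls: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the overall design

Given a promoter-scale nucleotide sequence, does it carry more short
transcription-factor binding motifs — and better-quality motifs — than its
own base composition predicts? The motivating case is the Churchill-type
zinc-finger activator, whose binding site is the degenerate consensus
`NGGGNN` (any base, three Gs, any two bases). Because the consensus is
dominated by a G-run, raw counts are extremely sensitive to G content, so
every comparison in this package is made against a *composition-matched*
null: an ensemble of random sequences with the same length and the same
mononucleotide frequencies as the region under study.

The pipeline (one call, `runAnalysis()`) chains:

1. composition profiling of the input region (`baseComposition()`);
2. simulation of the null ensemble (`simulateBackground()`);
3. consensus scanning of the region and of every ensemble member
   (`scanMotif()`, `motifCounts()`);
4. count-level inference: null summary and kernel density, one-sample
   Z-test, analytic expectation, compound-Poisson and Monte-Carlo global
   enrichment tests;
5. quality-level inference: per-site log-likelihood (logL) scoring against
   a position weight matrix (PWM), replicated Kruskal-Wallis rank tests,
   success classification, and a Monte-Carlo Beta A/B comparison of
   success rates;
6. a 150-nt sliding-window profile that localises the enrichment.

# The null model

The background is order-0: every position of every null sequence is drawn
i.i.d. from the region's A/C/G/T frequencies, computed over unambiguous
residues only (`N` is excluded from numerator and denominator, and a
consensus `N` never matches a literal `N` residue — the null simulator
emits only A/C/G/T, so matched composition must be over unambiguous
bases). We deliberately do not preserve dinucleotide structure: the
protocol this implements matches length and mononucleotide composition
only, and the analytic expectations below are exact under that model. This
is a known limitation — CpG depletion and poly-purine tracts in real
promoters are not reproduced — and is the main caveat when interpreting a
significant result on real data.

Under this model the expected consensus count in a sequence of length
$L$ is

$$\lambda = (L - m + 1) \prod_{j=1}^{m} q_j,$$

with $m$ the pattern width and $q_j$ the total background frequency of
the bases allowed at pattern position $j$; for `NGGGNN`,
$\lambda = (L-5)\,p_G^3$. `expectedMotifCount()` implements this closed
form and the test suite verifies that simulated ensembles converge to it.

# Site quality: the logL ratio

Each located site $s = s_1 \ldots s_m$ is scored

$$\mathrm{logL}(s) \;=\; \ln \frac{P(s \mid \mathrm{PWM})}{P(s \mid \mathrm{bg})}
 \;=\; \sum_{j=1}^{m} \ln \frac{f_{j,s_j}}{\pi_{s_j}},$$

where $f_{j,\cdot}$ are the PWM column frequencies and $\pi$ the
background composition. Natural log is the default; `logl_base` in the
configuration switches to base 2 or 10 for replication attempts against
tools that report those. A pseudocount (default $10^{-4}$, applied as
$(f + c)/(1 + 4c)$ per cell at ingest) keeps every stored frequency
positive so logL is finite for all A/C/G/T sites; at this magnitude it
does not materially shift frequencies read from a typical selection-assay
table of tens of sequences.

A site is a binding **success** when its logL strictly exceeds a
threshold; ties count as failures. With only a published PWM available,
the default threshold (`successThreshold()`, method `"pwm-expectation"`)
is the expected logL of a site drawn from the PWM itself,

$$\tau = \mathbb{E}_{s \sim \mathrm{PWM}}[\mathrm{logL}(s)]
 = \sum_j \mathrm{KL}(f_j \,\|\, \pi),$$

the per-position Kullback-Leibler divergence summed over positions (the
$4^m$-site expectation factorises). By Gibbs' inequality $\tau \ge 0$,
with equality only when the PWM equals the background everywhere — both
property-tested. When an explicit list of selection-experiment sites is
available, method `"explicit"` accepts the cutoff computed from it
instead; `samplePWMSites()` plus `logLNormality()` (Shapiro-Wilk) provide
the reference logL sample and its normality check.

# Count-level inference

**One-sample Z-test.** The single observed count $x$ is standardised
against the simulated null: $z = (x - \bar{x})/s$ with $\bar{x}, s$ the
ensemble mean and sample SD ($n-1$ denominator). The headline p-value is
one-sided in the enrichment direction; the two-sided value is always
reported alongside. A flag switches to the $s/\sqrt{n}$ normalisation
(testing the simulated mean rather than the single observation); both
forms are reported in the literature and the package treats the
single-observation form as the scientifically meaningful default — the
question is whether one region is consistent with the null ensemble, not
whether the ensemble mean is known precisely.

**Compound-Poisson test.** `NGGGNN` overlaps itself: a run of $g \ge 3$
Gs yields $g-2$ overlapping hits, so counts are clumped and a plain
Poisson tail is anti-conservative. `compoundPoissonPValue()` models the
count as Polya-Aeppli: clumps arrive as a Poisson process, clump sizes
are geometric. The parameters are fitted to the *exact* first two moments
of the count, obtained by enumerating the pattern's self-overlap
structure: for each shift $d < m$ the conditional match probability
$\gamma_d$ is the product of per-position probabilities of the
intersected allowed sets (for `NGGGNN`: $\gamma_1 = p_G$,
$\gamma_2 = p_G^2$, and $\gamma_d = q$ for core-disjoint shifts), giving

$$V = Mq(1-q) + 2\sum_{d=1}^{m-1} (M-d)\, q(\gamma_d - q), \qquad
\rho = \frac{V - \lambda}{V + \lambda}, \qquad
\lambda_c = \lambda(1 - \rho),$$

with $M = L - m + 1$. The tail is evaluated exactly for that fitted
distribution by the Panjer recursion. For a pattern with no self-overlap
the variance drops just below the mean, $\rho$ is clipped to 0 and the
test reduces to the plain Poisson tail. Moment matching rather than a
fixed asymptotic continuation probability ($\rho \to p_G$ for long
sequences) was chosen because it absorbs the finite-length covariance
deficit; the Monte-Carlo cross-validation in the acceptance tests
(`mcCountPValue()`, add-one-corrected empirical tail, so never exactly 0)
agrees within $\max(0.005,\ 2\,\mathrm{SE})$ over a grid of
$p_G \in \{0.15, 0.25, 0.35\}$, $L \in \{1000, 4000\}$ and observations
at $\{1, 1.5, 2\}\times\lambda$. An exact finite-horizon transfer-matrix
p-value is deliberately out of scope.

The fold enrichment is reported as $x / \lambda$ with the *analytic*
denominator; the simulated mean is printed next to it so users can see
any discrepancy between the two expectations (tool chains that mix a
simulated denominator with a score-thresholded numerator produce folds
that are not mutually reproducible).

# Quality-level inference

**Kruskal-Wallis replicates.** All motifs of the null ensemble are pooled
and scored. Each of `n_kw_reps` (default 1000) replicates draws, without
replacement, a fresh pool subsample of the same size as the biological
collection and runs a two-group Kruskal-Wallis rank test (the two-group
case of the stated method, chi-square approximation with tie correction)
at `alpha` (default 0.05); the fraction of significant replicates is
reported. A calibration caveat found while validating: the biological
side is *one* fixed collection, and its overlapping hits share G-run
residues, so its logL values are correlated; against an i.i.d. pool
subsample this inflates the rejection rate above `alpha` even for a null
region (we measure roughly twice the nominal level). The calibration
tests therefore use exchangeable pool draws for the null case; on real
data the replicate fraction should be read as descriptive, not as a
calibrated test size.

**Beta A/B success-rate test.** Success counts on both sides get
independent Beta posteriors under a symmetric Beta(0.35, 0.35) prior (a
single-number Beta specification is read as equal shape parameters; both
shapes are configurable). `ab_beta_test()` draws `n_ab_draws` (default
100,000) posterior pairs and reports
$P(\text{rate}_\mathrm{bio} > \text{rate}_\mathrm{sim})$ — by
construction identical, up to measure-zero ties, to the fraction of draws
whose rate ratio exceeds 1, which is what the ratio ECDF displays. The
simulated side pools all ensemble motifs into one success count by
default (the only construction yielding a single comparable posterior); a
per-member mode, where each draw samples one ensemble member's posterior,
is provided because the ECDF phrasing of the source protocol admits that
reading too — neither is guessed to be "the" original. The deterministic
quadrature oracle `abPosteriorExact()` integrates
$\int f_\mathrm{bio}(x)\, F_\mathrm{sim}(x)\, dx$ to $10^{-6}$ and
anchors the Monte-Carlo implementation in the tests.

# Positional profile

`windowProfile()` slides a 150-nt window (step 1 by default — the
protocol states the width but not the step; `step = window` gives a
non-overlapping tiling) and assigns a hit to a window iff the whole site
fits inside it. Per window it reports the count, the closed-form
expectation $(w - m + 1)\prod_j q_j$, and an upper-tail Poisson p-value
at that expectation — a screening quantity (it ignores clumping), not a
multiplicity-corrected test.

# Coordinates and formats

In-package coordinates are Bioconductor-style 1-based closed intervals
(hits are `GRanges`, cluster intervals `IRanges`); BED export converts to
0-based half-open and maps logL affinely to the 0-1000 BED score (the map
is recorded in the track header). Overlapping occurrences are all counted
(a `GGGG` run is two sites) — the analytic expectation assumes
per-position counting. Scanning is sense-strand by default because the
consensus is non-palindromic and published counts of this kind are
single-stranded; `strands = "both"` scans the reverse complement and maps
hits back to plus-strand coordinates.

# The synthetic-data generator

`makeScenarioSequence()` emulates the statistical structure of the study
inputs: i.i.d. background at a stated composition (fixture default
$p_G = 0.247$, which at $L \approx 4340$ puts the null mean near 65
motifs per sequence — the regime of the motivating study), with consensus
sites `xGGGyz` overwritten at random positions until the realised count
reaches the background count plus $\mathrm{round}((\mathrm{fold}-1)\lambda)$.
Overwriting (not inserting) preserves length so the closed-form $\lambda$
stays valid; planting net of accidentally destroyed background hits keeps
the fold estimator unbiased while preserving background sampling noise.
Planted sites never overlap one another — random overlapping insertions
saturate near 0.14 hits/bp because later insertions destroy earlier
cores, well below the density a strong planted cluster needs — so interval
capacity is one site per 6 bp and exceeding it is an error.

`makeStudyLikePair()` builds a 4,662-bp promoter-like fixture with two
planted clusters (the "two enrichment peaks upstream of the first and
second exons" geometry) whose *measured* composition still implies
roughly half the observed count, i.e. fold about 2 under the profile an
analyst would actually compute from the sequence. That requires two
choices: a G-poorer generating composition ($p_G = 0.20$) and G-free,
C-biased flanks on planted sites, because planted G-cores feed back into
the measured $p_G$ cubically — planting composition-drawn flanks at a
generating-profile fold of 2 yields a measured-profile z of only about 3,
too weak to represent the study regime (z between 5 and 7.5). The
C-biased flanks also make planted sites higher-quality than chance hits
under the returned binding model, so the fixture exercises the A/B test
in its intended direction. What the fixture does *not* emulate: real
promoter dinucleotide structure, CpG islands, repeats, or the actual
(unpublished) PWM cell values — a passing pipeline on this fixture shows
the statistics recover planted truth under the package's own null, not
that any particular real promoter is enriched.

With `plantedFold = 1` the generator feeds the null-calibration tests:
one-sided Z p-values are approximately uniform across seeds and the A/B
posterior centres on 0.5.

# Numerical and reproducibility choices

- One top-level seed; every stochastic stage derives an independent
  substream from it (`seed`, stage label) so stages can be re-run in
  isolation and a cached null ensemble reproduces a fresh run exactly.
- Monte-Carlo count p-values use the $(1 + k)/(n + 1)$ correction.
- The Beta quadrature clips to $[0,1]$ and treats integration failure as
  an error rather than returning a default.
- Degenerate inputs error early: all-`N` sequences, constant samples for
  the KDE (without an explicit bandwidth) and Shapiro-Wilk, zero null SD,
  empty PWM columns.
- KDE bandwidth defaults to Silverman's rule-of-thumb on the null counts;
  the density is evaluated on a 512-point grid spanning
  $[\min - 3b,\ \max + 3b]$.
- Report JSON is written with stable key order and full-precision
  numbers: two identical invocations are byte-identical.

# Problem sizes in the shipped tests

The package defaults are the protocol scale (10,000 null sequences, 1,000
KW replicates, 100,000 A/B draws) and the acceptance script runs at that
scale. The unit-test suite runs the same code paths at reduced sizes
chosen as the smallest that keep the statistical assertions sharp:
ensembles of 150-2,000 members, 200-1,000 calibration replicates, 50
recovery replicates per planted fold, 200 seeds for the uniformity check.

# Known limitations

- Order-0 background only (a dinucleotide-preserving shuffle is a natural
  extension and deliberately not implemented here).
- The KW replicate fraction is not a calibrated test size for a single
  biological region (correlated overlapping hits; see above).
- The window-profile p-values are per-window Poisson screens, not
  clump-corrected or multiplicity-adjusted.
- The success threshold from the PWM expectation is a surrogate for the
  mean logL of real selection-assay sites; with the "explicit" method and
  an actual site list the two can differ.
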