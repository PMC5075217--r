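---
title: "Calling germline CNVs from multiplex-PCR amplicon coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling germline CNVs from multiplex-PCR amplicon coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplicnv)
```

## The problem

Targeted sequencing panels enriched by multiplex PCR give deep coverage of a
few genes, but the read count of each amplicon depends exponentially on its
amplification efficiency: the quantity of product after $c$ cycles follows

$$N = N_0 \, (1 + e)^c,$$

where $N_0$ is the template amount (what a copy-number variant changes) and
$e$ the efficiency. Small, uncontrollable shifts in reaction conditions move
$e$, so raw or library-size-normalised coverages are not comparable across
samples, and conventional read-depth CNV callers built for genome or exome
data break down on such panels. This package detects germline deletions and
duplications — down to single-exon events — by exploiting the one structure
multiplex PCR does preserve: subsets of amplicons respond to condition
shifts *together*, so their log coverages are strongly correlated across
samples of a run. Comparing an amplicon against its correlated partners
removes the shared amplification variation without any library-size
normalisation; what remains is shot noise plus any change in $N_0$.

Zygosity states act multiplicatively on $N_0$: 0.5 for a heterozygous
deletion, 1 for wild type, 1.5 for a heterozygous duplication, 2 for a
homozygous duplication. On the log scale (used throughout — it stabilises
the variance of the amplification process) these are additive shifts of
$\log 0.5$ and $\log 1.5$. Ploidies of three and above are all reported as
`DUP`: their prediction intervals overlap too much to separate. Homozygous
deletions are trivial — no template, (almost) no reads — and are handled by
quality control.

## Pipeline overview

One coverage matrix (amplicon × sample read counts) is one sequencing run
and is analysed on its own; runs are never pooled. `run_pipeline()` chains:

1. **Quality control** — low-read samples out, homozygous-deletion cells
   flagged and masked, under-covered and partnerless amplicons masked,
   irregular samples removed.
2. **Unsupervised caller** — per-amplicon, per-sample zygosity by robust
   regression against correlated partner amplicons.
3. **Control/test split** — samples with no outlying amplicon become the
   control set (or an a-priori control list is supplied).
4. **Supervised classifier** — site-level (exon-level) classification
   against per-amplicon copy-number models fitted on controls, with
   iterative control growth.
5. **Report** — consecutive same-state sites merge into runs; duplications
   confined to a single site are flagged `single_site_dup` and suppressed
   from the default report (the duplication and wild-type models overlap
   too much for a one-exon duplication to be trustworthy).

## Robust estimators

CNV carriers are exactly the outliers the statistics must survive, so every
location, scale, correlation and regression estimate is robust:

* **Sn scale** (Rousseeuw–Croux): $1.1926 \cdot c_n \cdot
  \mathrm{lomed}_i\, \mathrm{himed}_{j \ne i} |x_i - x_j|$, with the
  finite-sample factors $c_n$ for $n \le 9$ and $n/(n-0.9)$ for odd $n$.
  The inner high median is taken over the $n-1$ differences at rank
  $\lfloor (n-1)/2 \rfloor + 1$, the outer low median at rank
  $\lfloor (n+1)/2 \rfloor$; medians of even-length vectors elsewhere in
  the package average the two central order statistics. An $O(n \log n)$
  rank-selection path handles large vectors; both paths are tested against
  each other and against exhaustive enumeration.
* **Sn-correlation**: $r = (S_n^2(u) - S_n^2(v)) / (S_n^2(u) + S_n^2(v))$
  on the robust principal variables $u, v$ built from medians and MADs of
  the two vectors. Pairs with zero MAD are degenerate and excluded.
* **Theil–Sen regression**: slope = median of pairwise slopes (ties in $x$
  skipped), intercept = median of $y - \hat\beta x$, residual scale = Sn of
  the residuals. Its breakdown point, $1 - 1/\sqrt{2} \approx 29.3\,\%$, is
  what lets carrier samples sit in the fitting set (they are assumed to be
  at most 20 % of samples per site).
* **Hodges–Lehmann location**: median of all Walsh averages (singletons
  included).
* **Studentized residuals** use the standard internally-studentized form
  $\hat\varepsilon_i / (S_n \sqrt{1 - h_i})$ with leverage
  $h_i = 1/n + (x_i - \bar x)^2 / \sum_j (x_j - \bar x)^2$, with Sn in
  place of the residual standard deviation.

## The unsupervised caller

For each amplicon $a_j$, the `L` = 5 amplicons with the highest
Sn-correlation of log coverages are selected as partners — from *other
genes* only, so a CNV spanning $a_j$ cannot also span a partner. The
correlation threshold `T` is chosen automatically: the largest grid value
(step 0.01) at which every CNV site still owns at least one amplicon that
passes the partner-availability check. Amplicons with fewer than `L`
partners above `T` fail QC; a site whose amplicons all fail is excluded
everywhere.

Each partner yields a Theil–Sen fit of $\log \mathrm{cov}(a_j)$ on
$\log \mathrm{cov}(a_{jk})$. A sample supports a heterozygous deletion in
one model when its studentized residual falls below the lower Student-$t$
critical value (level $\alpha_{del} = 0.02$, $df = n - 2$) *and* the simple
Bayes factor

$$K = \frac{P(\mathrm{cov}(a_j) \mid M_{HetDel})}{P(\mathrm{cov}(a_j) \mid
M_{Normal})} > 1,$$

where both likelihoods are normal densities in log space with the model's
residual scale, and the deletion line is the fitted line shifted by
$\log 0.5$. Duplication support is symmetric (upper tail,
$\alpha_{dup} = 0.05$, shift $\log 1.5$); the milder level reflects the
smaller shift and the variance increase under duplication. A state is
called when at least `votes_required` = 4 of the 5 models agree — voting
across partners suppresses errors in any single predictor. Datasets with
fewer than 25 samples are refused unless explicitly overridden, because the
robust estimates become unreliable.

## The supervised classifier

The supervised stage needs at least 20 CNV-free controls — from the
unsupervised split or supplied a priori. Per amplicon it:

1. builds a normalisation **cluster** of $k = 5$ amplicons from other genes,
   chosen by correlation on control samples (Pearson when more than 20
   controls, Sn-correlation otherwise). Members must correlate above
   `cluster_min_corr` = 0.5; the cluster shrinks rather than admit weak
   members, whose unrelated fluctuations would otherwise leak into the
   statistic (in our null experiments a single weak member was enough to
   fabricate a plausible-looking single-amplicon deletion);
2. computes $x_j = \log \mathrm{cov}(a_j) - \frac{1}{|C|}\sum_{k \in C}
   \log \mathrm{cov}(a_{jk})$ — library size cancels exactly;
3. fits three models: $M_{Normal}$ with the Hodges–Lehmann location and Sn
   scale of the control $x_j$; $M_{HetDel}$ and $M_{Dup}$ at shifts
   $\log 0.5$ and $\log 1.5$ with scales multiplied by $\sqrt{2}$ and
   $\sqrt{2/3}$. The corrections come from the delta method: for
   Poisson-distributed reads, $\mathrm{Var}(\log X) \approx 1/\lambda$, so
   halving the rate doubles the log-scale variance and multiplying it by
   1.5 scales the variance by 2/3.

Two refinements guard the normalised statistic itself. First, a cluster
cell can lie inside a CNV of the *sample being tested* (the different-gene
rule only protects the target amplicon): cells the unsupervised stage
flagged non-NORMAL, and homozygous-deletion cells, contribute their
reference level (median over controls) instead of their own deviation, and
the deviation average is taken over the surviving members — so a deletion
elsewhere in the genome cannot masquerade as a duplication here, and the
sample's shared condition response is still tracked at full strength.
Second, the Sn scale is estimated on controls at their typical depth, but
a test sample's expected counts differ by its condition factors, and in
log space the Poisson contribution to the variance is $1/\mu$ per cell —
the same delta-method fact behind the 2 and 2/3 factors. Each cell's model
variance is therefore adjusted by the difference between its own composite
shot-noise term, $1/\hat\mu_j + \sum_{k \in C} 1/\mathrm{cov}(a_{jk}) /
|C|^2$ (target $\hat\mu$ from the normal model, members from their
observed counts), and the control median of that term, which is already
inside the fitted scale. Without this, a routine two-to-three-sigma count
fluctuation at a condition-depressed, low-depth amplicon is several
nominal standard deviations wide and passes all three gates as a
single-amplicon deletion.

Each (site, test sample) pair then answers three questions in order.
*Admissibility*: every amplicon's squared standardized distance to the
candidate model must stay below the $\chi^2_1$ quantile at level
$0.05 / E$, where $E$ = (amplicons in the test set)/2 estimates how many
amplicons could plausibly be altered under the ≤ 20 % carrier assumption;
only then is the site "suspicious" for that state. *Rejection of normal*:
the squared normalised Euclidean distance $\sum_j (x_j - \mu_j)^2 /
s_j^2$ to the normal locations follows $\chi^2$ with one degree of freedom
per amplicon (the cluster normalisation leaves the covariance approximately
diagonal — blocks of size one); p-values are Benjamini–Hochberg-adjusted
across all suspicious pairs of the iteration and must pass the 5 % FDR
level. *Best explanation*: the Bayes factor (product of per-amplicon normal
density ratios, equal priors) must reach 100. Test samples that end the
pass without a single non-NORMAL site join the control set, and the whole
stage repeats — the control set only grows — until nothing moves or
`max_iterations` is reached.

## Quality control details

* Samples with fewer than 15 000 reads are removed.
* Cells with coverage below 10 on an amplicon whose across-sample mean is
  at least 50 are homozygous deletions; they are reported and masked so no
  estimator ever sees them.
* Amplicons with mean coverage below 50, or without the partners the
  unsupervised caller needs, fail QC; a site loses analysis everywhere only
  if all its amplicons fail.
* **Irregular samples**: per gene, coverages are divided by the gene's
  total reads in that sample (so a whole-gene CNV does not bias the
  normalisation) and log-transformed; the reference profile is the
  per-amplicon Hodges–Lehmann location, the scale the per-amplicon Sn. The
  test statistic keeps the smallest 80 % (rounded up) of squared
  standardized coordinates — trimming shields it from the extreme values
  that legitimate CNVs or artefacts produce — and is compared to the
  $\chi^2$ upper-0.01 quantile with the trimmed count as degrees of
  freedom. A sample is irregular only when more than half of the (more
  than two) testable genes fail: a sample would need large anomalies in
  most genes at once, which is far more likely a library artefact than
  biology. The choice of 0.01 for the per-gene level is ours; the
  composite rule makes the final decision insensitive to it over a wide
  range.

Because same-group amplicons inside one gene deviate *together*, the
per-gene statistic's coordinates are positively correlated and the
$\chi^2$ reference is mildly anticonservative; the 80 % trimming absorbs
most of it. We therefore read the guarantee at the per-gene test level
(irregular rate at or below the per-gene 0.01), not as the much smaller
composite-rule rate; on simulated null runs the observed rate is ~0.3 %.

## The simulator

`simulate_coverage()` generates matrices with exactly the structure the
method assumes, plus a truth set, so the whole pipeline is testable without
sequencing data. For amplicon $j$ in efficiency group $g$ and sample $i$:

$$\mu_{ij} = m_{ij}\, d_j\, \frac{(1 + e_j f_{gi})^c}{\overline{(1 + e_j
f_{g\cdot})^c}}, \qquad \text{count}_{ij} \sim \mathrm{Pois}(\mu_{ij}),$$

with $m_{ij}$ the CNV multiplier (1 for wild type; 0, 0.5, 1.5 or 2 inside
injected events), $d_j$ a per-amplicon depth drawn log-uniformly in
[150, 1080] around a target of 400 reads (matching the 120–1200 range such
panels produce), $e_j$ the efficiency and $f_{gi}$ a lognormal
(sd 0.05) condition factor shared by all amplicons of group $g$ in sample
$i$. Defaults: 48 samples, 3 genes of ~43 amplicons with exon sites of 1–5
amplicons, 25 cycles. Raw amplification magnitudes after 25 cycles are
astronomical, so the response is rescaled per amplicon to its depth — only
its *relative* cross-sample variation matters.

Groups are laid out as aligned blocks: each gene's amplicons split into
consecutive blocks of at least three, and block $g$ of every gene belongs
to group $g$. This gives every amplicon at least six strongly correlated
partners on other genes (the unsupervised caller needs five) while keeping
the number of same-group amplicons within any one gene small (three-ish),
which in turn keeps the per-gene QC statistic close to its reference
distribution. Group-centre efficiencies are uniform on [0.45, 0.85] with a
within-group half-width of only 0.02: group mates are biochemically
similar by construction, so log-log regression slopes between them are
near 1 — the property that makes a global per-sample scaling move points
*along* the regression lines and renders library-size normalisation
unnecessary. An overdispersion knob switches the noise to negative
binomial; it is off by default, matching the Poisson reads-per-fragment
assumption behind the variance corrections.

What the simulator does **not** emulate: GC and length biases (the method
never uses them), primer-binding artefacts that produce recurrent
single-amplicon dropouts in real replicates, batch structure across runs
(runs are analysed separately by design), and mosaic or somatic fractions.
Passing tests on simulated data therefore demonstrate the statistical
machinery under the model's own assumptions, not performance on any
particular chemistry.

Event generators for power studies draw contiguous site runs of 2–10
amplicons at multipliers 0.5 or 1.5 with per-site carrier fractions within
the 20 % assumption; duplication events span at least two sites because
single-site duplications are outside the caller's reporting scope (they
are emitted flagged, but suppressed by default).

## Scoring

`score_calls()` matches calls to truth by the ≥ 50 % reciprocal-span rule:
a call in the right sample and gene, with the right direction, overlapping
at least half of the true event's amplicon span is a true positive.
Sensitivity is reported as TP/(TP+FN); the phrase "proportion of true
positives among all positive results" describes the positive predictive
value, which is reported separately. Specificity is sample-level (an
event-free sample with any call counts against it), with Wilson 95 %
intervals.

## Numerical choices and degenerate inputs

* Natural log throughout; zero counts on QC-passed cells get a 0.5
  pseudo-count before the log (true zeros are already masked as homozygous
  deletions).
* The outlier test uses Student-$t$ quantiles with $df = n - 2$, the
  simple-regression convention.
* Theil–Sen pairs with equal $x$ contribute no slope; an all-equal
  predictor is an error. A perfect fit (zero residual scale) raises a
  degenerate-model error rather than emitting infinite residuals.
* Partner and cluster ranking ties break by correlation, then genomic
  distance, then amplicon id — runs are fully deterministic, and identical
  seeds give byte-identical reports.
* Constant control vectors (zero Sn) exclude the amplicon from the
  supervised stage with a warning.
* `expected_altered` is recomputed each iteration from the current test
  set and floored at one.

## Problem sizes used in the test-suite

The packaged tests exercise the full pipeline at the scale one run of the
target panels has: 48 samples × ~130 amplicons. Null calibration uses 50
such runs, parameter recovery 20 runs with four carriers each; estimator
oracle checks run 1000 random instances at $n \le 8$ against exhaustive
enumeration. The Monte-Carlo check of the variance-correction factors uses
100 000 draws per Poisson rate.

## Known limitations

* Single-amplicon evidence is intrinsically fragile; duplications confined
  to one site are suppressed by default, and single-amplicon deletions
  should be treated as hypotheses for orthogonal confirmation (e.g. MLPA).
* The supervised stage needs 20 genuine controls; cohorts saturated with
  carriers of the same CNV violate both stages' assumptions (the 20 %
  carrier bound is load-bearing).
* Exact integer copy numbers above three are not resolved.
* The per-gene QC statistic is approximate under strong within-gene
  correlation (discussed above).
* Read counting uses maximal-overlap assignment of primary alignments; it
  does not attempt realignment-based rescue of ambiguous reads.
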