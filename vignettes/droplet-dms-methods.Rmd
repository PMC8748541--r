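---
title: "Models and methods behind dropscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dropscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropscan)
```

# The experiment being modelled

A droplet-microfluidic deep mutational scan measures, for hundreds of
thousands of enzyme variants at once, whether each variant retains catalytic
activity. Cells expressing a mutagenized library are loaded into picoliter
droplets together with lysis reagents and a fluorogenic substrate; after a
short on-chip incubation (minutes, so that even weakly active variants do
not saturate), droplets whose fluorescence exceeds a gate are sorted.
Sequencing the presorted and sorted pools, calling amino-acid substitutions,
and comparing substitution frequencies between pools yields a
per-substitution fitness coefficient.

`dropscan` implements every computational stage of this design, plus a
simulator with the same statistical structure, so that each stage — and the
pipeline end to end — can be validated against planted ground truth.

# The screen simulator

## Library model

Error-prone PCR is modelled as a Poisson number of uniformly placed
single-nucleotide substitutions per gene copy (default mean 4.5, matching a
manganese-doped Taq protocol), each substituted base drawn uniformly from
the three alternatives. With default settings on a ~100-codon construct this
yields roughly 2–4 amino-acid substitutions per variant. The mutation
spectrum is deliberately uniform: typical Taq transition bias changes which
substitutions appear but not the downstream statistics being tested, and the
per-variant substitution lists are exposed so a biased spectrum can be
injected if needed. Indels are not simulated; the analysis stages are
substitution-only by design (gapless codon-aware calling).

## Activity model

Each variant's latent activity probability is logistic in its substitutions:
$p(\text{active}) = \sigma(\beta_0 + \sum_j \beta_j)$, with stop gains
forcing $p = 0$. Ground-truth coefficients come from a two-component model
(default: 40% of substitutions deleterious with effects $N(-4, 1)$, the rest
$N(0, 0.5)$) — the bimodal shape typical of mutational scans. The intercept
$\beta_0$ is solved numerically so that the library-mean activity equals the
target prior $\pi$ (default 0.25, the functional fraction measured for
unsorted libraries in plate assays). This calibration is exact in
probability; the realized Bernoulli active fraction differs only by
sampling error.

## Droplet sort

Droplets receive $k \sim \text{Poisson}(\lambda)$ cells. "10% occupancy" is
interpreted as $P(k \ge 1) = 0.10$, i.e. $\lambda = -\ln 0.9 \approx 0.105$,
which reproduces the 80–100 cells/s arithmetic of a 0.8–1 kHz sorter.
Droplet fluorescence is the sum over resident cells of
rate × incubation × lognormal expression noise (CV 0.3, mean 1), plus
Gaussian autofluorescence (sd 10 units). Defaults: active variants
accumulate 100 units/min, inactive 2 units/min, 3 min incubation, gate at
60 units. Passing droplets contribute **all** resident variants to the
sorted pool. Co-encapsulation carryover is therefore the dominant
false-positive mechanism: at $\lambda = 0.105$ about 5% of occupied droplets
hold ≥2 cells, which (with gate and noise defaults, $\pi = 0.25$) caps
sorted-pool purity at ~93%. That lands inside the 60–90%+ purity regime
observed when sorted libraries are re-assayed clone by clone. The true
false-positive mechanism of a physical sorter is not identifiable from
published data; co-encapsulation is one plausible, parsimonious mechanism
and is flagged as a modelling choice, not a reconstruction.

## Reads

Reads are full-length gene copies sampled with replacement from a pool, with
i.i.d. per-base substitution errors and Phred qualities set consistently
with the error rate. Fragmentation/tagmentation is not simulated: it would
add no behavior that the gapless calling stage tests. What the simulator
therefore does **not** emulate about real data: alignment ambiguity, indel
sequencing errors, PCR chimeras and jackpotting, position-dependent quality
decay, and barcode-free variant identity (reads are anonymous here too, but
real paired-end stitching is skipped). Passing tests demonstrate
correctness of the statistical machinery under the stated generative model,
not robustness to those artifacts.

# Mutation calling

Reads with mean Phred quality below 30 are discarded (the threshold is a
config knob; mean-based filtering is the mildest reading of a "quality
score < 30" rule and keeps the boundary testable: 29.9 drops, 30.0 stays).
Calling is codon-wise comparison of the translated read against the
translated reference; synonymous changes yield nothing, stop gains are
reported with alt `*`, and positions are shifted by a configurable
`numbering_offset` so truncated constructs report canonical residue numbers
(e.g. an N-terminally truncated protease construct still calls D175A).
Substitutions observed fewer than 10 times — pooled across input and sorted
pools within a replicate, the least destructive reading, also configurable —
are dropped. Reads carrying stop gains are retained: they are informative
negatives for the fitness model.

# Positive-unlabeled fitness estimation

The sorted pool contains (almost) only active variants; the input pool is
unlabeled with known active prevalence $\pi$. Under case-control sampling
from these two pools, a read with substitution indicators $x$ and activity
probability $\sigma(x) = \text{logistic}(\beta_0 + x^\top\beta)$ belongs to
the sorted pool with probability

$$ q(x) = \frac{n_P\,\sigma(x)}{n_P\,\sigma(x) + n_U\,\pi}, $$

where $n_P$ and $n_U$ are the pool sizes. The coefficients minimize the
Bernoulli negative log-likelihood of the pool labels under $q$, with an L2
penalty ($10^{-4}$ by default) on slopes only. This is the standard
case-control positive-unlabeled likelihood with known class prior; the
package states it explicitly so that results are reproducible regardless of
which PU variant other implementations choose. Numerical choices:

- observations are reads, not deduplicated variants — read counts are the
  only abundance signal without barcodes;
- identical (features, pool) observations are collapsed with multiplicity
  weights before optimization, which leaves the likelihood unchanged and
  makes the fit cost independent of sequencing depth;
- optimization is L-BFGS-B with analytic gradients, warm-restarted until
  the optimizer reports convergence at relative tolerance $10^{-8}$ (500
  iterations per round, 5 rounds max); the convergence flag is honest;
- features present in only one pool are separable; their slopes are
  box-constrained to ±10 and flagged;
- $q$ is clamped to $[10^{-12}, 1 - 10^{-12}]$ with a warning;
- standard errors come from the inverse observed information at the
  optimum (optional).

The prior $\pi$ is supplied, not estimated (default 0.25 from plate-assay
functional fractions). A naive pseudocounted log-enrichment per substitution
is provided as a diagnostic baseline. The two statistics estimate the same
quantity only when variants carry few substitutions: at the default ~3–4
substitutions per variant, the regression coefficient is *conditional* on
co-occurring mutations while the enrichment ratio is *marginal*, so
near-neutral substitutions that ride along with deleterious partners have
negative marginal enrichment but near-zero coefficients. Their sign
agreement (≥ 80%) is therefore asserted in a ≤2-substitution regime.

Replicates are compared by Pearson correlation over shared substitutions.
Exclusion is iterative: while ≥3 replicates remain, the replicate with the
lowest mean pairwise correlation is dropped if that mean is below 0.5 —
recomputing after each drop, so a single discordant replicate cannot drag
its concordant partners below the cutoff. Retained replicates are combined
by a count-weighted mean.

# Tolerance and divergence profiles

Site tolerance is the mean |coefficient| over all retained substitutions at
a position (positions with no retained substitutions are omitted, not
zero-filled), reported as a percentile rank, $\text{rank}/n \times 100$ with
tie averaging. Conservation profiles from an MSA use normalized Shannon
column entropy ($H/\log 20$, gaps excluded, columns with >50% gaps or a
gapped reference dropped) — a standard, assumption-light choice of
conservation metric. Paralogs are aligned globally (BLOSUM62, affine gaps
10/0.5, fixed in config for reproducibility) and reduced to matched-column
position pairs. Divergence profiles difference the two tolerance profiles at
aligned positions and smooth with a centered moving average (window 9,
truncated at the edges; chosen as roughly one secondary-structure element —
any odd window is accepted). Per-site significance of divergence uses a
permutation test that shuffles substitution-level |coefficients| between
enzymes within a site, BH-corrected; with $m$ coefficients per enzyme per
site the attainable p-value floor is $2/\binom{2m}{m}$, which matters for
small panels.

# Kinetics

Initial velocities against substrate are fitted to the Hill equation
$v = V_{max} S^n / (K^n + S^n)$ by Levenberg–Marquardt least squares.
Because low-$n$ Hill fits are weakly identified, the fit is multi-started
(≥9 starts: $K$ at substrate quantiles × several Hill coefficients) and the
best converged start is kept; $n$ can be fixed (e.g. 1 recovers a
Michaelis–Menten fit). Active-site titration fits a line to the declining
regime of residual activity vs. irreversible inhibitor (points after the
first near-zero activity are excluded) and reports the x-intercept as the
active enzyme concentration; then $k_{cat} = V_{max}/[E]$ and
$k_{cat}/K$. Velocity units are left abstract — $k_{cat}$ is only a true
turnover number when $V_{max}$ is in concentration/time units consistent
with $[E]$, and conversion factors are the caller's responsibility.

# Screen statistics

Binomial proportions (e.g. functional fractions of clone panels) get Wilson
score intervals: at the small $n$ of plate-format panels the Wilson interval
keeps near-nominal coverage where the Wald interval collapses
(Clopper–Pearson is conservative); the method is selectable. A clone counts
as functional iff its activity strictly exceeds 50% of wild type. Fold
enrichment is the ratio of active fractions after/before sorting.

# Problem sizes and determinism

Every stochastic operation takes an explicit seed and is exactly
reproducible; the pipeline manifest records the config, seeds, stage counts,
and MD5 digests of outputs, and reruns are byte-identical. Simulation-based
tests use libraries of a few hundred to a few thousand variants, $10^4$ to
$2 \times 10^5$ droplets, and $10^4$–$10^5$ reads per pool — sizes at which
the sampling-error bands in the tests (typically 3 standard errors) are
informative while a full run stays on the scale of minutes on one core. The
screen-calibration script averages sorted-pool purity over 10 seeds ×
$10^5$ droplets.

## Identifiability at small library sizes

Per-substitution coefficients are identifiable only when substitutions
recur across variants. In a library where a substitution appears in a
single variant, only the *sum* of that variant's coefficients is
determined by the data; the ridge penalty then controls, but does not
remove, the arbitrary split, and compensating coefficient pairs of large
magnitude can appear. Real screens (with $10^5$–$10^6$ variants, each
substitution on hundreds of backgrounds) are far from this regime;
simulated demonstrations should keep the ratio of variants to possible
substitutions comfortably above one, as the bundled demo configuration
does (1000 variants of a 40-codon construct).

# Known limitations

- The analysis is substitution-only and gapless; indel variants or reads
  must be handled upstream (a gapless full-length SAM importer is provided,
  but alignment itself is out of scope).
- $\pi$ is taken as known; misspecification biases the intercept and, less
  severely, compresses coefficients. A sensitivity sweep over $\pi$ is a
  one-line loop over `fit_pu_logistic`.
- No epistasis terms: coefficients are additive on the log-odds scale.
- The sorter's false-positive mechanism is a model (co-encapsulation +
  autofluorescence), not a measurement.
- Hill fits on noisy low-$n$ data can trade $V_{max}$ against $K$; the
  multi-start reports only the best least-squares solution, not a posterior.
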