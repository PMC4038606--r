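---
title: "Simulating demography, deleterious variation, and complex-trait architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating demography, deleterious variation, and complex-trait architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demarch)
library(dplyr)
```

## The question the package addresses

Human populations that expanded explosively in the recent past carry an
excess of rare, mostly deleterious, protein-coding variants. If mutations
that damage proteins also contribute risk to complex traits, that excess
should reshape the genetic architecture of those traits — how much additive
genetic variance ($V_A$) sits on rare versus common variants, how many
distinct causal alleles a case sample carries, and how many of them a
case-control association study of a given size can expect to find.

`demarch` provides a complete, reproducible pipeline to study these
questions by simulation:

1. a forward-in-time Wright–Fisher simulator with selection over
   independent sites (`run_model()`), under step-wise demographic histories
   (`canonical_model()`, `rescale_model()`);
2. a quantitative-trait layer coupling selection coefficients to effect
   sizes (`select_causal()`, `assign_effects()`, `calibrate_C()`,
   `variance_decomposition()`);
3. a liability-threshold case-control sampler (`make_cohort()`,
   `ascertain()`);
4. single-marker exact association tests and yield summaries
   (`assoc_test()`, `count_significant()`, `va_explained_by_pvalue()`);
5. a replication driver tying the stages together (`run_experiment()`).

## The population-genetic model

Each generation, allele frequencies change deterministically by genic
selection, $p^\* = p(1+s)/(1+ps)$, and stochastically by binomial sampling
of the offspring generation's $2N$ chromosomes. Genic selection is the
first-order equivalent of additive diploid selection with $h = 1/2$; the
model family we emulate does not state a dominance model, and the additive
choice is the conventional one for this class of simulation. A coefficient
$s \le -1$ is treated as lethal ($p^\* = 0$).

New mutations enter as single copies among the offspring generation's
chromosomes, as a Poisson number with mean $2N\mu L$ per class per
generation. The order within a generation is fixed and documented: drift
first, then mutational influx, so a new mutation is observable (count 1) in
the generation in which it arose and first drifts in the next. The
alternative order (influx before drift) silently removes a fraction
$e^{-1}$ of each cohort before it can be observed and depresses equilibrium
diversity below Watterson's prediction; the test suite enforces the
Watterson check, which pins this convention down.

Sites are fully independent (free recombination, no linkage
disequilibrium), the Poisson Random Field picture. Synonymous mutations are
neutral; the nonsynonymous mutational target is 2.5 times the synonymous
target, reflecting the excess of coding sites whose mutation changes the
protein. Selection coefficients of new nonsynonymous mutations are drawn
from a gamma distribution of deleterious effects; the defaults (shape
0.184, mean $|s|$ 0.0257) follow the classic gamma fit to human
nonsynonymous site-frequency data of Boyko and colleagues (2008), and both
are configuration entries. Under these defaults roughly 29% of new
nonsynonymous mutations are effectively neutral ($|s| < 10^{-4}$) and
roughly a third are strongly deleterious ($|s| > 10^{-2}$), matching the
published fit's headline percentages.

### Demographic histories

`canonical_model()` provides the three step-wise histories studied:

* **BN** — a severe Out-of-Africa-style bottleneck 2000 generations before
  sampling, recovery to the ancestral size 1960 generations before
  sampling;
* **BN_growth** — the same bottleneck plus an instantaneous 100-fold
  expansion 80 generations (about 2000 years) before sampling;
* **Old_growth** — an African-like 2-fold expansion 4000 generations before
  sampling.

The published description prints the timings but not the sizes. We take an
ancestral size of $N = 10{,}000$ diploids and a bottleneck to $N/10$ for 40
generations as documented defaults; both are parameters of
`canonical_model()`, and quantitative summaries that depend on the
bottleneck's severity (association yields in particular) should be read
with that assumption in mind. Each run starts from a mutation-free
population and burns in for $10 \times 2N$ generations at the ancestral
size, which is ample for mutation–selection–drift equilibrium (the
Watterson check in the test suite verifies equilibrium diversity levels).

### Rescaling

Forward simulation at human population sizes is slow, so
`rescale_model(model, lambda)` divides sizes and times by $\lambda$ while
multiplying $s$ and $\mu$ by $\lambda$, preserving $4N\mu$ and $4Ns$. In
the diffusion limit the site-frequency dynamics depend only on these scaled
parameters. `run_model()` applies the stored multipliers internally and
reports selection coefficients and mutation ages back on the natural scale,
so downstream stages are $\lambda$-agnostic.

Rescaling has one resolution cost that matters here: the smallest
representable frequency is $1/(2N/\lambda)$. At $\lambda = 20$ a
bottleneck-history population holds only 1000 chromosomes, so variants
below 0.1% frequency cannot exist at all, and the rare tail of the
$V_A$-by-frequency distribution is truncated; at $\lambda = 10$ the tail
extends to 0.05%. Quantities dominated by that tail (the share of $V_A$
below a rare-frequency threshold, the share of $V_A$ invisible to a finite
case-control sample) converge from above as $\lambda$ shrinks and should be
computed at the smallest affordable $\lambda$; a rescaling-invariance
property test (sample summaries at $\lambda \in \{2, 10\}$) guards the
quantities that should not depend on $\lambda$. The package's desk-scale
default is $\lambda = 10$ with 200 replicates, which keeps a full
three-history replication under twenty minutes on one CPU; the same
configuration at $\lambda = 2$ reproduces the published scale and is meant
for cluster use.

## The trait model

A random subset of the nonsynonymous target of $L_{ns}$ bp forms the
mutational target of $M$ bp ($M = 70$ or 140 kb): each nonsynonymous site
is causal with probability $M/L_{ns}$. A causal SNP's effect is

$$\alpha_i = \delta\, |s_i|^{\tau} (1 + \epsilon_i)\, C, \qquad
\epsilon_i \sim \mathcal{N}(0, 0.5^2),$$

the Eyre-Walker coupling of fitness and trait effects. $\tau = 0.5$ makes
more deleterious mutations have larger trait effects; $\tau = 0$ decouples
the two. $\delta = 1$: causal alleles increase trait/liability. The noise
term is deliberately untruncated, so a small fraction of effects flip sign.

$C$ scales effects so that the target accounts for a chosen heritability
$h^2 \in \{0.05, 0.1, 0.3\}$: in each constant-size calibration replicate,
$C_r$ solves $C_r^2 X_r/(C_r^2 X_r + V_E) = h^2$ with
$X_r = 2\sum_i p_i(1-p_i)(|s_i|^\tau(1+\epsilon_i))^2$, and
`calibrate_C()` returns the mean $C_r$. That constant is then **frozen**
and reused under every demography, so a given mutation has the same
biological effect regardless of population history, and the realised $h^2$
per replicate is stochastic. We fix $V_E = 1$ trait-units²; since only the
ratio $V_A/V_E$ matters, any positive $V_E$ rescales the units. The
"calibration demography" is the constant-size model with the same DFE and
mutation rates — selection must act during calibration because effects
depend on $s$.

Phenotypes are additive, $Y_j = \sum_i z_{ij}\alpha_i + \epsilon_j$ with
$\epsilon_j \sim \mathcal{N}(0, V_E)$, over Hardy–Weinberg genotypes
$z_{ij} \sim \text{Binomial}(2, p_i)$ (independent sites imply linkage
equilibrium).

## Case-control design and association testing

Disease status follows the liability-threshold model: phenotypes of a
source cohort (default 6000 individuals) are rank-transformed to the
standard normal scale (Blom offsets, random tie-breaking), and the
threshold is the 60% quantile, giving a prevalence of 40%. 1000 cases are
drawn uniformly from above the threshold and 1000 controls from below,
without replacement.

Each causal SNP is tested with the allelic Fisher exact test on the
2×2 table of derived-allele copies versus other alleles in case and
control chromosomes. Two-sided P-values use the minimum-likelihood rule
(the classical convention, identical to `stats::fisher.test`); we document
this because two-sided conventions differ. Sites monomorphic in the
combined sample are untestable and flagged. The allelic (rather than
genotypic) table is an interpretive choice: the odds-ratio-by-frequency
summaries this design family reports imply allele counting.

Yield summaries follow the study design: counts of causal SNPs significant
at $10^{-2}$, $10^{-5}$ and $5\times10^{-8}$; the share of target $V_A$
(computed with population frequencies) on SNPs below each P-value
threshold; and per-bin detection power across replicates.

## What the generator does and does not emulate

The simulator *is* the data generator: allele frequencies, ages and
selection coefficients arise from an explicit evolutionary process rather
than from a fitted frequency spectrum. It reproduces the features that
drive the scientific conclusions — bottleneck-induced loss of rare
variants, growth-induced excess of young deleterious mutations, the
resulting shift of trait variance onto rare alleles when $\tau > 0$, and
demography-insensitive genetic load and heritability. It does **not**
emulate linkage disequilibrium or haplotype structure (so gene-based burden
tests are out of scope by construction), positive or balancing selection,
dominance or epistasis, population structure or covariates. Passing tests
therefore speak to single-marker designs on effectively independent causal
sites, not to LD-aware analyses of real sequence data.

## Numerical choices and degenerate inputs

* Durations are rounded to the nearest integer (minimum 1) on rescaling;
  the burn-in likewise.
* A rescaled $s\lambda \le -1$ is lethal; such mutations die in their first
  generation and never reach any sample, so capping affects dynamics only
  through the (intended) loss of effectively-lethal mutations.
* `calibrate_C()` skips replicates with zero raw variance with a warning;
  an empty causal set yields zero $V_A$ and `NA` fractions rather than an
  error.
* Genetic load is multiplicative across sites,
  $1 - \prod_i(1 + p_i s_i)$, consistent with per-site mean fitness
  $1 + ps$ under genic selection; an additive variant $\sum p_i|s_i|$ is
  available. The combining rule is not stated by the emulated design;
  with realistic loads (~$10^{-3}$) the two differ negligibly.
* Fixed deleterious mutations leave the segregating set and are excluded
  from load (per-step absorption counts are exposed as attributes of
  `generation_step()`).
* Replicate seeds derive from the master seed via a fixed integer mixing
  scheme (`replicate_seed()`); every table produced by `run_experiment()`
  is byte-reproducible from the configuration and master seed.

## A worked miniature

A full desk-scale replication takes minutes; here is a miniature with a
toy-sized history to show the moving parts (numbers below come from this
actual run).

```{r miniature}
rates <- mutation_rates(mu_site = 2e-6, L_syn = 2000)
dfe <- dfe_config()

bn <- canonical_model("BN", N_ancestral = 100, N_bottleneck = 20,
                      t_bottleneck_start = 100, t_bottleneck_end = 80,
                      t_growth = 10, burn_in = 2000)
sim <- run_model(bn, rates, dfe, seed = 1)
glance(present_state(sim))

cfg <- trait_config(tau = 0.5, h2_target = 0.3, M = 3500)
cal <- simulate_replicates(
  canonical_model("constant", N_ancestral = 100, burn_in = 2000),
  rates, dfe, n = 5, seed = 2)
C <- calibrate_C(simulate_causal_sites(cal, 3500, rates$L_ns), cfg)

sites <- tidy(present_state(sim))
arch <- assign_effects(select_causal(sites, 3500, rates$L_ns), cfg,
                       as.numeric(C), twoN = present_state(sim)$twoN)
vd <- variance_decomposition(arch)
c(V_A = vd$V_A, h2 = vd$h2)

set.seed(3)
cohort <- make_cohort(arch, n_source = 600, n_cases = 100, n_controls = 100)
res <- assoc_test(cohort)
glance(res)
```

## Known limitations

* Quantities carried by variants rarer than the rescaled frequency floor
  are truncated at coarse $\lambda$; compare across $\lambda$ before
  trusting a rare-tail number.
* The bottleneck's severity and the ancestral size are assumptions;
  association-yield magnitudes (though not the orderings between
  demographies) are sensitive to them, and `canonical_model()` exposes both
  for sensitivity sweeps.
* The DFE is a point estimate; uncertainty in its shape propagates directly
  into the rare-variant share of $V_A$.
* With 1000 cases and controls, significance counts at loose thresholds are
  medians of small integers; compare distributions, not single medians,
  when modifying the design.
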