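---
title: "Benchmarking fitness inference on simulated evolving populations"
author: "fitbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking fitness inference on simulated evolving populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitbench)
```

## The problem

Dense genomic time series — viral surveillance data, experimental evolution,
ancient DNA — raise the question of whether fitness can be read off from how
genotype frequencies change. `fitbench` is an in-silico test bed for that
question: it simulates haploid populations of binary genomes evolving under a
known quadratic fitness function, hands the resulting time-stamped samples to
two independent inference schemes, and scores how well each recovers the
parameters and, more importantly, the *fitness rank order* of the observed
genotypes.

Genotypes are spin vectors $s \in \{-1,+1\}^L$ and log-fitness is

$$F(s) = f_0 + \sum_i f_i s_i + \sum_{i<j} f_{ij} s_i s_j,$$

with additive effects $f_i \sim \mathcal N(0, \sigma_{f_i})$ and pairwise
epistatic effects $f_{ij} \sim \mathcal N(0, \sigma_{f_{ij}})$. The offset
$f_0$ shifts every genotype equally; selection acts only on fitness
differences, so $f_0$ is carried through the data structures but is never an
inference target, and shift invariance is one of the tested properties.

## The simulator

`run_replicate()` advances a population of $N$ haploids one generation at a
time, applying in fixed order:

1. **selection + drift** — $N$ offspring drawn multinomially with weight
   $\propto \exp F(g)$ (Malthusian mapping; weights stay positive for any
   parameter draw, and the $(1+F)$ alternative could be slotted into
   `reproductive_weight()` without touching anything else);
2. **recombination** — each offspring is, with probability $r$, replaced by a
   free recombinant of itself and a uniformly chosen second parent (every
   locus from either parent with probability 1/2, so every pair of loci
   separates with probability $c_{ij} = 1/2$);
3. **mutation** — every site flips sign independently with probability $\mu$.

The within-generation event order is a genuine modelling choice; any fixed
order differs only at $O(\mu, 1/N)$ per generation, and the order is
centralised in one internal function so it can be permuted.

The default study conditions are the six canonical settings exposed by
`scenario_presets()`: $N = 1000$, $L = 25$, $T = 30$ generations, $r = 0.5$,
with three additive-only rows ($\mu \in \{0.003, 0.01\}$,
$\sigma_{f_i} \in \{0.01, 0.05\}$, one replicate) and three epistatic rows
($\mu = 0.01$, $\sigma_{f_{ij}} = 0.002$,
$\sigma_{f_i} \in \{0.005, 0.05, 0.1\}$, thirty replicates). Populations
start at uniform random genotypes (expected allele frequency 0.5 per site), a
polymorphic start that gives both methods usable initial diversity; a
monomorphic start and explicit initial frequencies are available for the
physics tests.

The simulator's correctness is pinned by closed-form oracles rather than by
comparison with another simulator: neutral allele frequencies are a
martingale; the mutation flux is $E[\Delta m] = \mu(1 - 2m)$; one-generation
drift variance is $m(1-m)/N$; neutral fixation probability equals the initial
frequency; and a single selected locus follows the deterministic replicator
recursion $m' = m e^{2f_i} / (m e^{2f_i} + 1 - m)$ at large $N$.

## Quasi-linkage-equilibrium inference (tQLE)

When recombination is fast relative to selection the genotype distribution is
transiently Gibbs–Boltzmann,
$P(s) \propto \exp(\sum_i h_i s_i + \sum_{i<j} J_{ij} s_i s_j)$, with
time-varying fields $h$ and couplings $J$. The package restricts to the
bi-allelic case, where the general indicator parameterisation reduces exactly
to this Ising gauge — the gauge in which the field formula uses
$\tanh^{-1}$ of magnetisations, so "frequency" in the field equation always
means the magnetisation $\chi_i = 2 m_i - 1 \in (-1, 1)$, never the $[0,1]$
allele frequency (conversions are centralised in the moment module).

Inference proceeds in three steps:

* **couplings** by naive mean field: $J_{ij} = -(C^{-1})_{ij}$ with $C$ the
  connected-correlation matrix. nMF is exact as $\|J\| \to 0$; the suite
  checks recovery against full Boltzmann enumeration at $L \le 5$.
* **fields**: $h_i = \tanh^{-1}\chi_i - \sum_j J_{ij}\chi_j$.
* **fitness**: the coupling dynamics relax to $J^*_{ij} = f_{ij}/(r c_{ij})$,
  so epistasis is read back as $f^*_{ij} = (r c_{ij} + 4\mu) J^*_{ij}$
  (variant `"nmf"`, the default; the mutation-free `"nmf_rc"` and the
  Gaussian-closure `"gc"` form
  $(r c_{ij} + 4\mu)\,\chi_{ij} / [(1-\chi_i^2)(1-\chi_j^2)]$, which avoids
  the matrix inversion, are both kept). The additive part comes from the
  field dynamics: $f^*_i = [h_i(t + \Delta t) - h_i(t)]/\Delta t -
  \sum_j f^*_{ij} \chi_j(t)$, averaged over all $T$ unit intervals
  (per-interval values are returned for diagnostics). With no epistasis the
  whole pipeline collapses to $f_i^* = \Delta \tanh^{-1}\chi_i / \Delta t$
  (`variant = "additive"`), which is the mode used on additive-only
  scenarios.

Two pooling semantics coexist deliberately. Fields are estimated per
generation from that generation's samples pooled across replicates — the time
derivative requires time-resolved values. Couplings are estimated from all
samples accumulated over generations $0..t$ and across replicates
(`j_pooling = "cumulative"`, the default). Accumulation buys a much larger
sample for the inversion and is what makes epistasis recovery work in the
epistasis-dominated regime, but it has a known cost: when strong additive
sweeps are underway ($\sigma_{f_i} \gtrsim 0.05$), pooling across time mixes
generations with different means, which injects sweep-driven covariance into
$C$ and degrades the *full-variant* additive estimate — one concrete
mechanism behind tQLE's degradation as additive variance grows. The
alternative `j_pooling = "per_gen"` avoids the mixture at the price of much
noisier couplings.

## Marginal path likelihood (MPL)

MPL works in the $[0,1]$ frequency convention under the Wright–Fisher
diffusion. With diffusion matrix $D$ (diagonal $m_i(1-m_i)$, off-diagonal
$m_{ij} - m_i m_j$) integrated over the observation window by a
left-endpoint rule (a trapezoidal option exists), the maximum of the path
probability under a Gaussian prior of width $\gamma$ is the ridge solve

$$\Big(\textstyle\sum_k \Delta t_k D(t_k) + \gamma I\Big)\, s =
  m(t_K) - m(t_0) - \mu \textstyle\sum_k \Delta t_k (1 - 2 m(t_k)).$$

The recovered $s$ are per-0/1-allele coefficients; changing one allele
changes $F$ by $2 f_i$ in the spin convention, so `solve_mpl()` returns
$f^*_i = s/2$. Getting this factor wrong would show up as a slope of
$\approx 2$ in every ground-truth recovery test, which is how it is
validated end to end. Replicate paths are independent, so their integrated
statistics simply add before the solve. MPL is additive-only by design here;
epistatic ground truth acts as a stress test, not as something it estimates.

## Tunable parameters that matter

| parameter | default | units / scale | role |
|---|---|---|---|
| `lambda` | 0.5 | pseudocount per pair table | keeps $|\chi_i| < 1$ (finite $\tanh^{-1}$) and $C$ positive definite at monomorphic sites; split $\lambda/4$ per joint state, $\lambda/2$ per single state |
| `gamma` | 0.1 | scale of integrated covariance entries at $N = 1000$, $T = 30$ | MPL ridge width; estimates shrink monotonically as it grows |
| `r`, `c` | 0.5, 0.5 | probabilities | only the product $r c_{ij}$ (plus $4\mu$) enters inference, so the ambiguity in what "recombination rate" means is confined to one constant, 0.25 by default |
| `smooth_window` | 0 (off) | generations | optional moving average on $h(t)$ before differencing; differencing amplifies sampling noise in $\tanh^{-1}\chi$ |
| `q` | 0.05 | fraction | elite set size (ceiling of $q$ × universe), selected by *true* fitness, scored by ranks computed on the full universe |

Raw endpoint frequencies (de-pseudocounted) are used for the MPL net-change
term, while pseudocounted frequencies enter the diffusion matrix — the
change term is a physical observable, the diffusion entries must stay
invertible.

## Evaluation

The ranking universe is the set of unique genotypes observed anywhere in the
analysed trajectories (not all $2^L$), ordered by true fitness with ties
broken by first observation. Rank metrics are midrank Spearman correlations,
over the whole universe and within the top-5% elite of true fitness; both
are invariant under strictly increasing transforms of the predictions, which
is the point — rank order is the evaluation currency, not parameter
magnitude. Fitness distributions are decomposed per individual
(count-weighted) into additive and epistatic components at the first and
last generation; their Kolmogorov–Smirnov distances quantify the observation
that with fast recombination the epistatic component is not heritable while
the additive mean advances. A min-oriented Gumbel fit to the final additive
fitness is reported descriptively and never gates any acceptance decision.

## Seeds and reproducibility

One experiment seed derives the landscape seed and per-replicate simulator
streams through a fixed affine map (`derive_seed()`), so any replicate can
be regenerated alone and increasing the replicate count never changes the
landscape or earlier replicates — a prerequisite for honest replicate-count
curves.

## What the tests show — and what they cannot

Problem sizes in the suite and in `scripts/acceptance.R` follow the canonical
settings above: single-replicate runs for the additive scenarios and
30-replicate sweeps at 5 experiment seeds (reported as medians) for the
epistatic ones; enumeration oracles use $L \le 5$ where $2^L$ states are
exact. Under those conditions the suite reproduces: accurate additive
recovery by both methods at $\sigma_{f_i} = 0.05$ with magnitudes
*under*-estimated (regression slope < 1); tQLE ahead of MPL on all-sequence
rank order when epistasis dominates ($\sigma_{f_i} = 0.005$) and MPL ahead
when additive variance dominates ($\sigma_{f_i} = 0.1$); epistasis recovery
that is best at low $\sigma_{f_i}$ and degrades monotonically; MPL nearly
insensitive to replicate count. One prescribed behaviour does not emerge
under these conditions: at $\sigma_{f_i} = 0.005$ tQLE's rank correlation
keeps improving up to 30 replicates instead of saturating at 5 — the
pairwise signal $\chi_{ij} \approx f_{ij}/(rc + 4\mu) \approx 0.007$ sits at
the sampling-noise floor of a single replicate, so more data keeps helping;
the saturation check is kept at its stated setting and reported as failing.

The generator emulates idealised conditions that real surveillance data do
not meet: complete population sampling without sequencing error, a panmictic
population with no geographic structure, uniform mutation and recombination
rates, a time-constant landscape with only pairwise epistasis, and known
$\mu$ and sampling times. Passing these tests therefore demonstrates
correctness of the machinery and the claimed parameter-regime behaviour *in
silico*; it does not certify performance on real data, where sampling noise,
structure and model misspecification all bite.

## A short session

```{r example, eval = FALSE}
library(fitbench)

run <- run_scenario(scenario("epistatic-low", seed = 1,
                             replicate_counts = c(5, 30)))
subset(compare_methods(run),
       metric %in% c("spearman_all", "spearman_top5", "fij_spearman"))
```
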