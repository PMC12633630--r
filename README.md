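# fitbench

Can fitness be inferred from population-wide, whole-genome, time-stamped
sequence data? `fitbench` answers this *in silico*: it simulates haploid
populations of binary genomes evolving under a known quadratic fitness
landscape — selection, mutation, outcrossing recombination and multinomial
drift — and benchmarks two independent inference schemes against that ground
truth, scoring both parameter recovery and the fitness rank order of observed
genotypes (including the top-5% elite). It is aimed at population geneticists
and method developers who want a controlled test bed for selection-inference
methods before touching real surveillance or experimental-evolution data.

## The model

Genotypes are spin vectors `s ∈ {−1, +1}^L` with log-fitness

    F(s) = f0 + Σ_i f_i s_i + Σ_{i<j} f_ij s_i s_j

where `f_i ~ N(0, σ_fi)` are additive selection coefficients and
`f_ij ~ N(0, σ_fij)` pairwise epistatic effects. Two estimators are
implemented:

* **tQLE** (transient quasi-linkage equilibrium): the genotype distribution
  is transiently Gibbs–Boltzmann with fields `h(t)` and couplings `J(t)`.
  Naive mean field recovers `J = −(C⁻¹)` (off-diagonal) from connected
  correlations and `h_i = atanh(χ_i) − Σ_j J_ij χ_j` from magnetisations;
  QLE dynamics then give epistasis `f*_ij = (r c_ij + 4μ) J_ij` and additive
  effects `f*_i = Δh_i/Δt − Σ_j f*_ij χ_j`.
* **MPL** (marginal path likelihood): under the Wright–Fisher diffusion the
  most probable parameters given an observed frequency path solve the ridge
  system `(Σ_k Δt_k D(t_k) + γI) s = Δm − μ Σ_k Δt_k (1 − 2m(t_k))`, with
  `D` the diffusion matrix; `f*_i = s_i / 2` converts to the spin convention.
  MPL is additive-only; epistatic ground truth stress-tests it.

Six canonical presets (`scenario_presets()`) cover additive-only and
epistatic regimes at `N = 1000`, `L = 25`, `T = 30`, `r = 0.5`. See the
methods vignette (`vignettes/fitness-inference.Rmd`) for assumptions,
parameter roles and known limitations.

## Worked example

Simulate one replicate of the strong-additive setting and ask both methods
to recover it:

```r
library(fitbench)

fl   <- sample_landscape(L = 25, sigma_fi = 0.05, sigma_fij = 0, seed = 42)
cfg  <- sim_config(N = 1000, L = 25, T = 30, r = 0.5, mu = 0.01, seed = 42)
traj <- run_replicate(fl, cfg, replicate_id = 1)

est_tqle <- infer_tqle(traj, variant = "additive")  # no-epistasis reduction
est_mpl  <- infer_mpl(traj, gamma = 0.1)

report <- evaluate_run(traj, fl, list(tqle = est_tqle, mpl = est_mpl))
for (e in report$estimates)
  cat(sprintf("%-5s spearman_all = %.3f  spearman_top5 = %.3f  fi: r = %.3f, slope = %.2f\n",
              e$method, e$spearman_all, e$spearman_top5,
              e$param_recovery$fi$pearson, e$param_recovery$fi$slope))
```

```
tqle  spearman_all = 0.982  spearman_top5 = 0.782  fi: r = 0.971, slope = 0.48
mpl   spearman_all = 0.995  spearman_top5 = 0.808  fi: r = 0.993, slope = 0.88
```

Both methods order the 17,129 observed genotypes almost perfectly
(`spearman_all`), rank the 857-member elite well (`spearman_top5`), and
recover the individual selection coefficients with high correlation but
regression slopes below one — magnitudes of the strongest effects are
systematically underestimated, which is exactly the expected behaviour in
this regime. `run_scenario(scenario("epistatic-low", seed = 1))` runs the
same pipeline end-to-end for the epistatic presets, including `f*_ij`
recovery and replicate-pooling sweeps; `compare_methods()` returns the
long-format comparison table.

A thin shell wrapper is included at `inst/cli/fitbench.R`
(`simulate` / `infer` / `sweep` subcommands) operating on the package's
trajectory (TSV / FASTA) and landscape (JSON) file formats.

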