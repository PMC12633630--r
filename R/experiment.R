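## End-to-end scenario orchestration: canonical parameter presets, replicate
## sweeps, paired tQLE/MPL inference and evaluation, with hierarchical seed
## derivation so that every artifact is reproducible from (scenario, seed)
## and adding replicates never changes the landscape or earlier replicates.

preset_table <- function() {
  list(
    ## additive-only settings (single replicate)
    "additive-weak"   = list(mu = 0.003, sigma_fi = 0.01, sigma_fij = 0,
                             n_replicates = 1L),
    "additive-mid"    = list(mu = 0.01, sigma_fi = 0.01, sigma_fij = 0,
                             n_replicates = 1L),
    "additive-strong" = list(mu = 0.01, sigma_fi = 0.05, sigma_fij = 0,
                             n_replicates = 1L),
    ## additive + pairwise epistasis settings (30 replicates)
    "epistatic-low"   = list(mu = 0.01, sigma_fi = 0.005, sigma_fij = 0.002,
                             n_replicates = 30L),
    "epistatic-mid"   = list(mu = 0.01, sigma_fi = 0.05, sigma_fij = 0.002,
                             n_replicates = 30L),
    "epistatic-high"  = list(mu = 0.01, sigma_fi = 0.1, sigma_fij = 0.002,
                             n_replicates = 30L))
}

#' Scenario presets
#'
#' The six canonical study settings: three additive-only rows
#' (`N = 1000`, 1 replicate, `L = 25`, `T = 30`, `r = 0.5`,
#' `mu` in \{0.003, 0.01\}, `sigma_fi` in \{0.01, 0.05\}, `sigma_fij = 0`)
#' and three epistatic rows (30 replicates, `mu = 0.01`,
#' `sigma_fi` in \{0.005, 0.05, 0.1\}, `sigma_fij = 0.002`).
#'
#' @return character vector of preset names.
#' @export
scenario_presets <- function() names(preset_table())

#' Build a scenario
#'
#' @param preset one of [scenario_presets()], or `NULL` to specify
#'   everything explicitly.
#' @param seed experiment seed; landscape and replicate streams derive from
#'   it hierarchically.
#' @param replicate_counts replicate counts at which to evaluate (pooled);
#'   defaults to the preset's full replicate count.
#' @param N,L,T,r,mu,sigma_fi,sigma_fij overrides of the preset parameters.
#' @param gamma MPL ridge width.
#' @param lambda moment pseudocount.
#' @param variant tQLE variant; `NULL` selects `"additive"` when
#'   `sigma_fij == 0` and `"nmf"` otherwise.
#' @return a `scenario` object.
#' @export
scenario <- function(preset = NULL, seed = 1L, replicate_counts = NULL,
                     N = 1000L, L = 25L, T = 30L, r = 0.5,
                     mu = NULL, sigma_fi = NULL, sigma_fij = NULL,
                     gamma = 0.1, lambda = 0.5, variant = NULL) {
  base <- list(mu = 0.01, sigma_fi = 0.05, sigma_fij = 0, n_replicates = 1L)
  if (!is.null(preset)) {
    tab <- preset_table()
    if (!preset %in% names(tab)) stop_invalid("unknown preset: ", preset)
    base <- tab[[preset]]
  }
  if (is.null(mu)) mu <- base$mu
  if (is.null(sigma_fi)) sigma_fi <- base$sigma_fi
  if (is.null(sigma_fij)) sigma_fij <- base$sigma_fij
  if (is.null(replicate_counts)) replicate_counts <- base$n_replicates
  if (is.null(variant)) variant <- if (sigma_fij == 0) "additive" else "nmf"
  structure(list(name = if (is.null(preset)) "custom" else preset,
                 seed = check_count(seed, "seed", 0L),
                 N = N, L = L, T = T, r = r, mu = mu,
                 sigma_fi = sigma_fi, sigma_fij = sigma_fij,
                 replicate_counts = sort(unique(as.integer(replicate_counts))),
                 gamma = gamma, lambda = lambda, variant = variant),
            class = "scenario")
}

#' Run a scenario end to end
#'
#' Draws the landscape, simulates the replicates, runs both inference
#' methods at every requested replicate count (tQLE with cumulatively
#' pooled moments, MPL with summed sufficient statistics) and evaluates
#' each against ground truth.
#'
#' @param sc a [scenario()].
#' @param keep_trajectories keep the simulated trajectories in the result
#'   (memory-heavy; default `FALSE`).
#' @param verbose log stage summaries.
#' @return list with `scenario`, `truth`, and `reports`: one
#'   `evaluation_report` per replicate count, named by the count.
#' @export
run_scenario <- function(sc, keep_trajectories = FALSE, verbose = FALSE) {
  if (!inherits(sc, "scenario")) stop_invalid("sc must be a scenario")
  truth <- sample_landscape(sc$L, sc$sigma_fi, sc$sigma_fij,
                            seed = derive_seed(sc$seed, 0L, stage = 0L))
  cfg <- sim_config(N = sc$N, L = sc$L, T = sc$T, r = sc$r, mu = sc$mu,
                    n_replicates = max(sc$replicate_counts), seed = sc$seed)
  trajs <- run_replicates(truth, cfg)
  if (verbose)
    message(sprintf("[%s seed=%d] simulated %d replicates (N=%d L=%d T=%d)",
                    sc$name, sc$seed, length(trajs), sc$N, sc$L, sc$T))
  reports <- lapply(sc$replicate_counts, function(n) {
    sub <- trajs[seq_len(n)]
    est_tqle <- suppressWarnings(
      infer_tqle(sub, variant = sc$variant, lambda = sc$lambda))
    est_mpl <- infer_mpl(sub, gamma = sc$gamma, lambda = sc$lambda)
    rep <- evaluate_run(sub, truth, list(tqle = est_tqle, mpl = est_mpl))
    rep$n_replicates <- n
    if (verbose)
      message(sprintf("  n=%d: spearman_all tqle=%.3f mpl=%.3f", n,
                      rep$estimates[[1L]]$spearman_all,
                      rep$estimates[[2L]]$spearman_all))
    rep
  })
  names(reports) <- as.character(sc$replicate_counts)
  out <- list(scenario = sc, truth = truth, reports = reports)
  if (keep_trajectories) out$trajectories <- trajs
  out
}

#' Long-format method comparison table
#'
#' @param run result of [run_scenario()], or a list of such results sharing
#'   a scenario name structure.
#' @return data.frame with columns `scenario`, `seed`, `method`,
#'   `n_replicates`, `metric`, `value`.
#' @export
compare_methods <- function(run) {
  runs <- if (!is.null(run$reports)) list(run) else run
  nm <- unique(vapply(runs, function(r) r$scenario$name, character(1L)))
  if (length(nm) > 1L) stop_invalid("runs come from different scenarios")
  rows <- list()
  for (r in runs) {
    for (rep in r$reports) {
      for (est in rep$estimates) {
        vals <- c(spearman_all = est$spearman_all,
                  spearman_top5 = est$spearman_top5,
                  fi_pearson = est$param_recovery$fi$pearson,
                  fi_slope = est$param_recovery$fi$slope,
                  fi_rmse = est$param_recovery$fi$rmse)
        if (!is.null(est$param_recovery$fij))
          vals <- c(vals, fij_spearman = est$param_recovery$fij$spearman)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = r$scenario$name, seed = r$scenario$seed,
          method = est$method, n_replicates = rep$n_replicates,
          metric = names(vals), value = unname(vals))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
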