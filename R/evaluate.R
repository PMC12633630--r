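## Scoring of inferred landscapes against ground truth: per-parameter
## recovery, genotype-level rank metrics (all sequences and the top-5%
## elite of true fitness), fitness-distribution decomposition and
## descriptive extreme-value (Gumbel) fits.

#' Predict genotype fitness from an inferred landscape
#'
#' Additive-only when `fij_star` is absent; otherwise the full quadratic
#' form with zero offset.
#'
#' @param genotypes matrix of genotypes (+/-1, one per row).
#' @param est an `inferred_landscape`.
#' @return numeric vector of predicted log-fitness values.
#' @export
predict_fitness <- function(genotypes, est) {
  S <- if (is.matrix(genotypes)) genotypes else matrix(genotypes, nrow = 1L)
  if (ncol(S) != est$L) stop_invalid("genotype length does not match L")
  pred <- as.vector(S %*% est$fi_star)
  if (!is.null(est$fij_star)) {
    M <- est$fij_star + t(est$fij_star)
    pred <- pred + 0.5 * rowSums((S %*% M) * S)
  }
  pred
}

#' Midrank Spearman correlation, on all values or within the true-fitness elite
#'
#' With `subset = "all"`, the usual average-rank Spearman correlation.  With
#' `subset = "top_fraction"`, the elite set is the `ceil(q * n)` genotypes of
#' highest TRUE fitness; ranks are computed on the full set (rank 1 = most
#' fit) and the correlation is taken between true and inferred ranks within
#' the elite.
#'
#' @param true_vals,pred_vals numeric vectors of equal length >= 2.
#' @param subset `"all"` or `"top_fraction"`.
#' @param q elite fraction (default 0.05).
#' @return Spearman correlation in `[-1, 1]`.
#' @export
spearman_ranks <- function(true_vals, pred_vals,
                           subset = c("all", "top_fraction"), q = 0.05) {
  subset <- match.arg(subset)
  if (length(true_vals) != length(pred_vals))
    stop_invalid("value vectors must have equal length")
  if (subset == "all") {
    if (length(true_vals) < 2L)
      stop(errorCondition("need >= 2 values for a rank correlation",
                          class = c("fitbench_undefined_result", "error")))
    return(stats::cor(true_vals, pred_vals, method = "spearman"))
  }
  n <- length(true_vals)
  k <- ceiling(q * n)
  if (k < 2L)
    stop(errorCondition("elite subset has fewer than 2 members",
                        class = c("fitbench_undefined_result", "error")))
  true_rank <- rank(-true_vals, ties.method = "average")
  pred_rank <- rank(-pred_vals, ties.method = "average")
  elite <- order(true_rank)[seq_len(k)]
  stats::cor(true_rank[elite], pred_rank[elite], method = "spearman")
}

#' Universe of unique genotypes observed in trajectories, ranked by truth
#'
#' Deduplicates every genotype observed anywhere in the supplied
#' trajectories and orders them by true fitness (most fit first), ties
#' broken by first observation.
#'
#' @param trajs a `trajectory` or list of trajectories.
#' @param fl the ground-truth [fitness_landscape()].
#' @return list with `geno` (unique genotypes, ranked), `fitness` (their
#'   true total fitness) and `n` (universe size).
#' @export
rank_universe <- function(trajs, fl) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  mats <- lapply(trajs, function(tr)
    do.call(rbind, lapply(tr$records, `[[`, "geno")))
  S <- do.call(rbind, mats)
  keys <- genotype_keys(S)
  S <- S[!duplicated(keys), , drop = FALSE]
  f <- fitness_of(S, fl)$total
  ord <- order(-f) # stable: ties keep first-observation order
  list(geno = S[ord, , drop = FALSE], fitness = f[ord], n = nrow(S))
}

#' Decompose per-individual fitness distributions at one generation
#'
#' Count-weighted (per-individual) total, additive and epistatic fitness of
#' the population sample at a recorded generation, pooled over replicates.
#'
#' @param trajs a `trajectory` or list of trajectories.
#' @param fl ground-truth landscape.
#' @param at `"initial"` (first recorded generation) or `"final"` (last).
#' @return list with numeric vectors `total`, `additive`, `epistatic`,
#'   weights `count`, the generation used, and component means.
#' @export
decompose_distributions <- function(trajs, fl, at = c("initial", "final")) {
  at <- match.arg(at)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  pick <- function(tr) {
    gens <- generations(tr)
    k <- if (at == "initial") which.min(gens) else which.max(gens)
    tr$records[[k]]
  }
  recs <- lapply(trajs, pick)
  S <- do.call(rbind, lapply(recs, `[[`, "geno"))
  count <- unlist(lapply(recs, `[[`, "count"))
  f <- fitness_of(S, fl)
  list(total = f$total, additive = f$additive, epistatic = f$epistatic,
       count = count, gen = pick(trajs[[1L]])$gen,
       mean = c(total = stats::weighted.mean(f$total, count),
                additive = stats::weighted.mean(f$additive, count),
                epistatic = stats::weighted.mean(f$epistatic, count)))
}

#' Maximum-likelihood Gumbel (extreme value) fit
#'
#' Two-parameter fit of a max- or min-oriented Gumbel distribution.  The
#' max-oriented density is `(1/b) exp(-z - exp(-z))`, `z = (x - a)/b`; the
#' min orientation is its reflection.  Used descriptively for final additive
#' fitness distributions; never a gate on inference quality.
#'
#' @param samples numeric vector (>= 20 values, nondegenerate).
#' @param orientation `"min"` or `"max"`.
#' @param weights optional nonnegative case weights.
#' @return list with `location`, `scale`, `orientation`, `loglik`,
#'   `converged`.
#' @export
fit_gumbel <- function(samples, orientation = c("min", "max"),
                       weights = NULL) {
  orientation <- match.arg(orientation)
  if (length(samples) < 20L) stop_invalid("need >= 20 samples")
  if (is.null(weights)) weights <- rep(1, length(samples))
  if (stats::sd(samples) == 0)
    stop_invalid("degenerate (constant) sample: Gumbel scale would be zero")
  x <- if (orientation == "min") -samples else samples
  wm <- stats::weighted.mean(x, weights)
  ws <- sqrt(stats::weighted.mean((x - wm)^2, weights))
  b0 <- ws * sqrt(6) / pi
  a0 <- wm - 0.5772156649 * b0 # Euler-Mascheroni
  nll <- function(par) {
    b <- exp(par[2L])
    z <- (x - par[1L]) / b
    sum(weights * (log(b) + z + exp(-z)))
  }
  opt <- stats::optim(c(a0, log(b0)), nll, method = "BFGS")
  loc <- opt$par[1L]
  if (orientation == "min") loc <- -loc
  list(location = loc, scale = exp(opt$par[2L]), orientation = orientation,
       loglik = -opt$value, converged = opt$convergence == 0L)
}

#' Full evaluation of inferred landscapes against ground truth
#'
#' For each estimate: parameter-recovery statistics for `fi` (and `fij`
#' where inferred), genotype-level Spearman correlations over the observed
#' universe (all genotypes and the top-5% elite of true fitness), the
#' elite rank table, the initial/final fitness decomposition with
#' per-component Kolmogorov-Smirnov distances, and a descriptive Gumbel fit
#' to the final additive fitness.
#'
#' @param trajs trajectories the estimates were inferred from (define the
#'   ranking universe and the distributions).
#' @param truth ground-truth [fitness_landscape()].
#' @param estimates a single `inferred_landscape` or list of them.
#' @param q elite fraction (default 0.05).
#' @return an `evaluation_report`: list with one entry per estimate
#'   (`spearman_all`, `spearman_top5`, `rank_pairs`, `param_recovery`) plus
#'   shared `decomposition`, `gumbel_fit`, `ks_initial_vs_final` and
#'   `universe_size`.
#' @export
evaluate_run <- function(trajs, truth, estimates, q = 0.05) {
  if (inherits(estimates, "inferred_landscape")) estimates <- list(estimates)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  uni <- rank_universe(trajs, truth)
  true_rank <- rank(-uni$fitness, ties.method = "average")
  k_elite <- ceiling(q * uni$n)

  per_est <- lapply(estimates, function(est) {
    if (est$L != truth$L) stop_invalid("estimate and truth disagree on L")
    pred <- predict_fitness(uni$geno, est)
    pred_rank <- rank(-pred, ties.method = "average")
    elite <- order(true_rank)[seq_len(k_elite)]
    rec <- param_recovery(truth, est)
    list(method = est$method, variant = est$variant,
         spearman_all = spearman_ranks(uni$fitness, pred, "all"),
         spearman_top5 = spearman_ranks(uni$fitness, pred, "top_fraction",
                                        q = q),
         rank_pairs = data.frame(true_rank = true_rank[elite],
                                 inferred_rank = pred_rank[elite]),
         param_recovery = rec)
  })
  names(per_est) <- vapply(per_est, function(e)
    paste0(e$method, if (!is.null(e$variant) && length(e$variant))
      paste0("_", e$variant) else ""), character(1L))

  dec0 <- decompose_distributions(trajs, truth, "initial")
  dec1 <- decompose_distributions(trajs, truth, "final")
  ks <- vapply(c("total", "additive", "epistatic"), function(comp)
    weighted_ks_distance(dec0[[comp]], dec0$count, dec1[[comp]], dec1$count),
    numeric(1L))
  gum <- if (stats::sd(dec1$additive) > 0)
    fit_gumbel(dec1$additive, "min", weights = dec1$count) else NULL

  structure(list(estimates = per_est,
                 decomposition = list(initial = dec0, final = dec1),
                 ks_initial_vs_final = ks, gumbel_fit = gum,
                 universe_size = uni$n, elite_size = k_elite),
            class = "evaluation_report")
}

## per-parameter recovery summary for one estimate
param_recovery <- function(truth, est) {
  fi_stats <- recovery_stats(truth$fi, est$fi_star)
  out <- list(fi = fi_stats)
  if (!is.null(est$fij_star)) {
    up <- upper.tri(truth$fij)
    out$fij <- recovery_stats(truth$fij[up], est$fij_star[up])
  }
  out
}

recovery_stats <- function(true_v, est_v) {
  rmse <- sqrt(mean((true_v - est_v)^2))
  if (stats::sd(true_v) == 0 || stats::sd(est_v) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_, slope = NA_real_,
                rmse = rmse))
  list(pearson = stats::cor(true_v, est_v),
       spearman = stats::cor(true_v, est_v, method = "spearman"),
       slope = unname(stats::coef(stats::lm(est_v ~ true_v))[2L]),
       rmse = rmse)
}

#' Write an evaluation report to JSON
#'
#' Scalar metrics only (rank tables and histograms are omitted); intended
#' for audit and regression comparison.
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  scal <- list(
    universe_size = report$universe_size,
    elite_size = report$elite_size,
    ks_initial_vs_final = as.list(report$ks_initial_vs_final),
    mean_initial = as.list(report$decomposition$initial$mean),
    mean_final = as.list(report$decomposition$final$mean),
    gumbel_fit = if (!is.null(report$gumbel_fit))
      report$gumbel_fit[c("location", "scale", "orientation", "converged")]
      else NULL,
    estimates = lapply(report$estimates, function(e)
      list(method = e$method, spearman_all = e$spearman_all,
           spearman_top5 = e$spearman_top5,
           param_recovery = e$param_recovery)))
  jsonlite::write_json(scal, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
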