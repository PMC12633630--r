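## Marginal path likelihood (MPL) inference of additive selection.
##
## Under the Wright-Fisher diffusion, allele frequencies m in [0,1]^L follow
## a Langevin dynamics with diffusion matrix D (diagonal m_i(1 - m_i),
## off-diagonal m_ij - m_i m_j) and a drift containing the selection term
## and the mutation flux mu (1 - 2 m).  Maximising the probability of an
## observed frequency path with a Gaussian prior of width gamma gives the
## ridge-regularised linear system
##   (sum_k dt_k D(t_k) + gamma I) s = m(t_K) - m(t_0) - mu sum_k dt_k (1 - 2 m(t_k)),
## solved for the 0/1-convention coefficients s; the +/-1-convention
## additive effects of the quadratic landscape are fi* = s / 2.

raw_frequencies <- function(ms) {
  ## invert the pseudocount to recover the raw sample frequencies
  (ms$m_i * (ms$n_samples + ms$lambda) - ms$lambda / 2) / ms$n_samples
}

#' Integrated sufficient statistics for MPL
#'
#' Left-endpoint quadrature of the diffusion matrix over each sampling
#' interval (a trapezoidal option is provided), net frequency change from
#' the raw endpoint frequencies, and the integrated mutation flux.
#'
#' @param series list of `moment_set` objects at increasing generations
#'   (e.g. [frequency_trajectory()]`$sets`).  Frequencies entering the
#'   diffusion matrix keep their pseudocount; endpoint frequencies are
#'   de-pseudocounted.
#' @param mu mutation rate used for the flux term.
#' @param gamma ridge regularisation width (recorded; applied in
#'   [solve_mpl()]).
#' @param quadrature `"left"` (default) or `"trapezoid"`.
#' @return an `mpl_stats` object with `Cint`, `dm`, `mut_flux`, `gamma`,
#'   `mu`, `time_grid`, `n_paths`.
#' @export
accumulate_statistics <- function(series, mu, gamma = 0.1,
                                  quadrature = c("left", "trapezoid")) {
  quadrature <- match.arg(quadrature)
  if (length(series) < 2L) stop_invalid("need at least two time points")
  mu <- check_scalar(mu, "mu", 0, 0.5)
  gamma <- check_scalar(gamma, "gamma", lower = 0)
  gens <- vapply(series, `[[`, numeric(1L), "gen")
  dts <- diff(gens)
  L <- length(series[[1L]]$m_i)
  D_at <- function(ms) {
    D <- ms$m_ij - outer(ms$m_i, ms$m_i)
    diag(D) <- ms$m_i * (1 - ms$m_i)
    D
  }
  Cint <- matrix(0, L, L)
  mut_flux <- numeric(L)
  for (k in seq_along(dts)) {
    Dk <- if (quadrature == "left") D_at(series[[k]])
          else (D_at(series[[k]]) + D_at(series[[k + 1L]])) / 2
    Cint <- Cint + dts[k] * Dk
    mk <- if (quadrature == "left") raw_frequencies(series[[k]])
          else (raw_frequencies(series[[k]]) +
                raw_frequencies(series[[k + 1L]])) / 2
    mut_flux <- mut_flux + mu * dts[k] * (1 - 2 * mk)
  }
  dm <- raw_frequencies(series[[length(series)]]) -
    raw_frequencies(series[[1L]])
  structure(list(Cint = (Cint + t(Cint)) / 2, dm = dm, mut_flux = mut_flux,
                 gamma = gamma, mu = mu, time_grid = gens, n_paths = 1L),
            class = "mpl_stats")
}

#' Pool sufficient statistics from independent replicate paths
#'
#' Path log-likelihoods of independent replicates add, so their integrated
#' statistics add entry-wise; `gamma` is shared.
#'
#' @param stats_list list of `mpl_stats`.
#' @return pooled `mpl_stats`.
#' @export
pool_statistics <- function(stats_list) {
  if (!length(stats_list)) stop_invalid("empty statistics list")
  out <- stats_list[[1L]]
  for (st in stats_list[-1L]) {
    out$Cint <- out$Cint + st$Cint
    out$dm <- out$dm + st$dm
    out$mut_flux <- out$mut_flux + st$mut_flux
    out$n_paths <- out$n_paths + st$n_paths
  }
  out
}

#' Solve the MPL ridge system
#'
#' @param stats an `mpl_stats` object.
#' @param gamma optional override of the regularisation width stored in
#'   `stats`; must be > 0 unless `Cint` is nonsingular.
#' @return list with `fi_star` (+/-1-convention additive effects, `= s/2`)
#'   and `s01` (the 0/1-convention coefficients).
#' @export
solve_mpl <- function(stats, gamma = NULL) {
  if (is.null(gamma)) gamma <- stats$gamma
  A <- stats$Cint + diag(gamma, nrow(stats$Cint))
  s <- tryCatch(solve(A, stats$dm - stats$mut_flux), error = function(e)
    stop("integrated covariance is singular; use gamma > 0", call. = FALSE))
  list(fi_star = as.vector(s) / 2, s01 = as.vector(s))
}

#' MPL inference from replicate trajectories
#'
#' Builds per-replicate sufficient statistics, pools them additively and
#' solves the regularised system.  The estimate is additive-only (`fij_star`
#' absent).
#'
#' @param trajs a `trajectory` or list of replicate trajectories.
#' @param mu mutation rate for the flux term (default: the trajectory
#'   configuration's rate).
#' @param gamma ridge width (default 0.1, on the scale of integrated
#'   covariance entries for N = 1000, T = 30).
#' @param lambda pseudocount used for the diffusion-matrix frequencies.
#' @param quadrature passed to [accumulate_statistics()].
#' @return an `inferred_landscape` with `fi_star`, `method = "mpl"` and the
#'   hyperparameters used.
#' @export
infer_mpl <- function(trajs, mu = NULL, gamma = 0.1, lambda = 0.5,
                      quadrature = "left") {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  cfg <- trajs[[1L]]$config
  if (is.null(mu)) mu <- cfg$mu
  stats_list <- lapply(trajs, function(tr)
    accumulate_statistics(frequency_trajectory(tr, lambda)$sets,
                          mu = mu, gamma = gamma, quadrature = quadrature))
  pooled <- pool_statistics(stats_list)
  sol <- solve_mpl(pooled)
  structure(list(L = length(sol$fi_star), fi_star = sol$fi_star,
                 fij_star = NULL, method = "mpl",
                 hyperparams = list(gamma = gamma, mu = mu, lambda = lambda,
                                    quadrature = quadrature,
                                    n_paths = pooled$n_paths)),
            class = "inferred_landscape")
}
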