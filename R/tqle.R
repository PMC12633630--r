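## Transient quasi-linkage-equilibrium (tQLE) inference.
##
## In the QLE regime the genotype distribution is transiently
## Gibbs-Boltzmann, P(s) ~ exp(sum_i h_i s_i + sum_{i<j} J_ij s_i s_j),
## with possibly time-varying fields h and couplings J.  Naive mean field
## recovers (h, J) from moments; QLE dynamics then map the couplings to
## epistatic fitness (J relaxes to fij / (r c), or fij / (r c + 4 mu) with
## mutation) and the time derivative of the fields to additive fitness:
##   fi*(t) = [h_i(t + dt) - h_i(t)] / dt - sum_j fij* chi_j(t).

#' Naive mean-field couplings from a moment set
#'
#' Inverts the connected-correlation matrix `C` (`C_ij = chi_ij`, diagonal
#' `1 - chi_i^2`): `J_ij = -(C^-1)_ij` off the diagonal, zero on it.
#'
#' @param ms a `moment_set`.
#' @return symmetric zero-diagonal `L x L` coupling matrix.
#' @export
infer_couplings_nmf <- function(ms) {
  C <- ms$chi_ij
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("correlation matrix is singular; re-estimate moments with a larger ",
         "pseudocount lambda", call. = FALSE))
  J <- -Cinv
  diag(J) <- 0
  (J + t(J)) / 2
}

#' Naive mean-field fields from a moment set and couplings
#'
#' `h_i = atanh(chi_i) - sum_j J_ij chi_j` (magnetisation convention).
#'
#' @param ms a `moment_set` with `|chi_i| < 1` (guaranteed by `lambda > 0`).
#' @param J symmetric coupling matrix (zero matrix for the additive-only
#'   reduction).
#' @return length-L field vector.
#' @export
infer_fields_nmf <- function(ms, J) {
  if (any(abs(ms$chi_i) >= 1))
    stop("|chi_i| >= 1: estimate moments with pseudocount lambda > 0")
  as.vector(atanh(ms$chi_i) - J %*% ms$chi_i)
}

#' Epistatic fitness from couplings or correlations
#'
#' Three estimators of `fij`:
#' \describe{
#'   \item{`"nmf"`}{`fij* = (r c + 4 mu) J_ij` — relaxation fixed point of
#'     the coupling dynamics including the mutation correction (default).}
#'   \item{`"nmf_rc"`}{`fij* = r c J_ij` — the mutation-free fixed point.}
#'   \item{`"gc"`}{Gaussian-closure estimator straight from correlations,
#'     `fij* = (r c + 4 mu) chi_ij / ((1 - chi_i^2)(1 - chi_j^2))`, which
#'     bypasses the matrix inversion.}
#' }
#'
#' @param ms a `moment_set` (required for `"gc"`, and supplies `J` via
#'   [infer_couplings_nmf()] when `J` is not given).
#' @param r outcrossing rate.
#' @param c pairwise separation probability (1/2 under free reassortment);
#'   only the product `r * c` matters.
#' @param mu mutation rate.
#' @param variant one of `"nmf"`, `"nmf_rc"`, `"gc"`.
#' @param J optional precomputed coupling matrix.
#' @return symmetric zero-diagonal matrix of `fij*`.
#' @export
infer_fij <- function(ms = NULL, r, c = 0.5, mu = 0,
                      variant = c("nmf", "nmf_rc", "gc"), J = NULL) {
  variant <- match.arg(variant)
  rate <- if (variant == "nmf_rc") r * c else r * c + 4 * mu
  if (rate <= 0) stop_invalid("effective rate r*c (+ 4 mu) must be positive")
  if (variant == "gc") {
    v <- 1 - ms$chi_i^2
    fij <- rate * ms$chi_ij / outer(v, v)
  } else {
    if (is.null(J)) J <- infer_couplings_nmf(ms)
    fij <- rate * J
  }
  diag(fij) <- 0
  fij
}

#' Additive fitness from fields at two consecutive times
#'
#' `fi* = [h(t + dt) - h(t)] / dt - fij* %*% chi(t)`.
#'
#' @param h_now,h_next lists with fields `gen` and `h` at the two times.
#' @param fij_star symmetric epistasis estimate (zero matrix allowed).
#' @param ms `moment_set` at the earlier time (supplies `chi_i`).
#' @param dt positive sampling interval; must equal
#'   `h_next$gen - h_now$gen`.
#' @return length-L per-interval estimate of `fi`.
#' @export
infer_fi <- function(h_now, h_next, fij_star, ms, dt) {
  dt <- check_count(dt, "dt", lower = 1L)
  if (!is.null(h_now$gen) && !is.null(h_next$gen) &&
      h_now$gen + dt != h_next$gen)
    stop_invalid("h_now$gen + dt must equal h_next$gen")
  as.vector((h_next$h - h_now$h) / dt - fij_star %*% ms$chi_i)
}

#' Average per-interval additive estimates
#'
#' @param per_interval list of length-L numeric vectors.
#' @return list with `fi_star` (unweighted mean across intervals) and
#'   `spread` (per-locus standard deviation across intervals, 0 for a single
#'   interval).
#' @export
aggregate_fi <- function(per_interval) {
  if (!length(per_interval)) stop_invalid("no per-interval estimates supplied")
  M <- do.call(rbind, per_interval)
  spread <- if (nrow(M) > 1L) apply(M, 2L, stats::sd) else numeric(ncol(M))
  list(fi_star = colMeans(M), spread = spread)
}

#' Additive-only tQLE inference from a moment series
#'
#' The no-epistasis reduction: `h_i(t) = atanh(chi_i(t))` and
#' `fi* = mean over intervals of [h(t+dt) - h(t)] / dt`.
#'
#' @param series list of `moment_set` objects at increasing generations (as
#'   from [frequency_trajectory()]`$sets`, or pooled per generation).
#' @return list with `fi_star`, `spread` and `per_interval`.
#' @export
infer_additive_only <- function(series) {
  if (length(series) < 2L)
    stop_invalid("need at least two time points for additive-only inference")
  gens <- vapply(series, `[[`, numeric(1L), "gen")
  h <- lapply(series, function(ms) atanh(ms$chi_i))
  per <- lapply(seq_len(length(series) - 1L), function(k)
    (h[[k + 1L]] - h[[k]]) / (gens[k + 1L] - gens[k]))
  c(aggregate_fi(per), list(per_interval = per))
}

#' Full tQLE inference from replicate trajectories
#'
#' Per generation, fields are estimated from moments pooled across
#' replicates at that generation; couplings from moments pooled cumulatively
#' over all generations up to the current one and across replicates.  The
#' additive estimate averages the per-interval field differences minus the
#' epistatic feedback; the epistatic estimate reported is the one from the
#' final (all-data) cumulative pool.
#'
#' @param trajs a `trajectory` or list of replicate trajectories.
#' @param variant `"nmf"`, `"nmf_rc"`, `"gc"` for full inference, or
#'   `"additive"` for the no-epistasis reduction (no couplings computed,
#'   `fij_star` absent).
#' @param lambda pseudocount for moment estimation.
#' @param r,c,mu evolutionary rates; defaults are taken from the trajectory
#'   configuration when present.
#' @param smooth_window optional odd width of a moving average applied to
#'   the field series before differencing (default 0 = off).
#' @param j_pooling moments used for coupling estimation: `"cumulative"`
#'   (default; all generations up to the current one, across replicates) or
#'   `"per_gen"` (the current generation only, across replicates).
#' @return an `inferred_landscape`: list with `L`, `fi_star`, `fij_star`
#'   (absent in additive mode), `method = "tqle"`, `variant`, `hyperparams`,
#'   `spread` and `unidentifiable` (monomorphic site indices).
#' @export
infer_tqle <- function(trajs, variant = c("nmf", "nmf_rc", "gc", "additive"),
                       lambda = 0.5, r = NULL, c = NULL, mu = NULL,
                       smooth_window = 0L,
                       j_pooling = c("cumulative", "per_gen")) {
  variant <- match.arg(variant)
  j_pooling <- match.arg(j_pooling)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  cfg <- trajs[[1L]]$config
  if (is.null(r)) r <- cfg$r
  if (is.null(c)) c <- if (!is.null(cfg$c)) cfg$c else 0.5
  if (is.null(mu)) mu <- cfg$mu
  gens <- generations(trajs[[1L]])
  K <- length(gens)
  if (K < 2L) stop_invalid("need at least two recorded generations")

  per_gen <- lapply(gens, function(g)
    pooled_moments(trajs, g, lambda = lambda, cumulative = FALSE))

  if (variant == "additive") {
    est <- infer_additive_only(per_gen)
    fij_star <- NULL
    J_final <- NULL
  } else {
    ## incremental cumulative accumulators for the coupling pool
    L <- cfg$L
    acc <- list(n = 0, plus = numeric(L), plus_plus = matrix(0, L, L), L = L)
    h_series <- vector("list", K)
    fij_by_gen <- vector("list", K)
    for (k in seq_len(K)) {
      for (tr in trajs) {
        rec <- tr$records[[k]]
        X <- (rec$geno + 1) / 2
        w <- as.numeric(rec$count)
        acc$n <- acc$n + sum(w)
        acc$plus <- acc$plus + as.vector(crossprod(X, w))
        acc$plus_plus <- acc$plus_plus + crossprod(X * sqrt(w))
      }
      ms_cum <- if (j_pooling == "cumulative")
        moments_from_counts(acc, gens[k], lambda) else per_gen[[k]]
      J <- infer_couplings_nmf(ms_cum)
      if (variant == "gc") {
        fij_by_gen[[k]] <- infer_fij(ms_cum, r = r, c = c, mu = mu,
                                     variant = "gc")
      } else {
        fij_by_gen[[k]] <- infer_fij(r = r, c = c, mu = mu, variant = variant,
                                     J = J)
      }
      h_series[[k]] <- list(gen = gens[k],
                            h = infer_fields_nmf(per_gen[[k]], J))
    }
    if (smooth_window > 1L) {
      hmat <- do.call(rbind, lapply(h_series, `[[`, "h"))
      hmat <- apply(hmat, 2L, function(col)
        stats::filter(col, rep(1 / smooth_window, smooth_window),
                      sides = 2L))
      for (k in seq_len(K))
        if (!anyNA(hmat[k, ])) h_series[[k]]$h <- hmat[k, ]
    }
    per <- lapply(seq_len(K - 1L), function(k)
      infer_fi(h_series[[k]], h_series[[k + 1L]], fij_by_gen[[k]],
               per_gen[[k]], dt = gens[k + 1L] - gens[k]))
    est <- aggregate_fi(per)
    full <- fij_by_gen[[K]]
    fij_star <- full * upper.tri(full)
  }

  mono <- monomorphic_sites(trajs)
  fi_star <- est$fi_star
  if (length(mono)) {
    ## no signal at sites never observed polymorphic: report the
    ## mutation-only balance (fi = 0) and flag them
    fi_star[mono] <- 0
    warning("monomorphic sites flagged unidentifiable: ",
            paste(mono, collapse = ", "))
  }
  out <- list(L = cfg$L, fi_star = fi_star, fij_star = fij_star,
              method = "tqle", variant = variant,
              hyperparams = list(r = r, c = c, mu = mu, lambda = lambda,
                                 smooth_window = smooth_window,
                                 j_pooling = j_pooling),
              spread = est$spread, unidentifiable = mono)
  if (variant == "additive") out$fij_star <- NULL
  structure(out, class = "inferred_landscape")
}
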