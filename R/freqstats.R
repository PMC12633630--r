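## Single- and pair-locus statistics from trajectory samples.
##
## Two equivalent conventions are carried side by side:
##   spin:      magnetisations chi_i = <s_i>, connected correlations
##              chi_ij = <s_i s_j> - <s_i><s_j>  (diagonal 1 - chi_i^2);
##   frequency: m_i = P(s_i = +1), m_ij = P(s_i = +1, s_j = +1),
## linked exactly by chi_i = 2 m_i - 1 and chi_ij = 4 (m_ij - m_i m_j).
##
## A pseudocount lambda (per pair table: lambda/4 to each of the four joint
## states, hence lambda/2 per single state) keeps |chi_i| < 1 so atanh stays
## finite and the correlation matrix positive definite on monomorphic sites.

## Raw weighted accumulators for a set of (geno, count) records.
accumulate_counts <- function(records) {
  L <- ncol(records[[1L]]$geno)
  n <- 0; s1 <- numeric(L); p11 <- matrix(0, L, L)
  for (rec in records) {
    X <- (rec$geno + 1) / 2
    w <- as.numeric(rec$count)
    n <- n + sum(w)
    s1 <- s1 + as.vector(crossprod(X, w))
    p11 <- p11 + crossprod(X * sqrt(w)) # t(X) %*% diag(w) %*% X
  }
  list(n = n, plus = s1, plus_plus = p11, L = L)
}

moments_from_counts <- function(acc, gen, lambda) {
  n <- acc$n; L <- acc$L
  m_i <- (acc$plus + lambda / 2) / (n + lambda)
  m_ij <- (acc$plus_plus + lambda / 4) / (n + lambda)
  diag(m_ij) <- m_i # joint (+,+) of a site with itself is the site itself
  chi_i <- 2 * m_i - 1
  chi_ij <- 4 * (m_ij - outer(m_i, m_i))
  chi_ij <- (chi_ij + t(chi_ij)) / 2
  structure(list(gen = gen, chi_i = chi_i, chi_ij = chi_ij,
                 m_i = m_i, m_ij = m_ij, n_samples = n, lambda = lambda),
            class = "moment_set")
}

#' Locus statistics at one generation of one trajectory
#'
#' Count-weighted allele frequencies, magnetisations and connected
#' correlations with pseudocount `lambda`.
#'
#' @param traj a `trajectory`.
#' @param gen recorded generation index.
#' @param lambda nonnegative pseudocount per pair table (default 0.5).
#' @return a `moment_set` with fields `gen`, `chi_i`, `chi_ij`, `m_i`,
#'   `m_ij`, `n_samples`, `lambda`.
#' @export
moments <- function(traj, gen, lambda = 0.5) {
  lambda <- check_scalar(lambda, "lambda", lower = 0)
  gens <- generations(traj)
  k <- match(gen, gens)
  if (is.na(k))
    stop(errorCondition(paste0("generation ", gen, " not recorded"),
                        class = c("fitbench_not_found", "error")))
  moments_from_counts(accumulate_counts(traj$records[k]), gen, lambda)
}

#' Pooled locus statistics across replicates
#'
#' With `cumulative = FALSE`, pools the samples at generation `gen` across
#' all trajectories.  With `cumulative = TRUE`, pools all samples from
#' generations `0..gen` across all trajectories (the accumulation rule used
#' for coupling estimation).
#'
#' @param trajs list of `trajectory` objects sharing a configuration.
#' @param gen generation index.
#' @param lambda pseudocount (see [moments()]).
#' @param cumulative pool over all generations up to `gen`?
#' @return a `moment_set`.
#' @export
pooled_moments <- function(trajs, gen, lambda = 0.5, cumulative = FALSE) {
  lambda <- check_scalar(lambda, "lambda", lower = 0)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  cfgs <- unique(vapply(trajs, function(tr) {
    if (is.null(tr$config)) return("")
    paste(tr$config$N, tr$config$L, tr$config$T, tr$config$r, tr$config$mu)
  }, character(1L)))
  if (length(cfgs) > 1L) stop_invalid("trajectories have mixed configurations")
  records <- list()
  for (tr in trajs) {
    gens <- generations(tr)
    keep <- if (cumulative) which(gens <= gen) else which(gens == gen)
    if (!length(keep))
      stop(errorCondition(paste0("generation ", gen, " not recorded"),
                          class = c("fitbench_not_found", "error")))
    records <- c(records, tr$records[keep])
  }
  moments_from_counts(accumulate_counts(records), gen, lambda)
}

#' Time series of locus statistics for one trajectory
#'
#' @param traj a `trajectory`.
#' @param lambda pseudocount (see [moments()]).
#' @return list with `sets` (one `moment_set` per recorded generation, in
#'   order), `gens` and `dt` (sampling intervals between consecutive
#'   records).
#' @export
frequency_trajectory <- function(traj, lambda = 0.5) {
  gens <- generations(traj)
  sets <- lapply(seq_along(gens), function(k)
    moments_from_counts(accumulate_counts(traj$records[k]), gens[k], lambda))
  list(sets = sets, gens = gens, dt = diff(gens))
}

#' Loci monomorphic in a pooled sample
#'
#' Sites whose raw pooled counts contain only one allele carry no inference
#' signal; they are reported so downstream estimates can be flagged as
#' unidentifiable rather than silently zero.
#'
#' @param trajs list of trajectories.
#' @return integer vector of monomorphic locus indices (possibly empty).
#' @export
monomorphic_sites <- function(trajs) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  acc <- accumulate_counts(unlist(lapply(trajs, `[[`, "records"),
                                  recursive = FALSE))
  which(acc$plus == 0 | acc$plus == acc$n)
}

#' Export a moment set as a long-format table
#'
#' @param ms a `moment_set`.
#' @return data.frame with columns `generation`, `i`, `j`, `statistic`,
#'   `value` (single-locus rows have `j = NA`).
#' @export
moments_long <- function(ms) {
  L <- length(ms$chi_i)
  singles <- data.frame(generation = ms$gen, i = seq_len(L), j = NA_integer_,
                        statistic = rep(c("m", "chi"), each = L),
                        value = c(ms$m_i, ms$chi_i), row.names = NULL)
  idx <- which(upper.tri(ms$chi_ij), arr.ind = TRUE)
  pairs <- data.frame(generation = ms$gen, i = idx[, 1L], j = idx[, 2L],
                      statistic = rep(c("m_pair", "chi_pair"),
                                      each = nrow(idx)),
                      value = c(ms$m_ij[idx], ms$chi_ij[idx]),
                      row.names = NULL)
  rbind(singles, pairs)
}
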