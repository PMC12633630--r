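## Discrete-generation haploid Wright-Fisher simulator with selection on a
## quadratic landscape, symmetric per-site mutation, outcrossing
## recombination with free reassortment between loci, and multinomial drift.

#' Simulation configuration
#'
#' @param N population size (individuals, >= 2).
#' @param L genome length (loci, >= 2).
#' @param T number of generations (>= 0; 0 records only the initial state).
#' @param r outcrossing rate: probability per offspring per generation of
#'   being produced sexually, in `[0, 1]`.
#' @param mu per-site per-generation symmetric mutation (spin-flip)
#'   probability, in `[0, 0.5]`.
#' @param n_replicates number of independent replicate populations.
#' @param seed root integer seed; replicate `k` uses the derived stream
#'   `derive_seed(seed, k, stage = 1)`.
#' @param init_mode one of `"uniform_random"` (each site of each founder is
#'   +/-1 with probability 1/2), `"monomorphic"` (all sites -1), or
#'   `"given_frequencies"` (sites drawn independently at
#'   `init_frequencies`).
#' @param init_frequencies length-`L` vector of +1-allele frequencies, used
#'   only with `init_mode = "given_frequencies"`.
#' @param sample_fraction fraction of the population recorded per generation
#'   (without replacement), in `(0, 1]`.
#' @param c pairwise recombination separation probability `c_ij`; under free
#'   reassortment every pair separates with probability 1/2, the default.
#'   Inference consumes only the product `r * c`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(N = 1000L, L = 25L, T = 30L, r = 0.5, mu = 0.01,
                       n_replicates = 1L, seed = 1L,
                       init_mode = c("uniform_random", "monomorphic",
                                     "given_frequencies"),
                       init_frequencies = NULL,
                       sample_fraction = 1, c = 0.5) {
  init_mode <- match.arg(init_mode)
  cfg <- list(
    N = check_count(N, "N", lower = 2L),
    L = check_count(L, "L", lower = 2L),
    T = check_count(T, "T", lower = 0L),
    r = check_scalar(r, "r", 0, 1),
    mu = check_scalar(mu, "mu", 0, 0.5),
    n_replicates = check_count(n_replicates, "n_replicates", lower = 1L),
    seed = check_count(seed, "seed", lower = 0L),
    init_mode = init_mode,
    init_frequencies = init_frequencies,
    sample_fraction = check_scalar(sample_fraction, "sample_fraction", 1e-12, 1),
    c = check_scalar(c, "c", 1e-12, 0.5)
  )
  if (init_mode == "given_frequencies") {
    if (is.null(init_frequencies) || length(init_frequencies) != cfg$L ||
        any(init_frequencies < 0) || any(init_frequencies > 1))
      stop_invalid("init_frequencies must be a length-L vector of values in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Initialise a population
#'
#' @param cfg a [sim_config()].  The caller is responsible for seeding the
#'   RNG; [run_replicate()] does this through the derived replicate stream.
#' @return a `population`: list with `geno` (matrix of unique genotypes,
#'   +/-1) and `count` (positive integers summing to `N`).
#' @export
init_population <- function(cfg) {
  N <- cfg$N; L <- cfg$L
  S <- switch(cfg$init_mode,
    uniform_random = matrix(ifelse(stats::runif(N * L) < 0.5, -1L, 1L), N, L),
    monomorphic = matrix(-1L, N, L),
    given_frequencies = {
      p <- rep(cfg$init_frequencies, each = N)
      matrix(ifelse(stats::runif(N * L) < p, 1L, -1L), N, L)
    })
  pop <- compress_genotypes(S)
  structure(pop, class = "population")
}

## One generation on the expanded N x L matrix; internal hot path.
## Order within a generation: selection + drift -> recombination -> mutation.
step_matrix <- function(S, fl, cfg) {
  N <- nrow(S); L <- ncol(S)
  ## selection + drift: multinomial resampling with weight exp(F(g))
  Fg <- fitness_of(S, fl)$total
  w <- exp(Fg - max(Fg)) # f0 and common shifts cancel
  S <- S[sample.int(N, N, replace = TRUE, prob = w), , drop = FALSE]
  ## recombination: with probability r an offspring is a free recombinant of
  ## itself and a uniformly chosen second parent from the post-selection pool
  if (cfg$r > 0) {
    rec <- which(stats::runif(N) < cfg$r)
    if (length(rec)) {
      partners <- sample.int(N, length(rec), replace = TRUE)
      take <- matrix(stats::runif(length(rec) * L) < 0.5, length(rec), L)
      block <- S[rec, , drop = FALSE]
      pblock <- S[partners, , drop = FALSE]
      block[take] <- pblock[take]
      S[rec, ] <- block
    }
  }
  ## mutation: independent symmetric spin flips
  if (cfg$mu > 0) {
    flip <- matrix(stats::runif(N * L) < cfg$mu, N, L)
    S[flip] <- -S[flip]
  }
  S
}

#' Advance a population by one generation
#'
#' Applies, in order: selection with multinomial drift (offspring drawn with
#' probability proportional to `exp(F)`), outcrossing recombination with free
#' reassortment, and symmetric per-site mutation.  Population size is
#' conserved exactly.
#'
#' @param pop a `population` as returned by [init_population()].
#' @param fl the generating [fitness_landscape()].
#' @param cfg a [sim_config()].
#' @return the next-generation `population`.
#' @export
step <- function(pop, fl, cfg) {
  if (length(pop$count) == 0L || sum(pop$count) == 0L)
    stop("cannot step an empty population")
  S <- pop$geno[rep(seq_along(pop$count), pop$count), , drop = FALSE]
  structure(compress_genotypes(step_matrix(S, fl, cfg)), class = "population")
}

#' Run one simulation replicate
#'
#' Records the generation-0 sample and then `T` stepped generations.  With
#' `sample_fraction < 1` each recorded sample is drawn without replacement
#' from the population.  Fully reproducible from `(cfg$seed, replicate_id)`.
#'
#' @param fl generating [fitness_landscape()].
#' @param cfg a [sim_config()].
#' @param replicate_id positive integer identifying the replicate stream.
#' @return a `trajectory`: list with `replicate_id`, `config`,
#'   `landscape_ref` and `records`, an ordered list of
#'   `list(gen, geno, count)` with counts summing to
#'   `round(N * sample_fraction)`.
#' @export
run_replicate <- function(fl, cfg, replicate_id = 1L) {
  replicate_id <- check_count(replicate_id, "replicate_id", lower = 1L)
  if (fl$L != cfg$L) stop_invalid("landscape and config disagree on L")
  set.seed(derive_seed(cfg$seed, replicate_id, stage = 1L))
  n_keep <- max(1L, as.integer(round(cfg$N * cfg$sample_fraction)))
  record <- function(S, gen) {
    if (n_keep < nrow(S)) S <- S[sample.int(nrow(S), n_keep), , drop = FALSE]
    c(list(gen = gen), compress_genotypes(S))
  }
  pop0 <- init_population(cfg)
  S <- pop0$geno[rep(seq_along(pop0$count), pop0$count), , drop = FALSE]
  records <- vector("list", cfg$T + 1L)
  records[[1L]] <- record(S, 0L)
  if (cfg$T >= 1L) for (g in seq_len(cfg$T)) {
    S <- step_matrix(S, fl, cfg)
    records[[g + 1L]] <- record(S, g)
  }
  structure(list(replicate_id = replicate_id, config = cfg,
                 landscape_ref = fl$meta$seed, records = records),
            class = "trajectory")
}

#' Run all replicates of a configuration
#'
#' @inheritParams run_replicate
#' @return list of `trajectory` objects, one per replicate.
#' @export
run_replicates <- function(fl, cfg) {
  lapply(seq_len(cfg$n_replicates), function(k) run_replicate(fl, cfg, k))
}

#' Generations recorded in a trajectory
#' @param traj a `trajectory`.
#' @return integer vector of recorded generation indices.
#' @export
generations <- function(traj) {
  vapply(traj$records, function(rec) as.integer(rec$gen), integer(1L))
}
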