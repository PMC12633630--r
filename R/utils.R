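#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules: argument checks, reproducible
## seed streams, genotype encodings and a weighted Kolmogorov-Smirnov
## distance.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("fitbench_invalid_argument", "error")))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_invalid(name, " must be a single number in [", lower, ", ", upper, "]")
  as.numeric(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x != round(x))
    stop_invalid(name, " must be an integer >= ", lower)
  as.integer(x)
}

#' Derive an independent child seed from a root seed
#'
#' Replicates, landscapes and experiment stages each get their own RNG
#' stream through a fixed affine map modulo a Mersenne prime, so that any
#' single replicate can be regenerated without rerunning the others and
#' adding replicates never perturbs earlier ones.
#'
#' @param seed root integer seed.
#' @param stream nonnegative integer stream index.
#' @param stage optional small integer separating stages (landscape = 0,
#'   replicates = 1, ...).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream, stage = 0L) {
  seed <- check_count(seed, "seed", lower = 0L)
  stream <- check_count(stream, "stream", lower = 0L)
  stage <- check_count(stage, "stage", lower = 0L)
  m <- 2147483629 # prime < 2^31; products below stay exact in doubles
  x <- (as.numeric(seed) %% m)
  x <- (x * 48271 + as.numeric(stage) * 16807 + as.numeric(stream) + 1) %% m
  x <- (x * 69621 + 12345) %% m
  as.integer(x)
}

## ---- genotype conventions -------------------------------------------------

#' Convert spin genotypes (-1/+1) to allele indicators (0/1)
#'
#' The simulator and the quasi-linkage-equilibrium formulas work in the
#' spin convention s in {-1, +1}; the path-likelihood estimator and the
#' file formats use allele indicators x in {0, 1} with x = (s + 1) / 2.
#'
#' @param s vector or matrix with entries -1/+1.
#' @return object of the same shape with entries 0/1.
#' @export
spin_to_allele <- function(s) {
  if (!all(abs(s) == 1)) stop_invalid("spin genotypes must have entries -1 or +1")
  x <- (s + 1) / 2
  storage.mode(x) <- storage.mode(s)
  x
}

#' Convert allele indicators (0/1) to spin genotypes (-1/+1)
#' @param x vector or matrix with entries 0/1.
#' @return object of the same shape with entries -1/+1.
#' @export
allele_to_spin <- function(x) {
  if (!all(x %in% c(0, 1))) stop_invalid("allele indicators must be 0 or 1")
  s <- 2 * x - 1
  storage.mode(s) <- storage.mode(x)
  s
}

## Integer keys for genotype rows (exact for L <= 52); used for dedup and
## counting.  Falls back to string keys for longer genomes.
genotype_keys <- function(S) {
  L <- ncol(S)
  X <- (S + 1) / 2
  if (L <= 52) as.vector(X %*% 2^(seq_len(L) - 1))
  else apply(X, 1L, paste0, collapse = "")
}

## Collapse a genotype matrix (rows = individuals) into unique rows + counts.
compress_genotypes <- function(S, w = NULL) {
  keys <- genotype_keys(S)
  first <- !duplicated(keys)
  idx <- match(keys, keys[first])
  n_unique <- sum(first)
  if (is.null(w)) {
    counts <- tabulate(idx, nbins = n_unique)
  } else {
    counts <- as.vector(rowsum(w, idx))
  }
  list(geno = S[first, , drop = FALSE], count = counts)
}

## Two-sample Kolmogorov-Smirnov distance for count-weighted samples.
weighted_ks_distance <- function(x, wx, y, wy) {
  ox <- order(x); oy <- order(y)
  x <- x[ox]; wx <- wx[ox] / sum(wx)
  y <- y[oy]; wy <- wy[oy] / sum(wy)
  grid <- sort(unique(c(x, y)))
  Fx <- c(0, cumsum(wx))[findInterval(grid, x) + 1L]
  Fy <- c(0, cumsum(wy))[findInterval(grid, y) + 1L]
  max(abs(Fx - Fy))
}
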