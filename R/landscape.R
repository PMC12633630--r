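## Quadratic fitness landscapes over binary (spin) genomes.
##
## Log-fitness of a genotype s in {-1,+1}^L is
##   F(s) = f0 + sum_i fi * s_i + sum_{i<j} fij * s_i * s_j,
## with additive effects fi and pairwise epistatic effects fij.  The offset
## f0 shifts every genotype equally and is never an inference target.

#' Construct a fitness landscape
#'
#' @param L number of loci (>= 2).
#' @param fi length-`L` vector of additive effects (log-fitness units).
#' @param fij strictly upper-triangular `L x L` matrix of pairwise epistatic
#'   effects; entries on or below the diagonal must be zero.  A value for the
#'   unordered pair \{i, j\} is stored once at `[min(i,j), max(i,j)]`.
#' @param f0 scalar log-fitness offset; defaults to 0.
#' @param meta optional list of provenance (sigmas, seed).
#' @return an object of class `fitness_landscape`.
#' @seealso [sample_landscape()], [fitness_of()]
#' @export
fitness_landscape <- function(L, fi = numeric(L), fij = matrix(0, L, L),
                              f0 = 0, meta = list()) {
  L <- check_count(L, "L", lower = 2L)
  f0 <- check_scalar(f0, "f0")
  if (length(fi) != L) stop_invalid("fi must have length L = ", L)
  if (!is.matrix(fij) || any(dim(fij) != L))
    stop_invalid("fij must be an L x L matrix")
  if (any(fij[lower.tri(fij, diag = TRUE)] != 0))
    stop_invalid("fij must be strictly upper triangular (zero on and below the diagonal)")
  structure(list(L = L, f0 = f0, fi = as.numeric(fi), fij = fij, meta = meta),
            class = "fitness_landscape")
}

#' Draw a random quadratic fitness landscape
#'
#' Additive effects are i.i.d. Normal(0, `sigma_fi`) and each pairwise
#' epistatic effect (i < j) is i.i.d. Normal(0, `sigma_fij`).  With a sigma
#' of zero the corresponding coefficients are exactly zero.
#'
#' @param L number of loci (>= 2).
#' @param sigma_fi standard deviation of additive effects (>= 0).
#' @param sigma_fij standard deviation of pairwise epistatic effects (>= 0).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return a [fitness_landscape()] with `f0 = 0`.
#' @export
sample_landscape <- function(L, sigma_fi, sigma_fij, seed) {
  L <- check_count(L, "L", lower = 2L)
  sigma_fi <- check_scalar(sigma_fi, "sigma_fi", lower = 0)
  sigma_fij <- check_scalar(sigma_fij, "sigma_fij", lower = 0)
  seed <- check_count(seed, "seed", lower = 0L)
  set.seed(seed)
  fi <- if (sigma_fi > 0) stats::rnorm(L, 0, sigma_fi) else numeric(L)
  fij <- matrix(0, L, L)
  up <- upper.tri(fij)
  n_pairs <- sum(up)
  if (sigma_fij > 0) fij[up] <- stats::rnorm(n_pairs, 0, sigma_fij)
  fitness_landscape(L, fi = fi, fij = fij, f0 = 0,
                    meta = list(sigma_fi = sigma_fi, sigma_fij = sigma_fij,
                                seed = seed))
}

#' Symmetric epistasis matrix of a landscape
#'
#' Expands the strictly upper-triangular storage into the full symmetric
#' zero-diagonal matrix `M` with `M[i, j] = M[j, i] = fij`.
#'
#' @param fl a `fitness_landscape` (or inferred landscape with `fij_star`).
#' @return `L x L` symmetric numeric matrix.
#' @export
epistasis_matrix <- function(fl) {
  fij <- if (!is.null(fl$fij)) fl$fij else fl$fij_star
  if (is.null(fij)) return(matrix(0, fl$L, fl$L))
  fij + t(fij)
}

#' Evaluate the fitness of genotypes
#'
#' Computes total, additive and epistatic log-fitness for one genotype
#' (a +/-1 vector) or for each row of a genotype matrix.  The decomposition
#' is exact: `total - f0 = additive + epistatic`.
#'
#' @param g genotype vector with entries -1/+1, or a matrix with one genotype
#'   per row.
#' @param fl a [fitness_landscape()].
#' @return a list with numeric components `total`, `additive`, `epistatic`
#'   (each of length `nrow(g)` for matrix input).
#' @export
fitness_of <- function(g, fl) {
  S <- if (is.matrix(g)) g else matrix(g, nrow = 1L)
  if (ncol(S) != fl$L)
    stop_invalid("genotype length ", ncol(S), " does not match landscape L = ", fl$L)
  if (!all(abs(S) == 1)) stop_invalid("genotype entries must be -1 or +1")
  additive <- as.vector(S %*% fl$fi)
  M <- epistasis_matrix(fl)
  epistatic <- 0.5 * rowSums((S %*% M) * S)
  list(total = fl$f0 + additive + epistatic,
       additive = additive, epistatic = epistatic)
}

#' Reproductive weight of genotypes
#'
#' Maps log-fitness to a positive sampling weight `exp(F(g))` (Malthusian
#' growth-rate semantics).  Selection acts on weight ratios, so any shift of
#' `f0` rescales all weights by a common factor and leaves expected offspring
#' frequencies unchanged.
#'
#' @inheritParams fitness_of
#' @return positive numeric vector of weights.
#' @export
reproductive_weight <- function(g, fl) {
  exp(fitness_of(g, fl)$total)
}

#' Write a landscape to a structured-text (JSON) file
#'
#' The file stores `L`, `f0`, the `fi` vector, the epistatic effects as
#' `[i, j, value]` triplets with 1-based indices `i < j`, and metadata.
#' The round trip through [read_landscape()] is lossless at full double
#' precision.
#'
#' @param fl a `fitness_landscape` or inferred landscape.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(fl, path) {
  fij <- if (!is.null(fl$fij)) fl$fij else fl$fij_star
  triplets <- list()
  if (!is.null(fij)) {
    idx <- which(upper.tri(fij) & fij != 0, arr.ind = TRUE)
    triplets <- lapply(seq_len(nrow(idx)), function(k)
      list(i = unname(idx[k, 1L]), j = unname(idx[k, 2L]),
           value = fij[idx[k, 1L], idx[k, 2L]]))
  }
  obj <- list(L = fl$L, f0 = if (is.null(fl$f0)) 0 else fl$f0,
              index_base = 1L,
              fi = if (!is.null(fl$fi)) fl$fi else fl$fi_star,
              fij = triplets,
              meta = fl$meta)
  if (!is.null(fl$method)) obj$method <- fl$method
  if (!is.null(fl$hyperparams)) obj$hyperparams <- fl$hyperparams
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a landscape from a JSON file written by [write_landscape()]
#'
#' @param path input file path.
#' @return a `fitness_landscape` (with `method`/`hyperparams` attached if the
#'   file carries inference metadata).
#' @export
read_landscape <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  L <- as.integer(obj$L)
  fij <- matrix(0, L, L)
  if (!is.null(obj$fij) && length(obj$fij)) {
    tr <- obj$fij
    for (k in seq_len(nrow(tr)))
      fij[tr$i[k], tr$j[k]] <- tr$value[k]
  }
  fl <- fitness_landscape(L, fi = obj$fi, fij = fij, f0 = obj$f0,
                          meta = as.list(obj$meta))
  if (!is.null(obj$method)) {
    fl$method <- obj$method
    fl$hyperparams <- as.list(obj$hyperparams)
  }
  fl
}
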