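## Independent oracles used across the suite.  These deliberately avoid the
## package's own moment/inference code paths: enumeration, naive counting
## and closed-form recursions only.

## Exact moments of an Ising distribution P(s) ~ exp(h.s + sum_{i<j} J s s)
## by full enumeration over 2^L states.  Returns a moment_set-shaped list.
enumerate_ising_moments <- function(h, J) {
  L <- length(h)
  states <- as.matrix(expand.grid(rep(list(c(-1, 1)), L)))
  colnames(states) <- NULL
  ## J symmetric zero-diagonal; energy sum_{i<j} J_ij s_i s_j = s'Js / 2
  E <- as.vector(states %*% h) + 0.5 * rowSums((states %*% J) * states)
  p <- exp(E - max(E)); p <- p / sum(p)
  chi_i <- as.vector(crossprod(states, p))
  ss <- crossprod(states * sqrt(p)) # <s_i s_j>
  chi_ij <- ss - outer(chi_i, chi_i)
  m_i <- (chi_i + 1) / 2
  X <- (states + 1) / 2
  m_ij <- crossprod(X * sqrt(p))
  diag(m_ij) <- m_i
  structure(list(gen = 0L, chi_i = chi_i, chi_ij = chi_ij,
                 m_i = m_i, m_ij = m_ij, n_samples = Inf, lambda = 0),
            class = "moment_set")
}

## Naive (loop-based) weighted moment counter, the brute-force oracle for
## the freqstats module.  No pseudocount.
naive_moments <- function(S, w) {
  L <- ncol(S); n <- sum(w)
  m_i <- numeric(L); m_ij <- matrix(0, L, L)
  for (i in seq_len(L)) {
    m_i[i] <- sum(w[S[, i] == 1]) / n
    for (j in seq_len(L))
      m_ij[i, j] <- sum(w[S[, i] == 1 & S[, j] == 1]) / n
  }
  chi_i <- 2 * m_i - 1
  chi_ij <- 4 * (m_ij - outer(m_i, m_i))
  list(m_i = m_i, m_ij = m_ij, chi_i = chi_i, chi_ij = chi_ij)
}

## Deterministic haploid selection-mutation recursion for one locus with
## spin effect fi and symmetric mutation mu: frequency m of the +1 allele.
recursion_step <- function(m, fi, mu) {
  msel <- m * exp(2 * fi) / (m * exp(2 * fi) + (1 - m))
  msel + mu * (1 - 2 * msel)
}

## Build a trajectory object by hand from a list of (gen, geno, count).
make_traj <- function(records, cfg = NULL, replicate_id = 1L) {
  structure(list(replicate_id = replicate_id, config = cfg,
                 landscape_ref = NULL, records = records),
            class = c("trajectory"))
}

## A tiny deterministic two-locus landscape used in several files.
tiny_landscape <- function(f1 = 0.1, f2 = -0.2, f12 = 0.05, f0 = 0) {
  m <- matrix(0, 2, 2); m[1, 2] <- f12
  fitness_landscape(2, fi = c(f1, f2), fij = m, f0 = f0)
}
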