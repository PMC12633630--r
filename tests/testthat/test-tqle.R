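test_that("independent loci give zero couplings and atanh fields", {
  ms <- enumerate_ising_moments(h = c(0, 0, 0), J = matrix(0, 3, 3))
  J <- infer_couplings_nmf(ms)
  expect_equal(J, matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(infer_fields_nmf(ms, J), rep(0, 3), tolerance = 1e-12)
  ## chi_i = tanh(0.3), J = 0 -> h = 0.3 exactly
  ms2 <- enumerate_ising_moments(h = rep(0.3, 4), J = matrix(0, 4, 4))
  expect_equal(infer_fields_nmf(ms2, matrix(0, 4, 4)), rep(0.3, 4))
})

test_that("two-spin coupling matches the closed-form nMF value", {
  ## exact chi_12 = tanh(J); nMF returns tanh(J) / (1 - tanh(J)^2)
  J <- matrix(0, 2, 2); J[1, 2] <- J[2, 1] <- 0.05
  ms <- enumerate_ising_moments(c(0, 0), J)
  expect_equal(ms$chi_ij[1, 2], tanh(0.05), tolerance = 1e-12)
  Jhat <- infer_couplings_nmf(ms)
  t05 <- tanh(0.05)
  expect_equal(Jhat[1, 2], t05 / (1 - t05^2), tolerance = 1e-10)
  expect_lt(abs(Jhat[1, 2] - 0.05) / 0.05, 0.002) # relative error < 0.2%
})

test_that("nMF recovers weak-coupling Ising parameters from exact moments", {
  set.seed(6)
  for (case in 1:5) {
    L <- 5
    J <- matrix(0, L, L)
    J[upper.tri(J)] <- runif(choose(L, 2), -0.05, 0.05)
    J <- J + t(J)
    h <- runif(L, -0.2, 0.2)
    ms <- enumerate_ising_moments(h, J)
    Jhat <- infer_couplings_nmf(ms)
    hhat <- infer_fields_nmf(ms, Jhat)
    expect_lt(max(abs(Jhat - J)), 0.01)
    expect_lt(max(abs(hhat - h)), 0.02)
  }
  ## L = 3 fields at the spec scale
  J3 <- matrix(0, 3, 3); J3[upper.tri(J3)] <- c(0.02, -0.02, 0.02)
  J3 <- J3 + t(J3)
  ms3 <- enumerate_ising_moments(c(0.1, -0.1, 0.2), J3)
  h3 <- infer_fields_nmf(ms3, infer_couplings_nmf(ms3))
  expect_lt(max(abs(h3 - c(0.1, -0.1, 0.2))), 0.02)
})

test_that("nMF error vanishes as couplings weaken (gauge consistency)", {
  set.seed(9)
  L <- 6
  base <- matrix(0, L, L)
  base[upper.tri(base)] <- runif(choose(L, 2), -1, 1)
  base <- base + t(base)
  h <- runif(L, -0.1, 0.1)
  errs <- vapply(c(0.08, 0.04, 0.02, 0.01), function(scale) {
    J <- base * scale
    ms <- enumerate_ising_moments(h, J)
    max(abs(infer_couplings_nmf(ms) - J))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("epistasis estimators follow their defining formulas", {
  L <- 3
  J <- matrix(0, L, L); J[1, 2] <- J[2, 1] <- 0.1
  ## (r c + 4 mu) J = (0.25 + 0.04) * 0.1; r c J = 0.025
  f5 <- infer_fij(r = 0.5, c = 0.5, mu = 0.01, variant = "nmf", J = J)
  expect_equal(f5[1, 2], 0.029)
  f4 <- infer_fij(r = 0.5, c = 0.5, mu = 0.01, variant = "nmf_rc", J = J)
  expect_equal(f4[1, 2], 0.025)
  ## zero couplings/correlations give zero epistasis under all variants
  ms0 <- enumerate_ising_moments(rep(0.2, L), matrix(0, L, L))
  for (v in c("nmf", "nmf_rc", "gc"))
    expect_equal(max(abs(infer_fij(ms0, r = 0.5, c = 0.5, mu = 0.01,
                                   variant = v))), 0, tolerance = 1e-12)
  ## Gaussian-closure formula, hand-evaluated
  msx <- enumerate_ising_moments(c(0, 0), matrix(c(0, 0.1, 0.1, 0), 2, 2))
  fgc <- infer_fij(msx, r = 0.5, c = 0.5, mu = 0.01, variant = "gc")
  expect_equal(fgc[1, 2],
               0.29 * msx$chi_ij[1, 2] /
                 ((1 - msx$chi_i[1]^2) * (1 - msx$chi_i[2]^2)))
  expect_error(infer_fij(r = 0, c = 0.5, mu = 0, variant = "nmf_rc", J = J),
               class = "fitbench_invalid_argument")
})

test_that("per-interval additive estimates follow the field differences", {
  L <- 3
  ms <- enumerate_ising_moments(rep(0.1, L), matrix(0, L, L))
  zeroJ <- matrix(0, L, L)
  h1 <- list(gen = 0L, h = c(0.1, 0.2, 0.3))
  ## constant fields, no epistasis -> zero
  expect_equal(infer_fi(h1, list(gen = 1L, h = h1$h), zeroJ, ms, dt = 1),
               rep(0, 3))
  ## a field jump of 0.02 over dt = 1
  h2 <- list(gen = 1L, h = h1$h + 0.02)
  expect_equal(infer_fi(h1, h2, zeroJ, ms, dt = 1), rep(0.02, 3))
  ## epistatic feedback subtracts fij* %*% chi
  fij <- matrix(0, L, L); fij[1, 2] <- fij[2, 1] <- 0.5
  expect_equal(infer_fi(h1, h2, fij, ms, dt = 1),
               0.02 - 0.5 * ms$chi_i[c(2, 1, 3)] * c(1, 1, 0))
  expect_error(infer_fi(h1, list(gen = 5L, h = h1$h), zeroJ, ms, dt = 1),
               class = "fitbench_invalid_argument")
})

test_that("interval aggregation averages and reports spread", {
  one <- list(c(0.1, -0.2))
  expect_equal(aggregate_fi(one)$fi_star, c(0.1, -0.2))
  expect_equal(aggregate_fi(one)$spread, c(0, 0))
  const <- rep(list(c(0.3, 0.3)), 4)
  expect_equal(aggregate_fi(const)$fi_star, c(0.3, 0.3))
  expect_equal(aggregate_fi(const)$spread, c(0, 0))
  alt <- rep(list(c(0.2), c(-0.2)), 3)
  agg <- aggregate_fi(alt)
  expect_equal(agg$fi_star, 0)
  expect_equal(agg$spread, sd(rep(c(0.2, -0.2), 3)))
  expect_error(aggregate_fi(list()), class = "fitbench_invalid_argument")
})

test_that("additive-only inference matches the deterministic recursion", {
  ## stationary magnetisations give zero
  g <- rbind(c(1L, 1L), c(-1L, -1L))
  sets <- lapply(0:3, function(t)
    moments(make_traj(list(list(gen = t, geno = g, count = c(3L, 1L)))),
            t, lambda = 0))
  expect_equal(infer_additive_only(sets)$fi_star, c(0, 0), tolerance = 1e-12)
  expect_error(infer_additive_only(sets[1]), class = "fitbench_invalid_argument")

  ## deterministic selection-mutation recursion, fi = 0.05, mu = 0.003:
  ## estimate from exact consecutive frequencies within 15% of truth
  m <- 0.4
  mseq <- Reduce(function(mm, .) recursion_step(mm, 0.05, 0.003), 1:2,
                 accumulate = TRUE, init = m)
  sets2 <- lapply(seq_along(mseq), function(k) {
    chi <- 2 * mseq[k] - 1
    structure(list(gen = k - 1L, chi_i = chi, chi_ij = matrix(1 - chi^2),
                   m_i = mseq[k], m_ij = matrix(mseq[k]),
                   n_samples = Inf, lambda = 0), class = "moment_set")
  })
  est <- infer_additive_only(sets2[1:2])
  expect_lt(abs(est$fi_star - 0.05) / 0.05, 0.15)
})

test_that("the additive variant is the J = 0 reduction of the full pipeline", {
  fl <- sample_landscape(6, 0.03, 0, seed = 18)
  cfg <- sim_config(N = 400, L = 6, T = 10, r = 0.5, mu = 0.01, seed = 6)
  tr <- run_replicate(fl, cfg, 1)
  add <- suppressWarnings(infer_tqle(tr, variant = "additive"))
  full <- suppressWarnings(infer_tqle(tr, variant = "nmf"))
  ## additive variant equals the plain field-difference estimator on the
  ## same per-generation moments, and never carries couplings
  gens <- generations(tr)
  sets <- lapply(gens, function(g) pooled_moments(tr, g, lambda = 0.5))
  expect_equal(add$fi_star, infer_additive_only(sets)$fi_star)
  expect_null(add$fij_star)
  expect_false(is.null(full$fij_star))
})

test_that("tQLE recovers additive effects in a single replicate", {
  fl <- sample_landscape(25, 0.05, 0, seed = 40)
  cfg <- sim_config(N = 1000, L = 25, T = 30, r = 0.5, mu = 0.01, seed = 40)
  tr <- run_replicate(fl, cfg, 1)
  est <- suppressWarnings(infer_tqle(tr, variant = "additive"))
  expect_gt(cor(est$fi_star, fl$fi), 0.7)
})

test_that("tQLE recovers pairwise epistasis in the epistasis-dominated regime", {
  fl <- sample_landscape(25, 0.005, 0.002, seed = 50)
  cfg <- sim_config(N = 1000, L = 25, T = 30, r = 0.5, mu = 0.01,
                    n_replicates = 10, seed = 50)
  trs <- run_replicates(fl, cfg)
  est <- suppressWarnings(infer_tqle(trs, variant = "nmf"))
  up <- upper.tri(fl$fij)
  expect_gt(cor(est$fij_star[up], fl$fij[up], method = "spearman"), 0.3)
})
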