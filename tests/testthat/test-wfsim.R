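neutral2 <- function(seed = 1) sample_landscape(2, 0, 0, seed = seed)

pop_freq <- function(pop, locus = 1L) {
  sum(pop$count[pop$geno[, locus] == 1]) / sum(pop$count)
}

test_that("population initialisation honours each mode", {
  cfg <- sim_config(N = 10, L = 4, T = 1, seed = 1, init_mode = "monomorphic")
  set.seed(1); pop <- init_population(cfg)
  expect_equal(length(pop$count), 1L)
  expect_equal(pop$count, 10)
  expect_true(all(pop$geno == -1))

  cfgb <- sim_config(N = 50, L = 3, T = 1, seed = 1,
                     init_mode = "given_frequencies",
                     init_frequencies = c(1, 1, 1))
  set.seed(1); popb <- init_population(cfgb)
  expect_true(all(popb$geno == 1)) # boundary frequency

  ## uniform start: per-site frequency within 0.5 +/- 0.05 (binomial tail
  ## bound at n = 1000 gives coverage > 0.99 across all 25 sites)
  cfgu <- sim_config(N = 1000, L = 25, T = 1, seed = 1)
  set.seed(7); popu <- init_population(cfgu)
  freqs <- colSums(popu$count * (popu$geno == 1)) / 1000
  expect_true(all(abs(freqs - 0.5) < 0.05))

  expect_error(sim_config(N = 10, L = 3, T = 1, init_mode = "given_frequencies",
                          init_frequencies = c(0.5, 2, 0.1)),
               class = "fitbench_invalid_argument")
})

test_that("every generation conserves population size and sample counts", {
  fl <- sample_landscape(6, 0.05, 0.01, seed = 2)
  cfg <- sim_config(N = 120, L = 6, T = 8, r = 0.5, mu = 0.02, seed = 9)
  tr <- run_replicate(fl, cfg, 1)
  expect_equal(generations(tr), 0:8)
  for (rec in tr$records) expect_equal(sum(rec$count), 120)
  ## subsampled recording
  cfg2 <- sim_config(N = 120, L = 6, T = 3, seed = 9, sample_fraction = 0.25)
  tr2 <- run_replicate(fl, cfg2, 1)
  for (rec in tr2$records) expect_equal(sum(rec$count), 30)
})

test_that("replicates are reproducible and T = 0 records only the start", {
  fl <- sample_landscape(5, 0.02, 0, seed = 3)
  cfg <- sim_config(N = 60, L = 5, T = 6, r = 0.3, mu = 0.01, seed = 17)
  expect_identical(run_replicate(fl, cfg, 2), run_replicate(fl, cfg, 2))
  expect_false(identical(run_replicate(fl, cfg, 1)$records,
                         run_replicate(fl, cfg, 2)$records))
  cfg0 <- sim_config(N = 60, L = 5, T = 0, seed = 17)
  expect_length(run_replicate(fl, cfg0, 1)$records, 1L)
})

test_that("neutral drift is a martingale in allele frequency", {
  fl <- neutral2()
  cfg <- sim_config(N = 1000, L = 2, T = 1, r = 0, mu = 0, seed = 1,
                    init_mode = "given_frequencies",
                    init_frequencies = c(0.3, 0.5))
  set.seed(5); pop <- init_population(cfg)
  m0 <- pop_freq(pop)
  set.seed(101)
  ms <- replicate(500, pop_freq(step(pop, fl, cfg)))
  expect_lt(abs(mean(ms) - m0), 0.01)
})

test_that("mutation moves frequencies by mu (1 - 2 m) in expectation", {
  fl <- neutral2()
  ## from the monomorphic -1 boundary one step gives E[m'] = mu
  cfg <- sim_config(N = 1000, L = 2, T = 1, r = 0, mu = 0.01, seed = 1,
                    init_mode = "monomorphic")
  pop <- init_population(cfg)
  set.seed(8)
  ms <- replicate(400, pop_freq(step(pop, fl, cfg)))
  expect_lt(abs(mean(ms) - 0.01), 0.0015)
  ## from an interior frequency
  cfgi <- sim_config(N = 1000, L = 2, T = 1, r = 0, mu = 0.01, seed = 1,
                     init_mode = "given_frequencies",
                     init_frequencies = c(0.3, 0.5))
  set.seed(9); popi <- init_population(cfgi)
  m0 <- pop_freq(popi)
  set.seed(10)
  msi <- replicate(800, pop_freq(step(popi, fl, cfgi)))
  expect_lt(abs(mean(msi) - m0 - 0.01 * (1 - 2 * m0)), 0.002)
})

test_that("selection follows the deterministic replicator recursion", {
  ## single selected locus fi = 0.1, large N: the 30-generation mean
  ## frequency path stays within 0.02 (sup norm) of the recursion
  ## m' = m e^{2fi} / (m e^{2fi} + 1 - m), averaged over 60 replicates
  fl <- fitness_landscape(2, fi = c(0.1, 0))
  cfg <- sim_config(N = 10000, L = 2, T = 30, r = 0, mu = 0, seed = 33,
                    init_mode = "given_frequencies",
                    init_frequencies = c(0.1, 0.5))
  paths <- sapply(1:60, function(k) {
    tr <- run_replicate(fl, cfg, k)
    vapply(tr$records, function(rec)
      sum(rec$count[rec$geno[, 1] == 1]) / sum(rec$count), numeric(1))
  })
  oracle <- Reduce(function(m, .) recursion_step(m, 0.1, 0), 1:30,
                   accumulate = TRUE, init = 0.1)
  expect_lt(max(abs(rowMeans(paths) - oracle)), 0.02)
})

test_that("selection response: mean fitness increases over a run", {
  fl <- sample_landscape(25, 0.05, 0, seed = 21)
  cfg <- sim_config(N = 1000, L = 25, T = 30, r = 0.5, mu = 0.01,
                    n_replicates = 30, seed = 55)
  trs <- run_replicates(fl, cfg)
  gains <- vapply(trs, function(tr) {
    first <- tr$records[[1L]]; last <- tr$records[[length(tr$records)]]
    f1 <- stats::weighted.mean(fitness_of(first$geno, fl)$total, first$count)
    f2 <- stats::weighted.mean(fitness_of(last$geno, fl)$total, last$count)
    f2 > f1
  }, logical(1))
  expect_gte(sum(gains), 28)
})

test_that("trajectory table and FASTA round trips preserve the data", {
  fl <- sample_landscape(6, 0.05, 0.01, seed = 2)
  cfg <- sim_config(N = 40, L = 6, T = 4, r = 0.5, mu = 0.05, seed = 12,
                    n_replicates = 2)
  trs <- run_replicates(fl, cfg)
  tdir <- withr::local_tempdir()

  tab <- file.path(tdir, "traj.tsv")
  write_trajectory_table(trs, tab, alphabet = "01")
  back <- read_trajectory_table(tab, config = cfg)
  expect_length(back, 2L)
  for (k in 1:2) {
    expect_equal(generations(back[[k]]), generations(trs[[k]]))
    for (g in seq_along(trs[[k]]$records)) {
      expect_identical(back[[k]]$records[[g]]$geno,
                       trs[[k]]$records[[g]]$geno)
      expect_equal(back[[k]]$records[[g]]$count, trs[[k]]$records[[g]]$count)
    }
  }

  fa <- file.path(tdir, "traj.fasta")
  write_trajectory_fasta(trs, fa)
  expect_true(file.exists(paste0(fa, ".meta.json")))
  backf <- read_trajectory_fasta(fa)
  for (k in 1:2) {
    m1 <- moments(trs[[k]], 4, lambda = 0)
    m2 <- moments(backf[[k]], 4, lambda = 0)
    expect_equal(m2$m_i, m1$m_i)
    expect_equal(m2$chi_ij, m1$chi_ij)
  }
  ## round-tripped config is usable
  expect_equal(backf[[1]]$config$N, 40)
})
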