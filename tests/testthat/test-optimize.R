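sphere <- function(g) { x <- -100 + 200 * g; -sum(x^2) }

test_that("control-parameter sampling respects ranges and the seed", {
  mem <- history_memory(6)
  set.seed(1)
  draws <- replicate(10000, unlist(sample_parameters(mem)))
  expect_true(all(draws["SF", ] > 0 & draws["SF", ] <= 1))
  expect_true(all(draws["CR", ] >= 0 & draws["CR", ] <= 1))

  mem0 <- history_memory(1)
  mem0$m_cr[1] <- 0
  set.seed(2)
  cr0 <- replicate(10000, sample_parameters(mem0)$CR)
  expect_lt(stats::median(cr0), 0.05)   # clipped normal around 0

  set.seed(7)
  a <- replicate(50, unlist(sample_parameters(mem)))
  set.seed(7)
  b <- replicate(50, unlist(sample_parameters(mem)))
  expect_identical(a, b)
})

test_that("weighted Lehmer mean matches hand arithmetic and stays bracketed", {
  expect_equal(weighted_lehmer_mean(c(0.3, 0.3, 0.3), c(1, 5, 2)), 0.3)
  expect_equal(weighted_lehmer_mean(0.77, 123), 0.77)
  expect_equal(weighted_lehmer_mean(c(0.2, 0.8), c(1, 3)), 0.49 / 0.65,
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:50) {
    s <- runif(5)
    d <- runif(5, 0.1, 2)
    m <- weighted_lehmer_mean(s, d)
    expect_gte(m, min(s) - 1e-12)
    expect_lte(m, max(s) + 1e-12)
  }
  expect_error(weighted_lehmer_mean(numeric(0), numeric(0)), "empty")
})

test_that("memory update blends with c and advances the write index cyclically", {
  mem <- history_memory(2)
  up <- update_memory(mem, s_sf = 0.9, s_cr = 0.9, delta_f = 1, c = 0.5)
  expect_equal(up$m_sf[1], 0.7)   # 0.5 * 0.5 + 0.5 * 0.9
  expect_equal(up$write_index, 2L)
  up2 <- update_memory(up, 0.9, 0.9, 1, c = 0.5)
  expect_equal(up2$write_index, 1L)

  same <- update_memory(mem, numeric(0), numeric(0), numeric(0))
  expect_identical(same, mem)     # empty generation: no change, no advance

  frozen <- update_memory(mem, 0.9, 0.9, 1, c = 1)
  expect_equal(frozen$m_sf, mem$m_sf)
  expect_error(update_memory(mem, 0.9, 0.9, 1, c = 0), "\\(0, 1\\]")
})

test_that("linear population size reduction follows the schedule exactly", {
  cfg <- lshade_config(np_init = 100, np_min = 4, nf_max = 10000)
  expect_equal(lpsr_size(cfg, 0), 100L)
  expect_equal(lpsr_size(cfg, 10000), 4L)
  expect_equal(lpsr_size(cfg, 5000), 52L)
  nps <- vapply(seq(0, 10000, by = 100), lpsr_size, integer(1), cfg = cfg)
  expect_true(all(diff(nps) <= 0))
  expect_error(lpsr_size(cfg, 10001), "nf_max")
})

test_that("trial generation: degenerate settings and bound repair", {
  set.seed(9)
  pop <- matrix(runif(40), nrow = 8, ncol = 5)
  arch <- matrix(numeric(0), 0, 5)
  # SF = 0 collapses the mutant onto the parent regardless of CR
  u0 <- propose_trial(pop, 3, SF = 0, CR = 1, pbest_idx = 1:2, archive = arch)
  expect_equal(u0, pop[3, ])
  u00 <- propose_trial(pop, 3, SF = 0, CR = 0, pbest_idx = 1:2, archive = arch)
  expect_equal(u00, pop[3, ])

  # identical population: every difference vanishes
  pop_same <- matrix(rep(pop[1, ], each = 8), nrow = 8)
  us <- propose_trial(pop_same, 2, SF = 0.8, CR = 0.5, pbest_idx = 1:2,
                      archive = arch)
  expect_equal(us, pop[1, ])

  expect_error(propose_trial(pop[1:3, ], 1, 0.5, 0.5, 1:2, arch),
               "at least 4")
  expect_error(propose_trial(pop, 1, 0.5, 0.5, integer(0), arch),
               "pbest")

  # midpoint repair keeps repaired coordinates strictly inside the unit box
  set.seed(10)
  for (i in 1:1000) {
    p <- matrix(runif(20, 0.05, 0.95), nrow = 4, ncol = 5)
    u <- propose_trial(p, 1, SF = 1, CR = 1, pbest_idx = 1:2, archive = arch)
    expect_true(all(u > 0 & u < 1))
  }
})

test_that("engine trace obeys the reduction schedule with in-range memory", {
  cfg <- lshade_config(np_init = 30, np_min = 4, nf_max = 1500, seed = 3)
  res <- optimize_lshade(sphere, 6, cfg)
  tr <- res$trace
  expect_lte(res$nf, 1500)
  # initial snapshot holds the full population; afterwards the size equals
  # the linear schedule exactly at every generation boundary
  expect_equal(tr$NP[1], cfg$np_init)
  for (r in seq_len(nrow(tr))[-1])
    expect_equal(tr$NP[r], lpsr_size(cfg, tr$nf[r]))
  expect_true(all(diff(tr$NP) <= 0))
  # best-so-far is monotone non-decreasing
  expect_true(all(diff(tr$best_fitness) >= 0))
  # memory snapshots stay in valid ranges throughout
  msf <- as.numeric(unlist(strsplit(tr$m_sf, ";")))
  mcr <- as.numeric(unlist(strsplit(tr$m_cr, ";")))
  expect_true(all(msf > 0 & msf <= 1))
  expect_true(all(mcr >= 0 & mcr <= 1))
})

test_that("population shrink removes exactly the worst members", {
  # engine invariant checked via trace: rerun with an objective whose value
  # identifies the individual (fitness = first coordinate)
  cfg <- lshade_config(np_init = 20, np_min = 4, nf_max = 200, seed = 5)
  res <- optimize_lshade(function(g) g[1], 3, cfg)
  expect_true(all(diff(res$trace$best_fitness) >= 0))
  expect_equal(res$trace$NP[nrow(res$trace)],
               lpsr_size(cfg, res$trace$nf[nrow(res$trace)]))
})

test_that("budget boundary: nf_max equal to the initial population", {
  cfg <- lshade_config(np_init = 10, np_min = 4, nf_max = 10, seed = 1)
  res <- optimize_lshade(sphere, 4, cfg)
  expect_equal(res$nf, 10L)
  expect_equal(nrow(res$trace), 1L)   # initial generation only
})

test_that("same seed gives identical traces; non-finite objectives are worst", {
  cfg <- lshade_config(np_init = 15, np_min = 4, nf_max = 300, seed = 11)
  r1 <- optimize_lshade(sphere, 5, cfg)
  r2 <- optimize_lshade(sphere, 5, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_genome, r2$best_genome)

  bad <- function(g) if (g[1] > 0.5) NaN else -sum(g^2)
  expect_warning(
    rb <- optimize_lshade(bad, 3,
                          lshade_config(np_init = 10, np_min = 4,
                                        nf_max = 50, seed = 2)),
    "non-finite")
  expect_true(is.finite(rb$best_fitness))
})

test_that("fixed-size engine equals the independent reference DE step for step", {
  # nf_max so large that the linear schedule keeps NP constant over the
  # checked generations; H = 1 keeps a single shared memory cell
  cfg <- lshade_config(np_init = 10, np_min = 4, memory_size = 1,
                       nf_max = 1e7, max_gen = 5, seed = 42)
  ref <- reference_de(sphere, 4, cfg, n_gen = 5)
  res <- optimize_lshade(sphere, 4, cfg)
  expect_equal(res$best_fitness, max(ref$fit), tolerance = 1e-12)
  expect_equal(res$best_genome, ref$pop[which.max(ref$fit), ],
               tolerance = 1e-12)
  expect_equal(res$nf, 10L + 5L * 10L)
})

test_that("decode maps genomes to typed hyperparameters", {
  sp <- default_search_space()
  lo <- decode(rep(0, 5), sp)
  hi <- decode(rep(1, 5), sp)
  expect_equal(lo$n_estimators, 10L)
  expect_equal(hi$n_estimators, 100L)
  expect_equal(lo$criterion, "gini")
  expect_equal(hi$criterion, "entropy")
  expect_equal(decode(c(0.5, 0.49, 0.5, 0.5, 0.5), sp)$criterion, "gini")
  expect_equal(decode(c(0.5, 0.51, 0.5, 0.5, 0.5), sp)$criterion, "entropy")
  expect_equal(lo$max_depth, 1L)
  expect_equal(hi$max_depth, 25L)
  expect_error(decode(rep(0.5, 3), sp), "length")
  # idempotent: decoding the same genome twice gives identical results
  g <- runif(5)
  expect_identical(decode(g, sp), decode(g, sp))
})

test_that("random search respects the budget and improves monotonically", {
  cfg <- lshade_config(np_init = 20, np_min = 4, nf_max = 100, seed = 8)
  res <- random_search(sphere, 5, cfg)
  expect_equal(res$nf, 100L)
  expect_true(all(diff(res$trace$best_fitness) >= 0))
})

test_that("tuning respects fixed dimensions and the evaluation budget", {
  m <- tiny_features()
  sp <- temporal_split(m, 0.7)
  space <- search_space(list(
    dim_int("n_estimators", 25, 25),
    dim_int("max_depth", 2, 10)
  ))
  cfg <- lshade_config(np_init = 6, np_min = 4, nf_max = 18, seed = 1)
  tn <- tune(sp$train, "et", space = space, cfg = cfg)
  expect_equal(tn$best_hp$n_estimators, 25L)
  expect_lte(nrow(tn$history), 18L)
  expect_gte(tn$best_fitness, 0)
  expect_lte(tn$best_fitness, 1)
})

test_that("degenerate cross-validation folds are rejected", {
  m <- tiny_features()
  few <- fm_rows(m, c(which(m$gesture == "g1")[1:2], which(m$gesture == "g2")))
  expect_error(tune(few, "et", folds = 3,
                    cfg = lshade_config(np_init = 6, np_min = 4, nf_max = 12)),
               "degenerate")
})
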