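test_that("mutate_cell is the zero-rate identity and conserves copy number", {
  cell <- cell_state(c(0L, 1L), c(0L, 2L), c(3L, 7L))
  expect_identical(mutate_cell(cell, l = 1000, mu_b = 0, mu_d = 0), cell)
  set.seed(1)
  out <- mutate_cell(cell, l = 100, mu_b = 0.01, mu_d = 0.02)
  expect_identical(sum(out$count), 10L)
  expect_true(min(out$alpha) >= 0 && min(out$kappa) >= 0)
  expect_error(mutate_cell(cell, l = 10, mu_b = 0.6, mu_d = 0.6),
               "mu_b \\+ mu_d")
})

test_that("mutation counts follow the per-genome binomial law", {
  # one cell with many copies, high rate so one draw is informative
  set.seed(42)
  cell <- cell_state(0L, 0L, 20000L)
  l <- 50; mu <- 0.01   # per-genome mean l*mu = 0.5
  out <- mutate_cell(cell, l, mu, 0)
  m <- sum(out$alpha * out$count) / sum(out$count)
  se <- sqrt(l * mu * (1 - mu) / 20000)
  expect_lt(abs(m - l * mu), 5 * se)
  # fraction of copies left unmutated matches (1 - mu)^l
  p0 <- sum(out$count[out$alpha == 0]) / sum(out$count)
  expect_lt(abs(p0 - (1 - mu)^l), 5 * sqrt((1 - mu)^l / 20000))
})

test_that("select_hosts resamples proportionally to fitness", {
  spec <- fitness_spec(s_b = 0.1, s_d = 0.9, beneficial_shape = "linear",
                       deleterious_shape = "linear", n_ref = 2,
                       gamma_ref = 50)  # X = 100
  # fitness 0.9 (no load) vs 0.45 (y = X/2): expected 2:1 after selection
  a <- cell_state(0L, 0L, 2L)
  bcell <- cell_state(0L, 25L, 2L)
  pop <- cyto_population(c(replicate(5000, a, simplify = FALSE),
                           replicate(5000, bcell, simplify = FALSE)))
  set.seed(7)
  out <- select_hosts(pop, spec)
  frac_a <- mean(vapply(out$cells, function(cell) all(cell$kappa == 0),
                        logical(1)))
  expect_lt(abs(frac_a - 2 / 3), 5 * sqrt(2 / 9 / 10000))
  # symmetric population passes through unchanged
  same <- cyto_population(replicate(20, a, simplify = FALSE))
  expect_identical(select_hosts(same, spec)$cells, same$cells)
  # extinction is an error that reports the generation
  # with s_b + s_d > 1 a fully loaded cell floors at zero fitness
  dead <- cyto_population(replicate(3, cell_state(0L, 100L, 2L),
                                    simplify = FALSE), generation = 17L)
  dead_spec <- fitness_spec(s_b = 0.6, s_d = 0.6,
                            deleterious_shape = "linear",
                            n_ref = 2, gamma_ref = 1)
  expect_error(select_hosts(dead, dead_spec), "17")
})

test_that("gametogenesis samples b copies with replacement from the parent", {
  hom <- cell_state(3L, 1L, 10L)
  g <- gametogenesis(hom, b = 5)
  expect_identical(g$A, cell_state(3L, 1L, 5L))
  expect_identical(g$a, cell_state(3L, 1L, 5L))
  # parent with 1 mutant copy of 2, b = 2: P(gamete all wild type) = 1/4
  parent <- cell_state(c(0L, 1L), c(0L, 0L), c(1L, 1L))
  set.seed(11)
  wt <- replicate(8000, {
    g <- gametogenesis(parent, b = 1)  # b = 1 here: P(wild type) = 1/2
    all(g$A$alpha == 0)
  })
  expect_lt(abs(mean(wt) - 0.5), 5 * sqrt(0.25 / 8000))
  set.seed(12)
  wt2 <- replicate(8000, {
    p2 <- cell_state(c(0L, 1L), c(0L, 0L), c(2L, 2L))
    g <- gametogenesis(p2, b = 2)
    all(g$A$alpha == 0)
  })
  expect_lt(abs(mean(wt2) - 0.25), 5 * sqrt(0.25 * 0.75 / 8000))
  # mutant copy count in the gamete is Binomial(b, fraction mutant)
  p3 <- cell_state(c(0L, 1L), c(0L, 0L), c(40L, 10L))
  set.seed(13)
  cnt <- replicate(3000, {
    g <- gametogenesis(p3, b = 5)
    sum(g$A$count[g$A$alpha == 1])
  })
  expect_lt(abs(mean(cnt) - 1), 5 * sqrt(5 * 0.2 * 0.8 / 3000))
})

test_that("mating and repopulation respect the inheritance mode", {
  gA <- replicate(6, cell_state(2L, 0L, 3L), simplify = FALSE)
  ga <- replicate(6, cell_state(0L, 5L, 3L), simplify = FALSE)
  set.seed(3)
  upi <- mate_and_repopulate(gA, ga, "uniparental", n = 8)
  expect_true(all(vapply(upi$cells, function(cell)
    identical(cell, cell_state(2L, 0L, 8L)), logical(1))))
  # biparental with both gametes homoplasmic for the same class
  both <- mate_and_repopulate(gA, gA, "biparental", n = 8)
  expect_true(all(vapply(both$cells, function(cell)
    identical(cell, cell_state(2L, 0L, 8L)), logical(1))))
  # biparental X/Y fusion: offspring X-count ~ Binomial(n, 1/2)
  set.seed(4)
  xc <- replicate(3000, {
    off <- mate_and_repopulate(gA[1], ga[1], "biparental", n = 8)
    sum(off$cells[[1]]$count[off$cells[[1]]$alpha == 2])
  })
  expect_lt(abs(mean(xc) - 4), 5 * sqrt(8 * 0.25 / 3000))
  expect_lt(abs(var(xc) - 2), 0.35)
  expect_error(mate_and_repopulate(gA, ga[1:3], "biparental", n = 8),
               "consistency")
})

test_that("advance_generation preserves population and copy-number invariants", {
  cfg <- small_config(seed = NULL)
  set.seed(5)
  pop <- founder_population(20, 10)
  cfg$N <- 20L
  for (i in 1:3) {
    pop <- advance_generation(pop, cfg)
    expect_length(pop$cells, 20)
    expect_true(all(vapply(pop$cells, function(cell) sum(cell$count),
                           integer(1)) == 10L))
  }
  expect_identical(pop$generation, 3L)
})

test_that("one engine generation matches the exhaustive enumeration oracle", {
  for (inh in c("uniparental", "biparental")) {
    inst <- tiny_instance(inh)
    expected <- enumerate_generation(inst$cells, mu = 0.2, s_b = 0.5,
                                     X = 2, inh == "uniparental")
    keys <- character(10000)
    for (s in seq_along(keys)) {
      cfg <- inst$config
      cfg$seed <- s
      tr <- run_simulation(cfg, initial_state = inst$initial_state)
      keys[s] <- final_state_key(tr$final_state)
    }
    p <- chisq_against(keys, expected)
    expect_gt(p, 1e-4)
  }
})

test_that("the reference R engine matches the same enumeration oracle", {
  inst <- tiny_instance("biparental")
  expected <- enumerate_generation(inst$cells, mu = 0.2, s_b = 0.5,
                                   X = 2, uniparental = FALSE)
  keys <- character(1000)
  for (s in seq_along(keys)) {
    cfg <- inst$config
    cfg$seed <- s
    tr <- run_simulation(cfg, engine = "reference",
                         initial_state = inst$initial_state)
    keys[s] <- final_state_key(tr$final_state)
  }
  expect_gt(chisq_against(keys, expected), 1e-4)
})

test_that("neutral runs obey the molecular clock and the drift martingale", {
  # s_b = s_d = 0: E[mean alpha at T] = T * l * mu_b, likewise for kappa
  cfg <- sim_config(N = 50, n = 10, b = 5, l = 1000, mu_b = 2e-5,
                    mu_d = 4e-5,
                    fitness = linear_spec(s_b = 0, s_d = 0, n_ref = 10),
                    stop_rule = "fixed_generations", max_generations = 50)
  finals <- t(sapply(derive_seeds(99, 60), function(s) {
    cfg$seed <- s
    last <- tail(run_simulation(cfg)$summary, 1)
    c(a = last$mean_alpha, k = last$mean_kappa)
  }))
  for (col in 1:2) {
    target <- 50 * 1000 * c(2e-5, 4e-5)[col]
    tt <- t.test(finals[, col], mu = target)
    expect_gt(tt$p.value, 1e-3)
  }
  # minimum loads never decrease along a run
  cfg$seed <- 123
  s <- run_simulation(cfg)$summary
  expect_true(all(diff(s$min_alpha) >= 0))
  expect_true(all(diff(s$min_kappa) >= 0))
})

test_that("runs are deterministic in the seed and flag unreachable targets", {
  cfg <- small_config(seed = 77)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$summary, t2$summary)
  expect_identical(t1$class_freq, t2$class_freq)
  expect_identical(t1$final_state, t2$final_state)
  # mu_b = 0 under the gamma stop rule can never finish: truncated, no error
  cfg0 <- sim_config(N = 20, n = 4, b = 2, l = 100, mu_b = 0, mu_d = 0,
                     fitness = linear_spec(n_ref = 4),
                     stop_rule = "all_genomes_reach_gamma", gamma = 1,
                     max_generations = 30, seed = 1)
  tr <- run_simulation(cfg0)
  expect_true(tr$stop$truncated)
  expect_identical(tr$stop$generation, 30L)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n = 50, b = 26), "b <= n/2")
  expect_error(sim_config(mu_b = 0.7, mu_d = 0.7), "mu_b \\+ mu_d")
  # the single-genome emulation case is allowed
  expect_s3_class(sim_config(n = 1, b = 1, fitness = linear_spec(n_ref = 1)),
                  "sim_config")
})
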