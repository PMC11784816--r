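test_that("register initialization is the uniform superposition", {
  reg <- qubit_register(5, 4)
  expect_equal(dim(reg$alpha), c(5, 4))
  expect_true(all(abs(reg$alpha - 1 / sqrt(2)) < 1e-15))
  expect_true(all(abs(reg$beta - 1 / sqrt(2)) < 1e-15))
  expect_lt(qgafs:::register_norm_error(reg), 1e-12)
  expect_error(qubit_register(5, 0), "positive")
  expect_error(qubit_register(0, 4), "positive")
})

test_that("observation collapses each gene with probability beta^2", {
  # deterministic extremes
  reg0 <- register_with_p1(rep(0, 50))
  reg1 <- register_with_p1(rep(1, 50))
  set.seed(1)
  expect_true(all(observe_register(reg0) == 0L))
  expect_true(all(observe_register(reg1) == 1L))
  # uniform superposition: binomial oracle, p = 0.5, 3-sigma band on 10,000
  set.seed(42)
  bits <- observe_register(qubit_register(10000, 1))
  expect_gte(mean(bits), 0.48)
  expect_lte(mean(bits), 0.52)
})

test_that("rotation gate matches closed-form trigonometry and preserves norm", {
  expect_equal(rotate_gene(c(1, 0), 0), c(1, 0))
  expect_equal(rotate_gene(c(1, 0), pi / 2), c(0, 1), tolerance = 1e-12)
  expect_equal(rotate_gene(c(1, 1) / sqrt(2), pi / 4), c(0, 1),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:1000) {
    ang <- runif(1, 0, 2 * pi)
    pair <- c(cos(ang), sin(ang))
    out <- rotate_gene(pair, runif(1, -pi, pi))
    expect_lt(abs(sum(out^2) - 1), 1e-12)
  }
  expect_error(rotate_gene(c(1, 1), 0.1), "not normalized")
})

test_that("register update rotates disagreeing genes towards the best bits", {
  cfg <- qga_config(population_size = 2, rotation_angle = 0.05 * pi)
  reg <- qubit_register(2, 3)
  best <- c(1L, 0L, 1L)
  bits <- rbind(best, best)         # full agreement: no change anywhere
  out <- update_register(reg, bits, c(0, 0), best, 1, cfg)
  expect_identical(out$alpha, reg$alpha)
  expect_identical(out$beta, reg$beta)

  bits <- rbind(c(0L, 1L, 1L), best)  # slot 1 disagrees on genes 1 and 2
  out <- update_register(reg, bits, c(0, 0), best, 1, cfg)
  expect_gt(out$beta[1, 1]^2, 0.5)    # towards bit 1
  expect_lt(out$beta[1, 2]^2, 0.5)    # towards bit 0
  expect_equal(out$beta[1, 3]^2, 0.5) # agreed, untouched
  expect_lt(qgafs:::register_norm_error(out), 1e-12)

  # an individual strictly fitter than the stored best is not rotated
  out <- update_register(reg, bits, c(2, 0), best, 1, cfg)
  expect_equal(out$beta[1, 1]^2, 0.5)

  expect_error(update_register(reg, bits[, 1:2], c(0, 0), best[1:2], 1, cfg),
               "does not match")
})

test_that("repeated updates drive beta^2 monotonically to the saturation bound", {
  cfg <- qga_config(population_size = 2, rotation_angle = 0.05 * pi,
                    beta_floor = 1e-4)
  reg <- qubit_register(1, 1)
  best <- 1L
  p_prev <- reg$beta[1, 1]^2
  for (i in 1:60) {
    reg <- update_register(reg, matrix(0L, 1, 1), 0, best, 1, cfg)
    p <- reg$beta[1, 1]^2
    expect_gte(p + 1e-12, p_prev)
    p_prev <- p
  }
  expect_equal(p_prev, 1 - 1e-4, tolerance = 1e-10)
})

test_that("amplitude-swap mutation preserves norms and the stated rate", {
  reg <- register_with_p1(seq(0.05, 0.95, length.out = 10))
  expect_identical(mutate_register(reg, 0), reg)
  flipped <- mutate_register(reg, 1)
  expect_equal(flipped$alpha, reg$beta)
  expect_equal(flipped$beta, reg$alpha)
  # binomial(1000, 0.01) oracle: 3-sigma band roughly [1, 25]
  big <- qubit_register(1, 1000)
  big$alpha <- matrix(1, 1, 1000); big$beta <- matrix(0, 1, 1000)
  set.seed(11)
  mut <- mutate_register(big, 0.01)
  n_swapped <- sum(mut$beta[1, ] == 1)
  expect_gte(n_swapped, 1)
  expect_lte(n_swapped, 25)
  expect_error(mutate_register(reg, 1.5), "probability")
})

test_that("the run finds exhaustive-search optima on OneMax and linear", {
  onemax <- function(b) sum(b)
  run <- qga(onemax, 8, qga_config(population_size = 20,
                                   max_generations = 50, seed = 3))
  expect_identical(run$best_bits, rep(1L, 8))
  expect_equal(run$best_fitness, exhaustive_optimum(onemax, 8))

  lin <- qgafs:::benchmark_fitness("linear", 9, seed = 2)
  run_l <- qga(lin, 9, qga_config(population_size = 20,
                                  max_generations = 50, seed = 5))
  expect_equal(run_l$best_fitness, exhaustive_optimum(lin, 9))
})

test_that("benchmark fitness functions implement their definitions", {
  trap <- qgafs:::benchmark_fitness("trap", 8)
  expect_equal(trap(rep(1L, 8)), 8)       # global optimum
  expect_equal(trap(rep(0L, 8)), 6)       # deceptive local optimum
  expect_equal(trap(c(rep(1L, 4), rep(0L, 4))), 7)
  expect_error(qgafs:::benchmark_fitness("trap", 6), "divisible")
  expect_error(qgafs:::benchmark_fitness("nope", 8), "unknown benchmark")
})

test_that("constant fitness is optimal at generation 0 and never changes", {
  run <- qga(function(b) 3.5, 6, qga_config(seed = 1, max_generations = 10))
  expect_true(all(run$history$best == 3.5))
  expect_equal(run$generation_born, 0L)
})

test_that("runs are deterministic and elitist, with normalized registers", {
  f <- function(b) sum(b * seq_along(b))
  r1 <- qga(f, 10, qga_config(seed = 9))
  r2 <- qga(f, 10, qga_config(seed = 9))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_bits, r2$best_bits)
  expect_true(all(diff(r1$history$best) >= 0))
  expect_lte(r1$max_norm_error, 1e-9)
})

test_that("non-finite fitness aborts naming the offending bitstring", {
  f <- function(b) if (b[1] == 1) NaN else sum(b)
  expect_error(qga(f, 4, qga_config(seed = 2)), "bitstring 1")
})

test_that("stall patience terminates the run early", {
  run <- qga(function(b) 1, 6,
             qga_config(max_generations = 50, stall_patience = 3, seed = 1))
  expect_equal(run$generations, 3L)
})

test_that("configuration invariants are enforced", {
  expect_error(qga_config(population_size = 1), "population_size")
  expect_error(qga_config(mutation_rate = 1.2), "mutation_rate")
  expect_error(qga_config(rotation_angle = 0), "rotation_angle")
  expect_error(qga_config(rotation_angle = pi), "rotation_angle")
  expect_error(qga_config(max_generations = 0), "max_generations")
})

test_that("run records serialize config, history and best bitstring", {
  run <- qga(function(b) sum(b), 5, qga_config(seed = 4, max_generations = 5))
  path <- withr::local_tempfile(fileext = ".json")
  run_record(run, path)
  rec <- jsonlite::fromJSON(path)
  expect_equal(rec$best_bits, run$best_bits)
  expect_equal(rec$config$seed, 4)
  expect_equal(nrow(rec$history), nrow(run$history))
})
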