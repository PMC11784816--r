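#' Quantum genetic algorithm configuration
#'
#' Collects and validates the hyperparameters of the quantum-inspired genetic
#' algorithm. A QGA maintains, for every population slot, a register of qubits
#' (amplitude pairs); bitstrings are sampled ("observed") from the registers,
#' evaluated, and the registers are rotated towards the best individual found
#' so far.
#'
#' @param population_size Number of qubit registers / observed individuals per
#'   generation. At least 2.
#' @param max_generations Hard cap on the number of update generations
#'   (`t_max`).
#' @param mutation_rate Per-gene probability of an amplitude-swap mutation
#'   (quantum NOT), in `[0, 1]`. Default 0.01 (1\%).
#' @param rotation_angle Magnitude of the rotation-gate angle, in radians, in
#'   `(0, pi/2]`. Default `0.05 * pi`.
#' @param stall_patience Number of consecutive generations without improvement
#'   of the best fitness after which the run stops early. Defaults to
#'   `max_generations`, i.e. disabled.
#' @param beta_floor Saturation guard: the probability of either bit value is
#'   kept within `[beta_floor, 1 - beta_floor]` so no gene collapses
#'   irreversibly. Default `1e-4`.
#' @param seed Optional integer seed; when non-`NULL`, [qga()] seeds the RNG
#'   before sampling, making the run fully reproducible.
#'
#' @return A list of class `"qga_config"`.
#' @seealso [qga()]
#' @export
qga_config <- function(population_size = 20, max_generations = 50,
                       mutation_rate = 0.01, rotation_angle = 0.05 * pi,
                       stall_patience = max_generations, beta_floor = 1e-4,
                       seed = NULL) {
  stopifnot(is.numeric(population_size), length(population_size) == 1,
            is.numeric(max_generations), length(max_generations) == 1)
  if (population_size < 2) stop("`population_size` must be >= 2")
  if (max_generations < 1) stop("`max_generations` must be >= 1")
  if (!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate > 1)
    stop("`mutation_rate` must be a probability in [0, 1]")
  if (!is.numeric(rotation_angle) || rotation_angle <= 0 ||
      rotation_angle > pi / 2)
    stop("`rotation_angle` must be in (0, pi/2]")
  if (stall_patience < 1) stop("`stall_patience` must be >= 1")
  if (beta_floor <= 0 || beta_floor >= 0.5)
    stop("`beta_floor` must be in (0, 0.5)")
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 mutation_rate = mutation_rate,
                 rotation_angle = rotation_angle,
                 stall_patience = as.integer(stall_patience),
                 beta_floor = beta_floor,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "qga_config")
}

#' Initialize a qubit register matrix
#'
#' Creates `n_slots` registers of `m` qubits each, all in the uniform
#' superposition `alpha = beta = 1/sqrt(2)`: every bit of every observed
#' individual is initially equally likely to be 0 or 1, so the register
#' implicitly represents all `2^m` bitstrings at once.
#'
#' @param n_slots Number of population slots (one register per slot).
#' @param m Number of genes (qubits) per register; must be >= 1.
#' @return An object of class `"qubit_register"`: a list with `n_slots x m`
#'   matrices `alpha` and `beta`. The normalization `alpha^2 + beta^2 = 1`
#'   holds gene-wise throughout the register's lifetime.
#' @export
qubit_register <- function(n_slots, m) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 1)
    stop("gene count `m` must be a positive integer")
  if (!is.numeric(n_slots) || length(n_slots) != 1 || n_slots < 1)
    stop("`n_slots` must be a positive integer")
  n_slots <- as.integer(n_slots); m <- as.integer(m)
  a <- matrix(1 / sqrt(2), n_slots, m)
  structure(list(alpha = a, beta = a, n_slots = n_slots, m = m),
            class = "qubit_register")
}

# Largest gene-wise deviation from the normalization alpha^2 + beta^2 = 1.
register_norm_error <- function(reg) {
  max(abs(reg$alpha^2 + reg$beta^2 - 1))
}

#' Observe (collapse) a qubit register into bitstrings
#'
#' Samples one bitstring per register slot: gene `i` collapses to 1 with
#' probability `beta_i^2`, to 0 otherwise, independently across genes and
#' slots. Consumes the R random number stream, so results are deterministic
#' under a fixed seed.
#'
#' @param reg A [qubit_register()].
#' @return An integer `n_slots x m` matrix of 0/1 bits.
#' @export
observe_register <- function(reg) {
  stopifnot(inherits(reg, "qubit_register"))
  p1 <- reg$beta^2
  bits <- matrix(as.integer(stats::runif(length(p1)) < p1),
                 reg$n_slots, reg$m)
  bits
}

#' Rotate one qubit amplitude pair
#'
#' Applies the 2x2 rotation gate to an amplitude pair:
#' `alpha' = cos(dtheta) * alpha - sin(dtheta) * beta`,
#' `beta'  = sin(dtheta) * alpha + cos(dtheta) * beta`.
#' The gate is orthogonal, so the normalization is preserved for any angle.
#'
#' @param pair Numeric vector `c(alpha, beta)` with `alpha^2 + beta^2 = 1`
#'   (within `1e-6`).
#' @param dtheta Rotation angle in radians (signed).
#' @return The rotated `c(alpha, beta)`.
#' @export
rotate_gene <- function(pair, dtheta) {
  stopifnot(is.numeric(pair), length(pair) == 2, is.numeric(dtheta))
  if (abs(sum(pair^2) - 1) > 1e-6)
    stop("amplitude pair is not normalized: alpha^2 + beta^2 != 1")
  c(cos(dtheta) * pair[1] - sin(dtheta) * pair[2],
    sin(dtheta) * pair[1] + cos(dtheta) * pair[2])
}

#' Rotate registers towards the best individual
#'
#' The update step of the QGA: for every population slot whose observed
#' fitness does not exceed the stored best fitness, every gene whose observed
#' bit disagrees with the best individual's bit is rotated by
#' `rotation_angle`, signed so that the probability of the best individual's
#' bit value increases. Genes that agree are left untouched. A saturation
#' guard clamps the rotation so the bit-1 probability stays within
#' `[beta_floor, 1 - beta_floor]`: genes approach the target bit
#' monotonically and stop at the bound, never collapsing irreversibly.
#'
#' @param reg A [qubit_register()].
#' @param bits Observed bit matrix for the current population
#'   (`n_slots x m`).
#' @param fitness Numeric vector of the individuals' fitness values
#'   (length `n_slots`).
#' @param best_bits Bit vector of the stored best individual (length `m`).
#' @param best_fitness Fitness of the stored best individual.
#' @param config A [qga_config()] (supplies `rotation_angle`, `beta_floor`).
#' @return The updated register; normalization holds gene-wise.
#' @export
update_register <- function(reg, bits, fitness, best_bits, best_fitness,
                            config = qga_config()) {
  stopifnot(inherits(reg, "qubit_register"))
  if (length(best_bits) != reg$m || ncol(bits) != reg$m)
    stop("bit-vector length does not match register gene count")
  if (nrow(bits) != reg$n_slots || length(fitness) != reg$n_slots)
    stop("population size does not match register slot count")

  best <- matrix(best_bits, reg$n_slots, reg$m, byrow = TRUE)
  eligible <- fitness <= best_fitness           # never rotate away from a new best
  disagree <- (bits != best) & eligible
  # sign: +angle moves probability mass towards bit 1 (both amplitudes start
  # positive and the saturation guard keeps them in the first quadrant)
  theta <- matrix(0, reg$n_slots, reg$m)
  theta[disagree & best == 1] <- config$rotation_angle
  theta[disagree & best == 0] <- -config$rotation_angle

  # amplitudes stay in the first quadrant (nonnegative) for the whole run, so
  # the rotation can be applied in angle space, clamped at the saturation
  # bounds: genes rotate monotonically towards the target bit and stop there.
  idx <- which(theta != 0)
  if (length(idx)) {
    eps <- config$beta_floor
    phi <- atan2(reg$beta[idx], reg$alpha[idx]) + theta[idx]
    phi <- pmin(pmax(phi, asin(sqrt(eps))), acos(sqrt(eps)))
    reg$alpha[idx] <- cos(phi)
    reg$beta[idx] <- sin(phi)
  }
  reg
}

#' Amplitude-swap mutation
#'
#' With probability `rate` per gene (independently), swaps the amplitude pair
#' `(alpha, beta) -> (beta, alpha)` — the quantum analogue of a NOT gate,
#' inverting the bit probabilities. Normalization is preserved by
#' construction.
#'
#' @param reg A [qubit_register()].
#' @param rate Mutation probability in `[0, 1]`.
#' @return The mutated register.
#' @export
mutate_register <- function(reg, rate) {
  stopifnot(inherits(reg, "qubit_register"))
  if (!is.numeric(rate) || rate < 0 || rate > 1)
    stop("`rate` must be a probability in [0, 1]")
  if (rate == 0) return(reg)
  swap <- matrix(stats::runif(reg$n_slots * reg$m) < rate,
                 reg$n_slots, reg$m)
  a <- reg$alpha; b <- reg$beta
  reg$alpha[swap] <- b[swap]
  reg$beta[swap] <- a[swap]
  reg
}

eval_population <- function(fitness, bits) {
  vals <- apply(bits, 1, fitness)
  if (!is.numeric(vals) || length(vals) != nrow(bits))
    stop("fitness function must return one finite number per bitstring")
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    stop("fitness returned a non-finite value for bitstring ",
         paste0(bits[bad[1], ], collapse = ""))
  }
  as.numeric(vals)
}

#' Run the quantum genetic algorithm
#'
#' Maximizes `fitness` over bitstrings of length `n_bits`. The loop is:
#' initialize all registers in uniform superposition; observe an initial
#' population and store the best individual `B`; then repeat (observe from
#' the previous registers, evaluate, rotate registers towards `B`, mutate,
#' update `B`) until `max_generations` is reached or the best fitness has
#' stalled for `stall_patience` generations. Elitism is exact: `B` is only
#' replaced by a strictly better individual, so the best-so-far fitness is
#' non-decreasing; ties keep the first-encountered individual.
#'
#' Gene-wise normalization of every register is checked (tolerance `1e-9`)
#' after every generation; the largest deviation seen is recorded in the
#' result.
#'
#' @param fitness Function mapping an integer 0/1 vector of length `n_bits`
#'   to a finite numeric scalar (higher is better). A non-finite value aborts
#'   the run with a diagnostic naming the offending bitstring.
#' @param n_bits Number of genes.
#' @param config A [qga_config()].
#' @return An object of class `"qga_run"` with elements `best_bits`,
#'   `best_fitness`, `generation_born` (generation at which the best was first
#'   observed), `history` (data frame: generation, best, mean), `register`
#'   (final state), `generations`, `max_norm_error`, and `config`.
#' @examples
#' onemax <- function(bits) sum(bits)
#' run <- qga(onemax, 8, qga_config(population_size = 10,
#'                                  max_generations = 25, seed = 1))
#' run$best_fitness
#' @export
qga <- function(fitness, n_bits, config = qga_config()) {
  stopifnot(is.function(fitness), inherits(config, "qga_config"))
  if (!is.numeric(n_bits) || n_bits < 1) stop("`n_bits` must be >= 1")
  n_bits <- as.integer(n_bits)
  if (!is.null(config$seed)) set.seed(config$seed)

  reg <- qubit_register(config$population_size, n_bits)
  bits <- observe_register(reg)
  fit <- eval_population(fitness, bits)
  i <- which.max(fit)
  best_bits <- bits[i, ]; best_fit <- fit[i]; born <- 0L

  hist_best <- best_fit
  hist_mean <- mean(fit)
  max_norm_err <- register_norm_error(reg)

  t <- 0L; stall <- 0L
  while (t < config$max_generations && stall < config$stall_patience) {
    t <- t + 1L
    bits <- observe_register(reg)
    fit <- eval_population(fitness, bits)
    reg <- update_register(reg, bits, fit, best_bits, best_fit, config)
    reg <- mutate_register(reg, config$mutation_rate)

    err <- register_norm_error(reg)
    max_norm_err <- max(max_norm_err, err)
    if (err > 1e-9)
      stop("qubit normalization violated at generation ", t,
           " (max |alpha^2 + beta^2 - 1| = ", format(err), ")")

    i <- which.max(fit)
    if (fit[i] > best_fit) {
      best_fit <- fit[i]; best_bits <- bits[i, ]; born <- t; stall <- 0L
    } else {
      stall <- stall + 1L
    }
    hist_best <- c(hist_best, best_fit)
    hist_mean <- c(hist_mean, mean(fit))
  }

  structure(list(best_bits = as.integer(best_bits),
                 best_fitness = best_fit,
                 generation_born = born,
                 history = data.frame(generation = seq_along(hist_best) - 1L,
                                      best = hist_best, mean = hist_mean),
                 register = reg,
                 generations = t,
                 max_norm_error = max_norm_err,
                 config = config),
            class = "qga_run")
}

#' @export
print.qga_run <- function(x, ...) {
  cat("Quantum genetic algorithm run\n")
  cat("  genes:          ", length(x$best_bits), "\n")
  cat("  generations:    ", x$generations, " (population ",
      x$config$population_size, ")\n", sep = "")
  cat("  best fitness:   ", format(x$best_fitness),
      " (first seen at generation ", x$generation_born, ")\n", sep = "")
  cat("  best bitstring: ", paste0(x$best_bits, collapse = ""), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.qga_run <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$generation, cbind(h$best, h$mean), type = "l",
                    lty = c(1, 2), col = c("black", "grey40"),
                    xlab = "generation", ylab = "fitness", ...)
  graphics::legend("bottomright", c("best", "mean"), lty = c(1, 2),
                   col = c("black", "grey40"), bty = "n")
  invisible(x)
}

#' Export a run record as structured text
#'
#' Writes (or returns) a JSON record of a seeded run: the configuration,
#' seed, per-generation best/mean fitness, and the final best bitstring.
#' Re-running [qga()] with the recorded config reproduces the run exactly.
#'
#' @param x A `"qga_run"` or `"qgafs"` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @param ... Unused.
#' @return The JSON string, invisibly when written to `path`.
#' @export
run_record <- function(x, path = NULL, ...) UseMethod("run_record")

#' @export
run_record.qga_run <- function(x, path = NULL, ...) {
  rec <- list(type = "qga_run",
              config = unclass(x$config),
              seed = x$config$seed,
              generations = x$generations,
              history = x$history,
              best_bits = x$best_bits,
              best_fitness = x$best_fitness)
  json <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

# Built-in benchmark fitness functions for the CLI and tests.
# onemax: number of 1-bits. linear: seeded random weights. trap: deceptive
# 4-bit trap blocks (all-ones block scores 4, otherwise 3 - ones).
benchmark_fitness <- function(name, m, seed = 1) {
  switch(name,
    onemax = function(bits) sum(bits),
    linear = {
      set.seed(seed)
      w <- stats::rnorm(m)
      function(bits) sum(w * bits)
    },
    trap = {
      if (m %% 4 != 0) stop("trap benchmark needs `m` divisible by 4")
      function(bits) {
        blocks <- matrix(bits, nrow = 4)
        sum(apply(blocks, 2, function(b) {
          s <- sum(b); if (s == 4) 4 else 3 - s
        }))
      }
    },
    stop("unknown benchmark '", name, "' (use onemax, linear or trap)")
  )
}
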