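#' Box-bounded search space
#'
#' @param lower,upper Numeric vectors of per-dimension bounds, `lower < upper`
#'   elementwise.
#' @return A `search_space` list with fields `lower`, `upper`, `dims`.
#' @export
search_space <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper)) abort("bound vectors must match in length.")
  if (!all(lower < upper)) abort("`lower` must be below `upper` elementwise.")
  structure(list(lower = lower, upper = upper, dims = length(lower)),
            class = "search_space")
}

#' Reptile search algorithm settings
#'
#' Defaults follow the study configuration: 20 candidate solutions, 50
#' iterations, and the two sensitivity parameters alpha and beta fixed at
#' 0.1. `epsilon` is the small denominator guard.
#'
#' @param n_candidates Population size N (>= 2).
#' @param max_iters Iteration budget T (>= 4, so each phase gets a quarter).
#' @param alpha,beta Sensitivity parameters of the hunting/encircling
#'   operators.
#' @param epsilon Small positive denominator guard.
#' @param seed Integer seed.
#' @return An `rsa_params` list.
#' @export
rsa_params <- function(n_candidates = 20, max_iters = 50, alpha = 0.1,
                       beta = 0.1, epsilon = 1e-10, seed = 1L) {
  stopifnot(n_candidates >= 2, max_iters >= 4, alpha > 0, beta > 0, epsilon > 0)
  structure(list(n_candidates = as.integer(n_candidates),
                 max_iters = as.integer(max_iters),
                 alpha = alpha, beta = beta, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "rsa_params")
}

#' Tent chaotic sequence
#'
#' Rows iterate the Tent map `z -> 2z` for `z <= 1/2`, `2(1 - z)` otherwise,
#' starting from a uniform random first row. The map's absorbing values
#' {0, 1/2, 1} (whose orbits collapse to 0) are replaced by a fresh uniform
#' draw whenever they appear.
#'
#' @param length Number of rows (sequence length).
#' @param dims Number of independent components per row.
#' @param seed Integer seed.
#' @param z1 Optional explicit first row (length `dims`), mainly for
#'   inspecting specific orbits; defaults to a uniform draw.
#' @return A `length` x `dims` matrix with entries in `[0, 1]`.
#' @export
tent_sequence <- function(length, dims, seed = 1L, z1 = NULL) {
  stopifnot(length >= 1, dims >= 1)
  set.seed(as.integer(seed))
  Z <- matrix(NA_real_, length, dims)
  if (!is.null(z1) && NROW(z1) != dims) abort("`z1` must have one entry per dim.")
  z <- z1 %||% runif(dims)
  bad <- z %in% c(0, 0.5, 1)
  if (any(bad)) z[bad] <- runif(sum(bad))
  Z[1, ] <- z
  if (length > 1) {
    for (i in 2:length) {
      z <- ifelse(z <= 0.5, 2 * z, 2 * (1 - z))
      bad <- z %in% c(0, 0.5, 1)
      if (any(bad)) z[bad] <- runif(sum(bad))
      Z[i, ] <- z
    }
  }
  Z
}

new_population <- function(positions, fitness = NULL) {
  best_position <- NULL; best_fitness <- NULL
  if (!is.null(fitness)) {
    b <- which.min(fitness)
    best_position <- positions[b, ]
    best_fitness <- fitness[b]
  }
  structure(list(positions = positions, fitness = fitness,
                 best_position = best_position, best_fitness = best_fitness),
            class = "rsa_population")
}

#' Tent-map population initialization
#'
#' Maps a [tent_sequence()] affinely onto the search box:
#' `x = z * (ub - lb) + lb`.
#'
#' @param space A [search_space()].
#' @param n Population size.
#' @param seed Integer seed.
#' @return An `rsa_population` with unevaluated fitness.
#' @export
tent_initialize <- function(space, n, seed = 1L) {
  Z <- tent_sequence(n, space$dims, seed)
  pos <- sweep(sweep(Z, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  new_population(pos)
}

clip_box <- function(X, space) {
  X <- sweep(X, 2, space$lower, pmax)
  sweep(X, 2, space$upper, pmin)
}

safe_objective <- function(objective) {
  force(objective)
  function(x) {
    v <- objective(x)
    if (!is.finite(v)) {
      warn("non-finite objective value treated as +Inf.")
      v <- Inf
    }
    v
  }
}

new_optimizer_result <- function(best_position, best_fitness, trace,
                                 evaluations, method) {
  structure(list(best_position = best_position, best_fitness = best_fitness,
                 trace = trace, evaluations = evaluations, method = method),
            class = "optimizer_result")
}

#' @export
print.optimizer_result <- function(x, ...) {
  cat(sprintf("# %s: best fitness %.6g after %d evaluations\n",
              toupper(x$method), x$best_fitness, x$evaluations))
  cat("# best position:", paste(sprintf("%.4g", x$best_position), collapse = ", "),
      "\n")
  invisible(x)
}

#' Gaussian random-walk perturbation with greedy acceptance
#'
#' Each individual is perturbed around the current best: with per-dimension
#' step scale `tau = (log(G)/G) * (x_i - best)`, the candidate is a draw from
#' `Normal(best, |tau|)` plus `g1 * best - g2 * x_i` with `g1, g2 ~ U[0, 1]`,
#' clipped to the box. The candidate replaces the individual only when its
#' objective value is strictly lower, so the population best never worsens.
#' At `G = 1` (and for the best individual itself) `tau = 0` and the Gaussian
#' degenerates to the deterministic mean.
#'
#' @param pop An `rsa_population` with evaluated fitness.
#' @param objective Function mapping a position vector to a scalar.
#' @param space A [search_space()].
#' @param iter Iteration counter G controlling the step decay.
#' @param seed Optional integer seed.
#' @return The perturbed `rsa_population`.
#' @export
gaussian_walk_step <- function(pop, objective, space, iter, seed = NULL) {
  if (is.null(pop$fitness)) abort("population fitness must be evaluated first.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  objective <- safe_objective(objective)
  upd <- grw_update(pop$positions, pop$fitness, pop$best_position,
                    pop$best_fitness, iter, space, objective)
  p <- new_population(upd$X, upd$fit)
  # keep the historical best in case no individual sits on it any more
  if (upd$best_f <= p$best_fitness) {
    p$best_position <- upd$best; p$best_fitness <- upd$best_f
  }
  p
}

grw_update <- function(X, fit, best, best_f, G, space, objective) {
  n <- nrow(X); D <- ncol(X)
  scale <- if (G <= 1) 0 else log(G) / G
  for (i in seq_len(n)) {
    tau <- scale * (X[i, ] - best)
    g1 <- runif(1); g2 <- runif(1)
    cand <- rnorm(D, mean = best, sd = abs(tau)) + g1 * best - g2 * X[i, ]
    cand <- pmin(pmax(cand, space$lower), space$upper)
    f <- objective(cand)
    if (f < fit[i]) {
      X[i, ] <- cand; fit[i] <- f
      if (f < best_f) { best <- cand; best_f <- f }
    }
  }
  list(X = X, fit = fit, best = best, best_f = best_f)
}

# Shared RSA/MRSA engine. The four update strategies follow the quarter
# schedule: high walking (t <= T/4), belly walking (T/4 < t <= T/2), hunting
# coordination (T/2 < t <= 3T/4) and hunting cooperation (t > 3T/4), with
#   R_ij  = (best_j - x_{r2,j}) / (best_j + eps)
#   ES(t) = 2 r3 (1 - t/T)            (default; "printed" variant: 2 r3 (1 - 1/T))
#   P_ij  = alpha + (x_ij - mean(x_i)) / (best_j (ub_j - lb_j) + eps)
#   eta_ij = best_j P_ij
# Positions are clipped to the box; the best-so-far is monotone.
reptile_engine <- function(objective, space, params, init = c("random", "tent"),
                           grw = c("none", "each_iter", "after_search"),
                           es_variant = c("decreasing", "printed"),
                           r3_integer = FALSE, method = "rsa") {
  init <- match.arg(init); grw <- match.arg(grw)
  es_variant <- match.arg(es_variant)
  objective <- safe_objective(objective)
  N <- params$n_candidates; Tmax <- params$max_iters
  alpha <- params$alpha; beta <- params$beta; eps <- params$epsilon
  lb <- space$lower; ub <- space$upper; D <- space$dims
  set.seed(params$seed)
  if (init == "tent") {
    Z <- tent_sequence_inner(N, D)
  } else {
    Z <- matrix(runif(N * D), N, D)
  }
  X <- sweep(sweep(Z, 2, ub - lb, "*"), 2, lb, "+")
  fit <- apply(X, 1, objective)
  evals <- N
  b <- which.min(fit); best <- X[b, ]; best_f <- fit[b]
  trace <- numeric(Tmax)
  for (t in seq_len(Tmax)) {
    r3 <- if (r3_integer) {
      matrix(sample(c(-1, 0, 1), N * D, replace = TRUE), N, D)
    } else {
      matrix(runif(N * D, -1, 1), N, D)
    }
    ES <- if (es_variant == "decreasing") 2 * r3 * (1 - t / Tmax) else
      2 * r3 * (1 - 1 / Tmax)
    r1 <- matrix(sample.int(N, N * D, replace = TRUE), N, D)
    r2 <- matrix(sample.int(N, N * D, replace = TRUE), N, D)
    rnd <- matrix(runif(N * D), N, D)
    Bm <- matrix(best, N, D, byrow = TRUE)
    span <- matrix(best * (ub - lb), N, D, byrow = TRUE)
    P <- alpha + (X - rowMeans(X)) / (span + eps)
    eta <- Bm * P
    Xr1 <- matrix(X[cbind(as.vector(r1), rep(seq_len(D), each = N))], N, D)
    Xr2 <- matrix(X[cbind(as.vector(r2), rep(seq_len(D), each = N))], N, D)
    R <- (Bm - Xr2) / (Bm + eps)
    Xnew <- if (t <= Tmax / 4) {
      Bm * (-eta) * beta - R * rnd
    } else if (t <= Tmax / 2) {
      Bm * Xr1 * ES * rnd
    } else if (t <= 3 * Tmax / 4) {
      Bm * P * rnd
    } else {
      Bm - eta * eps - R * rnd
    }
    X <- clip_box(Xnew, space)
    fit <- apply(X, 1, objective)
    evals <- evals + N
    b <- which.min(fit)
    if (fit[b] < best_f) { best <- X[b, ]; best_f <- fit[b] }
    if (grw == "each_iter") {
      upd <- grw_update(X, fit, best, best_f, t, space, objective)
      X <- upd$X; fit <- upd$fit; best <- upd$best; best_f <- upd$best_f
      evals <- evals + N
    }
    trace[t] <- best_f
  }
  if (grw == "after_search") {
    upd <- grw_update(X, fit, best, best_f, Tmax, space, objective)
    best <- upd$best; best_f <- upd$best_f
    evals <- evals + N
    trace[Tmax] <- best_f
  }
  new_optimizer_result(best, best_f, trace, evals, method)
}

# tent sequence drawing from the current RNG stream (no re-seeding), used by
# the engine so that seeding happens exactly once per run
tent_sequence_inner <- function(n, dims) {
  Z <- matrix(NA_real_, n, dims)
  z <- runif(dims)
  bad <- z %in% c(0, 0.5, 1)
  if (any(bad)) z[bad] <- runif(sum(bad))
  Z[1, ] <- z
  if (n > 1) {
    for (i in 2:n) {
      z <- ifelse(z <= 0.5, 2 * z, 2 * (1 - z))
      bad <- z %in% c(0, 0.5, 1)
      if (any(bad)) z[bad] <- runif(sum(bad))
      Z[i, ] <- z
    }
  }
  Z
}

#' Reptile search algorithm (RSA)
#'
#' Canonical crocodile-hunting metaheuristic minimizing `objective` over a
#' box: uniform random initialization, then per-iteration position updates
#' through the encircling (high/belly walking) and hunting
#' (coordination/cooperation) strategies on the quarter-iteration schedule.
#'
#' @param objective Function from a position vector to a scalar (minimized).
#'   Non-finite values are treated as `+Inf` with a warning.
#' @param space A [search_space()].
#' @param params An [rsa_params()].
#' @param es_variant `"decreasing"` (default) uses the evolutionary sense
#'   `ES(t) = 2 r3 (1 - t/T)`, decaying over iterations; `"printed"` uses the
#'   constant `2 r3 (1 - 1/T)` form.
#' @param r3_integer Draw `r3` from the integers `{-1, 0, 1}` instead of the
#'   continuous uniform on `[-1, 1]`.
#' @return An `optimizer_result`: `best_position`, `best_fitness`, the
#'   per-iteration best-so-far `trace` (non-increasing), and the evaluation
#'   count.
#' @export
rsa_minimize <- function(objective, space, params = rsa_params(),
                         es_variant = "decreasing", r3_integer = FALSE) {
  reptile_engine(objective, space, params, init = "random", grw = "none",
                 es_variant = es_variant, r3_integer = r3_integer,
                 method = "rsa")
}

#' Modified reptile search algorithm (MRSA)
#'
#' RSA augmented with Tent chaotic-map population initialization and a
#' per-iteration Gaussian random-walk perturbation around the best individual
#' with greedy acceptance. With `tent_init = FALSE` and `grw = "none"` it
#' reduces exactly to [rsa_minimize()] (identical trace under the same seed).
#'
#' @inheritParams rsa_minimize
#' @param tent_init Initialize via the Tent chaotic map.
#' @param grw When the Gaussian random walk runs: every iteration
#'   (`"each_iter"`, default), once after the search loop
#'   (`"after_search"`), or not at all (`"none"`).
#' @return An `optimizer_result`.
#' @export
mrsa_minimize <- function(objective, space, params = rsa_params(),
                          tent_init = TRUE, grw = "each_iter",
                          es_variant = "decreasing", r3_integer = FALSE) {
  reptile_engine(objective, space, params,
                 init = if (tent_init) "tent" else "random",
                 grw = grw, es_variant = es_variant, r3_integer = r3_integer,
                 method = "mrsa")
}

#' GA and PSO baseline optimizers
#'
#' Canonical baselines at the same interface and budget as [rsa_minimize()]:
#' a real-coded genetic algorithm (tournament selection of size 2, blend
#' (BLX-0.5) crossover, Gaussian mutation, elitism of one) and global-best
#' particle swarm optimization (inertia decaying linearly 0.9 to 0.4,
#' `c1 = c2 = 2`, velocities clamped to half the box range).
#'
#' @param method `"ga"` or `"pso"`.
#' @inheritParams rsa_minimize
#' @param n Population / swarm size.
#' @param iters Iteration budget.
#' @param seed Integer seed.
#' @return An `optimizer_result`.
#' @export
baseline_minimize <- function(method = c("ga", "pso"), objective, space,
                              n = 20, iters = 50, seed = 1L) {
  method <- match.arg(method)
  objective <- safe_objective(objective)
  set.seed(as.integer(seed))
  lb <- space$lower; ub <- space$upper; D <- space$dims
  X <- sweep(sweep(matrix(runif(n * D), n, D), 2, ub - lb, "*"), 2, lb, "+")
  fit <- apply(X, 1, objective)
  evals <- n
  b <- which.min(fit); best <- X[b, ]; best_f <- fit[b]
  trace <- numeric(iters)
  if (method == "ga") {
    p_cross <- 0.9; p_mut <- 0.1; mut_sd <- 0.1 * (ub - lb)
    for (t in seq_len(iters)) {
      newX <- matrix(NA_real_, n, D)
      newX[1, ] <- X[which.min(fit), ]  # elitism
      for (i in 2:n) {
        pick <- function() {
          cand <- sample.int(n, 2)
          cand[which.min(fit[cand])]
        }
        pa <- X[pick(), ]; pb <- X[pick(), ]
        child <- if (runif(1) < p_cross) {
          lo <- pmin(pa, pb); hi <- pmax(pa, pb); d <- hi - lo
          runif(D, lo - 0.5 * d, hi + 0.5 * d)
        } else pa
        mut <- runif(D) < p_mut
        child[mut] <- child[mut] + rnorm(sum(mut), sd = mut_sd[mut])
        newX[i, ] <- pmin(pmax(child, lb), ub)
      }
      X <- newX
      fit <- apply(X, 1, objective)
      evals <- evals + n
      b <- which.min(fit)
      if (fit[b] < best_f) { best <- X[b, ]; best_f <- fit[b] }
      trace[t] <- best_f
    }
  } else {
    V <- matrix(0, n, D)
    vmax <- 0.5 * (ub - lb)
    Pbest <- X; pbest_f <- fit
    for (t in seq_len(iters)) {
      w <- 0.9 - 0.5 * (t - 1) / max(1, iters - 1)
      r1 <- matrix(runif(n * D), n, D); r2 <- matrix(runif(n * D), n, D)
      Gm <- matrix(best, n, D, byrow = TRUE)
      V <- w * V + 2 * r1 * (Pbest - X) + 2 * r2 * (Gm - X)
      V <- sweep(V, 2, vmax, function(v, m) pmin(pmax(v, -m), m))
      X <- clip_box(X + V, space)
      fit <- apply(X, 1, objective)
      evals <- evals + n
      imp <- fit < pbest_f
      Pbest[imp, ] <- X[imp, ]; pbest_f[imp] <- fit[imp]
      b <- which.min(pbest_f)
      if (pbest_f[b] < best_f) { best <- Pbest[b, ]; best_f <- pbest_f[b] }
      trace[t] <- best_f
    }
  }
  new_optimizer_result(best, best_f, trace, evals, method)
}
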