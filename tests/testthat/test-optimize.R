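test_that("tent map iterates the piecewise-linear recurrence", {
  z <- tent_sequence(5, 1, seed = 1, z1 = 0.3)[, 1]
  expect_equal(z, c(0.3, 0.6, 0.8, 0.4, 0.8), tolerance = 1e-9)
  # absorbing start 0.5 would collapse to 1 -> 0 -> 0; the guard re-seeds
  z2 <- tent_sequence(4, 1, seed = 2, z1 = 0.5)[, 1]
  expect_false(any(z2[-1] %in% c(0, 1)))
  Z <- tent_sequence(200, 3, seed = 3)
  expect_true(all(Z >= 0 & Z <= 1))
})

test_that("tent initialization maps chaotic values onto the box", {
  unit <- search_space(c(0, 0), c(1, 1))
  p <- tent_initialize(unit, 6, seed = 4)
  expect_equal(p$positions, tent_sequence(6, 2, seed = 4))
  box <- search_space(c(-5, 0.25), c(5, 256))
  q <- tent_initialize(box, 50, seed = 5)
  expect_true(all(t(q$positions) >= box$lower & t(q$positions) <= box$upper))
  expect_equal(tent_initialize(box, 50, seed = 5)$positions, q$positions)
  expect_null(p$fitness)
})

test_that("RSA handles constant objectives and keeps a monotone trace", {
  res <- rsa_minimize(function(x) 3, sphere_space(), rsa_params(seed = 1))
  expect_equal(res$best_fitness, 3)
  expect_true(all(res$trace == 3))
  res2 <- rsa_minimize(sphere_fn, sphere_space(), rsa_params(seed = 2))
  expect_true(all(diff(res2$trace) <= 0))
  expect_true(all(res2$best_position >= -10 & res2$best_position <= 10))
  expect_gte(res2$evaluations, 20 * 50)
})

test_that("optimizers are deterministic under a fixed seed", {
  for (fn in list(rsa_minimize, mrsa_minimize)) {
    a <- fn(sphere_fn, sphere_space(), rsa_params(seed = 9))
    b <- fn(sphere_fn, sphere_space(), rsa_params(seed = 9))
    expect_identical(a$trace, b$trace)
    expect_identical(a$best_position, b$best_position)
  }
  for (m in c("ga", "pso")) {
    a <- baseline_minimize(m, sphere_fn, sphere_space(), seed = 9)
    b <- baseline_minimize(m, sphere_fn, sphere_space(), seed = 9)
    expect_identical(a$trace, b$trace)
  }
})

test_that("MRSA with Tent and random-walk disabled reduces exactly to RSA", {
  a <- rsa_minimize(sphere_fn, sphere_space(), rsa_params(seed = 7))
  b <- mrsa_minimize(sphere_fn, sphere_space(), rsa_params(seed = 7),
                     tent_init = FALSE, grw = "none")
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_position, b$best_position)
})

test_that("Gaussian random walk never worsens the population best", {
  set.seed(3)
  space <- sphere_space()
  pos <- matrix(runif(20, -10, 10), 10, 2)
  fit <- apply(pos, 1, sphere_fn)
  pop <- specdefect:::new_population(pos, fit)
  for (G in c(1, 2, 10)) {
    out <- gaussian_walk_step(pop, sphere_fn, space, iter = G, seed = G)
    expect_lte(out$best_fitness, pop$best_fitness)
    expect_true(all(t(out$positions) >= space$lower &
                      t(out$positions) <= space$upper))
  }
  # G = 1: log(1) = 0 so tau = 0 for every individual; the Gaussian part
  # degenerates to the best position plus the deterministic attraction
  expect_error(gaussian_walk_step(specdefect:::new_population(pos), sphere_fn,
                                  space, iter = 1), "evaluated")
})

test_that("non-finite objective values are treated as +Inf with a warning", {
  bad <- function(x) if (x[1] > 0) NaN else sum(x^2)
  w <- capture_warnings(res <- rsa_minimize(bad, sphere_space(),
                                            rsa_params(n_candidates = 5,
                                                       max_iters = 4,
                                                       seed = 1)))
  expect_true(any(grepl("non-finite", w)))
  expect_true(is.finite(res$best_fitness))
})

test_that("all optimizers solve the 2-D sphere at the study budget", {
  seeds <- 1:20
  f_rsa <- sapply(seeds, function(s)
    rsa_minimize(sphere_fn, sphere_space(), rsa_params(seed = s))$best_fitness)
  f_mrsa <- sapply(seeds, function(s)
    mrsa_minimize(sphere_fn, sphere_space(), rsa_params(seed = s))$best_fitness)
  expect_lte(median(f_rsa), 1e-2)
  expect_lte(median(f_mrsa), 1e-2)
  # paired comparison: the modified variant is at least as strong
  expect_lte(median(f_mrsa), median(f_rsa))
  f_ga <- sapply(seeds, function(s)
    baseline_minimize("ga", sphere_fn, sphere_space(), seed = s)$best_fitness)
  f_pso <- sapply(seeds, function(s)
    baseline_minimize("pso", sphere_fn, sphere_space(), seed = s)$best_fitness)
  expect_lte(median(f_ga), 1e-1)
  expect_lte(median(f_pso), 1e-1)
})

test_that("MRSA beats random search on the multimodal Rastrigin surface", {
  ras <- function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)
  space <- search_space(c(-5.12, -5.12), c(5.12, 5.12))
  f_m <- sapply(1:20, function(s)
    mrsa_minimize(ras, space, rsa_params(seed = s))$best_fitness)
  budget <- mrsa_minimize(ras, space, rsa_params(seed = 1))$evaluations
  f_rs <- sapply(1:20, function(s) {
    set.seed(s)
    min(apply(matrix(runif(budget * 2, -5.12, 5.12), ncol = 2), 1, ras))
  })
  expect_lt(median(f_m), median(f_rs))
})

test_that("search space and parameter validation reject bad input", {
  expect_error(search_space(c(1, 2), c(2, 1)), "elementwise")
  expect_error(search_space(0, c(1, 2)), "length")
  expect_error(rsa_params(n_candidates = 1), "n_candidates")
  expect_error(baseline_minimize("annealing", sphere_fn, sphere_space()))
})
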