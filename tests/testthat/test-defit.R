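sphere <- function(x) sum(x^2)

test_that("euclidean fitness behaves under each normalization mode", {
  expect_equal(euclidean_fitness(c(1, 2, 3), c(1, 2, 3),
                                 normalization = "none"), 0)
  expect_equal(euclidean_fitness(c(0, 0, 0), c(1, 1, 1),
                                 normalization = "none"), sqrt(3))
  # permutation covariance: shuffling both vectors identically changes nothing
  set.seed(31)
  m <- runif(6); t <- runif(6); p <- sample(6)
  expect_equal(euclidean_fitness(m, t), euclidean_fitness(m[p], t[p]))
  # minmax_both is invariant to affine rescaling of either input
  expect_equal(euclidean_fitness(m, t),
               euclidean_fitness(3 * m + 2, t), tolerance = 1e-12)
  # ratings_div_scale divides ratings only
  expect_equal(euclidean_fitness(c(0.5, 0.5), c(5, 5),
                                 normalization = "ratings_div_scale"), 0)
  expect_error(euclidean_fitness(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("weight-pair constraints reproduce the published relative distances", {
  # fitted uniform-digram pair: 2|0.33 - 0.30| / 0.63 = 0.0952 (feasible)
  expect_equal(round(relative_distance(0.33, 0.30), 4), 0.0952)
  # fitted alternating-digram pair: 2|0.69 - 0.68| / 1.37 = 0.0146 (feasible)
  expect_equal(round(relative_distance(0.69, 0.68), 4), 0.0146)
  cs <- marcellin_constraints()
  expect_true(check_constraints(c(0.33, 0.69, 0.68, 0.30), cs))
  expect_false(check_constraints(c(0.9, 0.5, 0.5, 0.1), cs))
  expect_false(check_constraints(c(0, 0.5, 0.5, 0), cs))  # zero pair infeasible
  expect_true(check_constraints(c(0.9, 0.5, 0.5, 0.1), NULL))
})

test_that("convergence criterion is the 1% band above the global best", {
  expect_true(convergence_check(0.728, 0.728))
  expect_false(convergence_check(0.7353, 0.728))  # 0.7353 > 0.72800 * 1.01
  expect_true(convergence_check(0.735, 0.728))
  expect_true(convergence_check(0, 5))
})

test_that("DE is reproducible bitwise and respects bounds", {
  ctrl <- de_control(seed = 7, generations = 40)
  a <- de_optimize(sphere, rep(-5, 4), rep(5, 4), control = ctrl)
  b <- de_optimize(sphere, rep(-5, 4), rep(5, 4), control = ctrl)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
  expect_identical(a$fitness, b$fitness)
  expect_true(all(a$population >= -5 & a$population <= 5))
  expect_true(all(diff(a$history) <= 0))  # greedy selection: monotone best
})

test_that("DE converges on the sphere function for every seed", {
  for (s in 1:10) {
    res <- de_optimize(sphere, rep(-5, 4), rep(5, 4),
                       control = de_control(seed = s))
    expect_lt(res$fitness, 1e-3)
  }
})

test_that("a constant objective leaves population fitness unchanged", {
  res <- de_optimize(function(x) 1.5, c(-1, -1), c(1, 1),
                     control = de_control(seed = 3, generations = 15))
  expect_true(all(res$history == 1.5))
  expect_equal(res$fitness, 1.5)
})

test_that("constrained DE only ever holds feasible members", {
  cs <- marcellin_constraints()
  obj <- function(w) sum((w - c(0.3, 0.7, 0.7, 0.3))^2)
  res <- de_optimize(obj, rep(1e-6, 4), rep(1 - 1e-6, 4), constraints = cs,
                     control = de_control(seed = 12, generations = 30))
  for (i in seq_len(nrow(res$population)))
    expect_true(check_constraints(res$population[i, ], cs))
  expect_true(check_constraints(res$params, cs))
  expect_lt(res$fitness, 1e-3)
})

test_that("DE configuration is validated", {
  expect_error(de_control(pop_size = 3), "at least 4")
  expect_error(de_control(F = 2.5), "\\[0, 2\\]")
  expect_error(de_control(CR = -0.1), "\\[0, 1\\]")
})

test_that("tuning grid has full shape and picks a convergent cell (reduced scale)", {
  # full-size tuning (180 cells x 10 runs x 100 generations) is a batch job;
  # the smoke benchmark shrinks the run count and generations but keeps the
  # full F x CR grid
  grid <- tune_parameters(sphere, c(-2, -2), c(2, 2), runs_per_cell = 1,
                          generations = 12, pop_size = 8, seed = 5)
  expect_equal(nrow(grid), 180L)
  expect_equal(sort(unique(grid$F)), seq(0.1, 2, by = 0.1))
  expect_equal(sort(unique(grid$CR)), seq(0.1, 0.9, by = 0.1))
  expect_true(all(grid$converge_pct >= 0 & grid$converge_pct <= 100))
  best <- attr(grid, "best")
  expect_equal(best$converge_pct, 100)
  # a focused grid at realistic depth converges in every run of the best
  # cell; the objective has a non-zero optimum (the 1% convergence band is
  # relative, so an optimum at exactly 0 would make it unmeetable)
  shifted <- function(x) sum(x^2) + 1
  small <- tune_parameters(shifted, c(-2, -2), c(2, 2), runs_per_cell = 5,
                           generations = 50, pop_size = 10, seed = 6,
                           F_grid = c(0.5, 0.6), CR_grid = c(0.5, 0.9))
  expect_equal(attr(small, "best")$converge_pct, 100)
})

test_that("fit_entropy wires the model curve into the optimizer", {
  expect_error(fit_entropy("shannon", NULL), "nothing to fit")
  curve <- synth_rating_curve(entropy_config("renyi", alpha = 2.37))
  fit <- fit_entropy("renyi", curve, control = de_control(seed = 2,
                                                          generations = 60))
  expect_s3_class(fit, "entropy_fit")
  expect_lt(abs(fit$params[["alpha"]] - 2.37), 0.1)
  expect_equal(fit$config$alpha, unname(fit$params["alpha"]))
  # fitted Marcellin parameters always satisfy the constraints
  mcurve <- synth_rating_curve(entropy_config("marcellin",
                                              weights = table1_weights))
  mfit <- fit_entropy("marcellin", mcurve,
                      control = de_control(seed = 2, generations = 40))
  expect_true(check_constraints(mfit$params, marcellin_constraints()))
  expect_named(mfit$params, c("OO", "OX", "XO", "XX"))
})

test_that("target curves validate and read from CSV", {
  expect_error(target_curve(c(0.2, 0.1), c(1, 2)), "increasing")
  expect_error(target_curve(0.5, 1), "length >= 2")
  expect_error(target_curve(c(0.1, 1.2), c(1, 2)), "\\[0, 1\\]")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# provenance comment", "pa,rating", "0.1,2", "0.5,8", "0.9,6"),
             path)
  tc <- read_target_curve(path)
  expect_s3_class(tc, "target_curve")
  expect_equal(tc$pa, c(0.1, 0.5, 0.9))
})
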