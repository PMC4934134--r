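test_that("Shannon entropy matches closed forms and rejects bad input", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_error(shannon_entropy(c(0.6, 0.6)), "sum to 1")
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")
})

test_that("Renyi entropy special orders and direct evaluation", {
  # uniform over N scores log2 N at every order, including the sentinels
  for (N in c(2, 4, 8)) {
    u <- rep(1 / N, N)
    for (a in c(0, 0.5, 1, 2, Inf))
      expect_equal(renyi_entropy(u, a), log2(N), tolerance = 1e-12)
  }
  expect_equal(renyi_entropy(c(0.5, 0.25, 0.25), 2), -log2(0.375),
               tolerance = 1e-12)
  expect_equal(renyi_entropy(c(0.5, 0.5, 0, 0), 0), 1)  # support size 2
  expect_equal(renyi_entropy(c(0.8, 0.2), Inf), -log2(0.8))
  expect_error(renyi_entropy(c(0.5, 0.5), -1), "non-negative")
})

test_that("Renyi limit at alpha -> 1, monotonicity and additivity", {
  set.seed(7)
  for (i in 1:20) {
    p <- rand_dist(sample(2:6, 1))
    h1 <- shannon_entropy(p)
    expect_lt(abs(renyi_entropy(p, 1 + 1e-6) - h1), 1e-4)
    expect_lt(abs(renyi_entropy(p, 1 - 1e-6) - h1), 1e-4)
    # non-increasing in alpha
    hs <- vapply(c(0, 0.25, 0.5, 0.9, 1, 1.5, 2, 5, 20, Inf),
                 function(a) renyi_entropy(p, a), numeric(1))
    expect_true(all(diff(hs) <= 1e-12))
    # additivity over product distributions
    q <- rand_dist(3)
    pq <- as.vector(outer(p, q))
    for (a in c(0.5, 2, 3))
      expect_equal(renyi_entropy(pq, a),
                   renyi_entropy(p, a) + renyi_entropy(q, a),
                   tolerance = 1e-9)
  }
})

test_that("Marcellin entropy: extremes, maximum at W, uniform-W symmetry", {
  # zero at any point mass
  expect_equal(marcellin_entropy(c(1, 0), c(0.3, 0.7)), 0)
  expect_equal(marcellin_entropy(c(0, 0, 1, 0), table1_weights), 0)
  # equals N when P = W (W itself a distribution)
  expect_equal(marcellin_entropy(c(0.5, 0.5), c(0.5, 0.5)), 2)
  expect_equal(marcellin_entropy(c(0.3, 0.7), c(0.3, 0.7)), 2)
  expect_equal(marcellin_entropy(rep(0.25, 4), rep(0.25, 4)), 4)
  # uniform W restores permutation symmetry; maximum then sits at uniform P
  set.seed(8)
  for (N in c(2, 4)) {
    w <- rep(1 / N, N)
    hu <- marcellin_entropy(rep(1 / N, N), w)
    for (i in 1:25) {
      p <- rand_dist(N)
      expect_equal(marcellin_entropy(p, w), marcellin_entropy(sample(p), w),
                   tolerance = 1e-12)
      expect_lte(marcellin_entropy(p, w), hu + 1e-12)
    }
  }
  expect_error(marcellin_entropy(c(0.5, 0.5), c(0.5, 1)), "strictly in")
  expect_error(marcellin_entropy(c(0.5, 0.5), c(0.2, 0.3, 0.5)), "same length")
})

test_that("Marcellin entropy is non-negative across the simplex for any valid W", {
  grid <- seq(0, 1, by = 0.1)
  set.seed(9)
  for (rep in 1:5) {
    w2 <- stats::runif(2, 0.01, 0.99)
    w4 <- stats::runif(4, 0.01, 0.99)
    for (p1 in grid) {
      expect_gte(marcellin_entropy(c(p1, 1 - p1), w2), 0)
      for (p2 in grid[grid <= 1 - p1]) {
        p <- c(p1, p2, (1 - p1 - p2) / 2, (1 - p1 - p2) / 2)
        expect_gte(marcellin_entropy(p, w4), 0)
      }
    }
  }
})

test_that("entropy_config validates family-specific parameters", {
  expect_error(entropy_config("renyi"), "alpha")
  expect_error(entropy_config("marcellin"), "weights")
  expect_error(entropy_config("shannon", alpha = 2), "Renyi")
  expect_error(entropy_config("marcellin", weights = c(a = 1, b = 2, c = 3, d = 4)),
               "names|strictly")
  cfg <- entropy_config("marcellin",
                        weights = c(XX = 0.30, OO = 0.33, XO = 0.68, OX = 0.69))
  expect_equal(cfg$weights, table1_weights)  # reordered to canonical order
})

test_that("second-order entropy of analytic level distributions", {
  sh <- entropy_config("shannon")
  bal <- c(0.5, 0.5)
  expect_equal(second_order(list(digram = expected_digram_dist(0.5), first = bal), sh), 1)
  expect_equal(second_order(list(digram = expected_digram_dist(1.0), first = bal), sh), 0)
  # Renyi at alpha = 1 collapses to Shannon on sequences too
  set.seed(10)
  r1 <- entropy_config("renyi", alpha = 1)
  for (i in 1:10) {
    s <- rand_string(sample(5:30, 1))
    expect_equal(second_order(s, r1), second_order(s, sh), tolerance = 1e-12)
  }
})

test_that("Marcellin curve over the P(A) grid is right-skewed (argmax > 0.5)", {
  cfg <- entropy_config("marcellin", weights = table1_weights)
  pa <- seq(0.1, 1, by = 0.1)
  curve <- model_curve(cfg, pa)
  expect_gt(pa[which.max(curve)], 0.5)
})

test_that("difference and conditional formulations agree exactly for Shannon", {
  # chain rule: exact whenever the first-order dist is the digram marginal
  set.seed(11)
  for (i in 1:20) {
    pa <- stats::runif(1)
    dig <- expected_digram_dist(pa)
    first <- c(X = dig[["XX"]] + dig[["XO"]], O = dig[["OO"]] + dig[["OX"]])
    d <- second_order(list(digram = dig, first = first),
                      entropy_config("shannon", formulation = "difference"))
    co <- second_order(list(digram = dig, first = first),
                       entropy_config("shannon", formulation = "conditional"))
    expect_equal(d, co, tolerance = 1e-12)
  }
  # ... and for random joint digram distributions with consistent marginals
  for (i in 1:20) {
    p <- rand_dist(4)
    names(p) <- c("OO", "OX", "XO", "XX")
    first <- c(X = p[["XX"]] + p[["XO"]], O = p[["OO"]] + p[["OX"]])
    d <- second_order(list(digram = p, first = first),
                      entropy_config("shannon"))
    co <- second_order(list(digram = p, first = first),
                       entropy_config("shannon", formulation = "conditional"))
    expect_equal(d, co, tolerance = 1e-12)
  }
  # for Renyi (alpha != 1) and Marcellin the formulations genuinely differ
  # on a non-product digram distribution (for any product distribution Renyi
  # additivity collapses the two, so the symmetric analytic levels cannot
  # separate them)
  dig <- c(OO = 0.4, OX = 0.2, XO = 0.1, XX = 0.3)
  first <- c(X = 0.4, O = 0.6)  # the digram first-symbol marginal
  x <- list(digram = dig, first = first)
  r2d <- second_order(x, entropy_config("renyi", alpha = 2))
  r2c <- second_order(x, entropy_config("renyi", alpha = 2,
                                        formulation = "conditional"))
  expect_false(isTRUE(all.equal(r2d, r2c)))
  md <- second_order(x, entropy_config("marcellin", weights = table1_weights))
  mc <- second_order(x, entropy_config("marcellin", weights = table1_weights,
                                       formulation = "conditional"))
  expect_false(isTRUE(all.equal(md, mc)))
})

test_that("entropy configs round-trip through JSON with fixed key names", {
  path <- withr::local_tempfile(fileext = ".json")
  cfg <- entropy_config("marcellin", weights = table1_weights,
                        formulation = "difference")
  write_entropy_config(cfg, path)
  json <- jsonlite::read_json(path)
  expect_named(json$weights, c("OO", "OX", "XO", "XX"), ignore.order = TRUE)
  back <- read_entropy_config(path)
  expect_equal(back$weights, cfg$weights)
  expect_equal(back$family, "marcellin")

  rcfg <- entropy_config("renyi", alpha = 2.37)
  write_entropy_config(rcfg, path)
  expect_equal(read_entropy_config(path)$alpha, 2.37)
})
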