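#' Target rating curve
#'
#' A set of (probability-of-alternation level, mean randomness rating) points:
#' the quantity the entropy models are fitted to.
#'
#' @param pa Strictly increasing vector of P(A) levels in \[0, 1\], length >= 2.
#' @param rating Mean ratings, same length.
#' @param rating_scale_max Top of the rating scale (default 10).
#' @return Object of class `target_curve` (a data.frame with columns `pa` and
#'   `rating`, attribute `rating_scale_max`).
#' @export
target_curve <- function(pa, rating, rating_scale_max = 10) {
  if (length(pa) < 2L || length(pa) != length(rating))
    stop("'pa' and 'rating' must have equal length >= 2")
  if (anyNA(pa) || anyNA(rating) || any(pa < 0) || any(pa > 1))
    stop("P(A) levels must be finite values in [0, 1]")
  if (any(diff(pa) <= 0)) stop("P(A) levels must be strictly increasing")
  structure(data.frame(pa = pa, rating = rating),
            rating_scale_max = rating_scale_max,
            class = c("target_curve", "data.frame"))
}

#' Read a target curve from CSV
#'
#' Expects columns `pa` and `rating`; lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @param rating_scale_max Top of the rating scale (default 10).
#' @return A [target_curve()].
#' @export
read_target_curve <- function(path, rating_scale_max = 10) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("pa", "rating") %in% names(df)))
    stop("target curve CSV must have columns 'pa' and 'rating'")
  target_curve(df$pa, df$rating, rating_scale_max = rating_scale_max)
}

#' Model curve over probability-of-alternation levels
#'
#' Evaluates the configured second-order entropy at each P(A) level of a
#' stimulus design, using the analytic expected digram distribution
#' ([expected_digram_dist()]) and the design's fixed first-order symbol split.
#' This is the deterministic model prediction that gets compared against a
#' mean rating curve.
#'
#' @param config An [entropy_config()].
#' @param pa_levels Vector of P(A) levels (default the classical grid
#'   0.1, 0.2, ..., 1.0).
#' @param n_first,n_second Design symbol counts (default 11 and 10: 21-symbol
#'   strings).
#' @return Numeric vector of model values, one per level.
#' @export
model_curve <- function(config, pa_levels = seq(0.1, 1, by = 0.1),
                        n_first = 11, n_second = 10) {
  first <- c(X = n_first, O = n_second) / (n_first + n_second)
  vapply(pa_levels, function(pa) {
    second_order(list(digram = expected_digram_dist(pa, n_first, n_second),
                      first = first), config)
  }, numeric(1))
}

# Min-max rescaling to [0, 1]; a flat vector maps to all 0.5 (documented
# degenerate-case convention).
.minmax <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Euclidean fitness between a model curve and a target curve
#'
#' The goodness-of-fit used by the DE fitter: the Euclidean distance between
#' model values and target ratings after normalization. Ratings (0-10) and
#' entropies (bits or dimensionless) live on different scales, so the default
#' `minmax_both` rescales both vectors to \[0, 1\] over the evaluated levels
#' and compares shapes; `ratings_div_scale` divides ratings by the scale
#' maximum and leaves the model raw; `none` compares raw vectors.
#'
#' @param model Numeric vector of model values.
#' @param target A [target_curve()] or a numeric vector of ratings of the
#'   same length as `model`.
#' @param normalization One of `"minmax_both"`, `"ratings_div_scale"`,
#'   `"none"`.
#' @param rating_scale_max Rating-scale maximum used by `ratings_div_scale`
#'   when `target` is a bare vector (a `target_curve` carries its own).
#' @return Non-negative distance (lower is better).
#' @export
euclidean_fitness <- function(model, target,
                              normalization = c("minmax_both",
                                                "ratings_div_scale", "none"),
                              rating_scale_max = 10) {
  normalization <- match.arg(normalization)
  if (inherits(target, "target_curve")) {
    rating_scale_max <- attr(target, "rating_scale_max")
    target <- target$rating
  }
  if (length(model) != length(target))
    stop("'model' and 'target' must have equal length")
  mt <- switch(normalization,
    minmax_both = list(.minmax(model), .minmax(target)),
    ratings_div_scale = list(model, target / rating_scale_max),
    none = list(model, target))
  sqrt(sum((mt[[1]] - mt[[2]])^2))
}

#' Relative distance between two non-negative values
#'
#' `2 |a - b| / (a + b)`, the quantity bounded by the digram-weight
#' equivalence constraints.
#'
#' @param a,b Non-negative numbers.
#' @return Relative distance; `Inf` when `a + b == 0`.
#' @export
relative_distance <- function(a, b) {
  if (a + b == 0) return(Inf)
  2 * abs(a - b) / (a + b)
}

#' Default Marcellin weight constraints
#'
#' The psychological-equivalence constraints on the digram weights: XX should
#' behave like OO and XO like OX, so each pair's relative distance
#' `2|a - b|/(a + b)` must not exceed `tol` (default 0.1).
#'
#' @param tol Maximum relative distance (default 0.1).
#' @return Constraint spec: list of `list(i, j, tol)` index triples on the
#'   canonical (OO, OX, XO, XX) parameter order.
#' @export
marcellin_constraints <- function(tol = 0.1) {
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be positive")
  list(list(i = 1L, j = 4L, tol = tol),   # (OO, XX)
       list(i = 2L, j = 3L, tol = tol))   # (OX, XO)
}

#' Check feasibility of a parameter vector
#'
#' @param params Numeric parameter vector.
#' @param constraints Constraint spec as produced by
#'   [marcellin_constraints()]: a list of `list(i, j, tol)`, each requiring
#'   `2|params[i] - params[j]| / (params[i] + params[j]) <= tol`. A pair
#'   summing to zero is infeasible. `NULL` means unconstrained.
#' @return `TRUE` iff every constraint holds.
#' @export
check_constraints <- function(params, constraints) {
  if (is.null(constraints) || !length(constraints)) return(TRUE)
  for (cs in constraints) {
    rd <- relative_distance(params[[cs$i]], params[[cs$j]])
    if (!is.finite(rd) || rd > cs$tol) return(FALSE)
  }
  TRUE
}

#' Differential Evolution control parameters
#'
#' @param pop_size Population size N (default 20; must be >= 4 so mutation
#'   can draw a target plus three distinct others).
#' @param F Differential weight in \[0, 2\] (default 0.6, the best tuning
#'   found on this problem family).
#' @param CR Crossover rate in \[0, 1\] (default 0.9).
#' @param generations Number of generations (default 100).
#' @param seed RNG seed for exact reproducibility (optional).
#' @param max_retries Trial-vector regenerations attempted when a trial
#'   violates the constraints before letting the target survive (default 100).
#' @return List of class `de_control`.
#' @export
de_control <- function(pop_size = 20, F = 0.6, CR = 0.9, generations = 100,
                       seed = NULL, max_retries = 100) {
  if (pop_size < 4) stop("'pop_size' must be at least 4")
  if (F < 0 || F > 2) stop("'F' must lie in [0, 2]")
  if (CR < 0 || CR > 1) stop("'CR' must lie in [0, 1]")
  if (generations < 1) stop("'generations' must be at least 1")
  structure(list(pop_size = as.integer(pop_size), F = F, CR = CR,
                 generations = as.integer(generations), seed = seed,
                 max_retries = as.integer(max_retries)),
            class = "de_control")
}

# Draw one constraint-feasible point in the box. Components are uniform;
# for each constrained pair the second member is drawn directly inside the
# feasible band b in [a(2-tol)/(2+tol), a(2+tol)/(2-tol)] intersected with
# its bounds (pure rejection on e.g. (0,1)^4 at tol = 0.1 succeeds only
# ~0.3% of the time, which would exhaust any sane retry cap).
.feasible_point <- function(lower, upper, constraints) {
  x <- stats::runif(length(lower), lower, upper)
  if (!is.null(constraints)) {
    for (cs in constraints) {
      a <- x[cs$i]
      lo <- max(lower[cs$j], a * (2 - cs$tol) / (2 + cs$tol))
      hi <- min(upper[cs$j], a * (2 + cs$tol) / (2 - cs$tol))
      x[cs$j] <- if (hi > lo) stats::runif(1, lo, hi) else
        min(max(a, lower[cs$j]), upper[cs$j])
    }
  }
  x
}

#' Differential Evolution optimizer (rand/1/bin) with feasibility constraints
#'
#' Minimizes `objective` over a box. Each generation, every target vector
#' v_ta is challenged by a trial built in two steps: mutation
#' `v_m = v_1 + F (v_2 - v_3)` from three distinct population members other
#' than the target (clipped to the bounds component-wise), and binomial
#' crossover taking each component from the mutant with probability CR (one
#' randomly chosen component is always taken from the mutant). A trial that
#' violates the constraint spec is discarded and regenerated, up to
#' `max_retries` times, after which the target survives unchallenged. The
#' greedy one-to-one selection keeps whichever of target and trial has the
#' better fitness, so the best-so-far fitness is non-increasing. Fully
#' deterministic given `control$seed`.
#'
#' @param objective Function mapping a parameter vector to a scalar to
#'   minimize.
#' @param lower,upper Numeric bound vectors of equal length.
#' @param constraints Optional constraint spec (see [check_constraints()]).
#' @param control A [de_control()].
#' @return List of class `de_fit`: `params` (best member), `fitness`,
#'   `history` (best fitness per generation), `generations_used`,
#'   `converged` (NA here; see [convergence_check()] — convergence is defined
#'   relative to the best fitness across repeated runs), `population`,
#'   `control`.
#' @export
de_optimize <- function(objective, lower, upper, constraints = NULL,
                        control = de_control()) {
  if (!inherits(control, "de_control")) stop("'control' must be a de_control")
  d <- length(lower)
  if (length(upper) != d || any(upper <= lower) || !all(is.finite(c(lower, upper))))
    stop("'lower' and 'upper' must be finite with lower < upper component-wise")
  if (!is.null(control$seed)) set.seed(control$seed)
  np <- control$pop_size
  pop <- do.call(rbind, lapply(seq_len(np), function(i)
    .feasible_point(lower, upper, constraints)))
  fit <- apply(pop, 1, objective)
  history <- numeric(control$generations)
  for (g in seq_len(control$generations)) {
    for (t in seq_len(np)) {
      trial <- NULL
      for (try in seq_len(max(1L, control$max_retries))) {
        idx <- sample(seq_len(np)[-t], 3L)
        vm <- pop[idx[1], ] + control$F * (pop[idx[2], ] - pop[idx[3], ])
        vm <- pmin(pmax(vm, lower), upper)
        jrand <- sample.int(d, 1L)
        use_mut <- stats::runif(d) < control$CR
        use_mut[jrand] <- TRUE
        cand <- ifelse(use_mut, vm, pop[t, ])
        if (check_constraints(cand, constraints)) { trial <- cand; break }
      }
      if (is.null(trial)) next  # retries exhausted: target survives
      f_tr <- objective(trial)
      if (f_tr <= fit[t]) { pop[t, ] <- trial; fit[t] <- f_tr }
    }
    history[g] <- min(fit)
  }
  best <- which.min(fit)
  structure(list(params = pop[best, ], fitness = fit[best], history = history,
                 generations_used = control$generations, converged = NA,
                 population = pop, control = control),
            class = "de_fit")
}

#' Convergence criterion relative to the best fitness across runs
#'
#' A run converged when its best fitness is less than the best fitness among
#' all runs increased by 1%.
#'
#' @param run_best Best fitness of one run (>= 0).
#' @param global_best Best fitness among all runs (>= 0).
#' @return Logical.
#' @export
convergence_check <- function(run_best, global_best) {
  run_best < global_best * 1.01
}

#' Tune the DE differential weight and crossover rate
#'
#' Runs the optimizer over the full grid F = 0.1, 0.2, ..., 2.0 crossed with
#' CR = 0.1, ..., 0.9 (180 cells), `runs_per_cell` seeded runs each. After
#' all runs, the best fitness over the whole grid defines convergence (see
#' [convergence_check()]); each cell reports its convergence percentage and
#' the mean number of generations its converged runs needed to first reach
#' the convergence band. The selected cell maximizes convergence percentage,
#' ties broken by fewer mean generations.
#'
#' @param objective,lower,upper,constraints As in [de_optimize()].
#' @param runs_per_cell Runs per (F, CR) cell (default 10).
#' @param generations,pop_size Per-run DE settings.
#' @param seed Base seed; run seeds are derived deterministically from it.
#' @param F_grid,CR_grid Override the default grids (mainly for reduced-scale
#'   smoke benchmarks).
#' @return data.frame with columns `F`, `CR`, `converge_pct`,
#'   `mean_generations`; the winning cell is in attribute `best`, the global
#'   best fitness in attribute `global_best`.
#' @export
tune_parameters <- function(objective, lower, upper, constraints = NULL,
                            runs_per_cell = 10, generations = 100,
                            pop_size = 20, seed = 1,
                            F_grid = seq(0.1, 2, by = 0.1),
                            CR_grid = seq(0.1, 0.9, by = 0.1)) {
  if (runs_per_cell < 1) stop("'runs_per_cell' must be at least 1")
  grid <- expand.grid(F = F_grid, CR = CR_grid)
  run_seed <- 0L
  histories <- vector("list", nrow(grid))
  bests <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    hs <- vector("list", runs_per_cell)
    bs <- numeric(runs_per_cell)
    for (r in seq_len(runs_per_cell)) {
      run_seed <- run_seed + 1L
      ctrl <- de_control(pop_size = pop_size, F = grid$F[k], CR = grid$CR[k],
                         generations = generations,
                         seed = (seed + run_seed) %% .Machine$integer.max)
      res <- de_optimize(objective, lower, upper, constraints, ctrl)
      hs[[r]] <- res$history
      bs[r] <- res$fitness
    }
    histories[[k]] <- hs
    bests[[k]] <- bs
  }
  global_best <- min(unlist(bests))
  band <- global_best * 1.01
  converge_pct <- numeric(nrow(grid))
  mean_gen <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    conv <- vapply(bests[[k]], convergence_check, logical(1), global_best)
    converge_pct[k] <- 100 * mean(conv)
    gens <- vapply(histories[[k]][conv],
                   function(h) which(h < band)[1], numeric(1))
    mean_gen[k] <- if (any(conv)) mean(gens) else NA_real_
  }
  out <- data.frame(F = grid$F, CR = grid$CR, converge_pct = converge_pct,
                    mean_generations = mean_gen)
  ord <- order(-out$converge_pct, out$mean_generations)
  attr(out, "best") <- out[ord[1], , drop = FALSE]
  attr(out, "global_best") <- global_best
  out
}

#' Fit an entropy model to a target rating curve
#'
#' Estimates the free parameters of the Renyi (order alpha) or Marcellin
#' (four digram weights) second-order entropy so that the model curve over
#' the target's P(A) levels best matches the mean ratings, by minimizing
#' [euclidean_fitness()] with [de_optimize()]. Marcellin weights are searched
#' on (0, 1)^4 under the pairwise equivalence constraints
#' ([marcellin_constraints()]); Renyi's alpha on (0, `alpha_max`\], no
#' constraints. Shannon has no free parameter, so requesting it is an error
#' (evaluate [model_curve()] directly). With `n_runs > 1` the fit is repeated
#' from derived seeds and the best run is returned, its `converged` flag set
#' by [convergence_check()] against the best fitness across runs.
#'
#' @param family `"renyi"` or `"marcellin"`.
#' @param target A [target_curve()] (or data.frame with `pa` and `rating`).
#' @param control A [de_control()].
#' @param normalization Passed to [euclidean_fitness()].
#' @param formulation Second-order formulation for the fitted config.
#' @param n_first,n_second Stimulus design symbol counts.
#' @param alpha_max Upper bound of the Renyi search interval (default 10; the
#'   lower bound is numerically open at 1e-6).
#' @param n_runs Number of independent DE runs (default 1).
#' @return Object of class `entropy_fit`: the `de_fit` fields plus `family`,
#'   named `params`, the fitted `config`, `normalization` and `n_runs`.
#' @export
fit_entropy <- function(family = c("renyi", "marcellin"), target,
                        control = de_control(),
                        normalization = c("minmax_both", "ratings_div_scale",
                                          "none"),
                        formulation = c("difference", "conditional"),
                        n_first = 11, n_second = 10, alpha_max = 10,
                        n_runs = 1) {
  if (identical(family, "shannon"))
    stop("Shannon has nothing to fit; use model_curve() directly")
  family <- match.arg(family)
  normalization <- match.arg(normalization)
  formulation <- match.arg(formulation)
  if (!inherits(target, "target_curve")) {
    if (!all(c("pa", "rating") %in% names(target)))
      stop("'target' must be a target_curve or have columns 'pa' and 'rating'")
    target <- target_curve(target$pa, target$rating)
  }
  eps <- 1e-6
  if (family == "marcellin") {
    lower <- rep(eps, 4); upper <- rep(1 - eps, 4)
    constraints <- marcellin_constraints()
    make_config <- function(p)
      entropy_config("marcellin",
                     weights = stats::setNames(p, DIGRAMS),
                     formulation = formulation)
  } else {
    lower <- eps; upper <- alpha_max
    constraints <- NULL
    make_config <- function(p)
      entropy_config("renyi", alpha = p, formulation = formulation)
  }
  objective <- function(p) {
    euclidean_fitness(
      model_curve(make_config(p), pa_levels = target$pa,
                  n_first = n_first, n_second = n_second),
      target, normalization = normalization)
  }
  base_seed <- if (is.null(control$seed)) NULL else control$seed
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    ctrl <- control
    if (!is.null(base_seed))
      ctrl$seed <- (base_seed + r - 1L) %% .Machine$integer.max
    runs[[r]] <- de_optimize(objective, lower, upper, constraints, ctrl)
  }
  fits <- vapply(runs, `[[`, numeric(1), "fitness")
  best <- which.min(fits)
  res <- runs[[best]]
  res$converged <- if (n_runs > 1)
    convergence_check(res$fitness, min(fits)) else NA
  res$family <- family
  res$params <- if (family == "marcellin")
    stats::setNames(res$params, DIGRAMS) else c(alpha = res$params)
  res$config <- make_config(unname(res$params))
  res$normalization <- normalization
  res$n_runs <- n_runs
  class(res) <- c("entropy_fit", "de_fit")
  res
}

#' @export
print.entropy_fit <- function(x, ...) {
  cat(sprintf("<entropy_fit> %s fit, fitness %.6g (%d generations, %d run%s)\n",
              x$family, x$fitness, x$generations_used, x$n_runs,
              if (x$n_runs == 1) "" else "s"))
  cat("  params:", paste(sprintf("%s=%.4g", names(x$params), x$params),
                         collapse = " "), "\n")
  invisible(x)
}

#' Write a fit result to JSON
#'
#' Emits family, fitted parameters, fitness, convergence diagnostics and an
#' echo of the DE configuration (including the seed) so results are
#' self-describing and byte-reproducible.
#'
#' @param fit An `entropy_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  obj <- list(family = fit$family,
              params = as.list(fit$params),
              fitness = fit$fitness,
              converged = fit$converged,
              generations_used = fit$generations_used,
              normalization = fit$normalization,
              n_runs = fit$n_runs,
              config = list(pop_size = fit$control$pop_size,
                            F = fit$control$F, CR = fit$control$CR,
                            generations = fit$control$generations,
                            max_retries = fit$control$max_retries),
              seed = fit$control$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
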