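# Validate a probability vector: non-negative masses summing to 1.
.check_dist <- function(p, tol = 1e-9, what = "probability vector") {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p))
    stop(what, " must be a numeric vector without NAs")
  if (any(p < 0)) stop(what, " has negative mass")
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("%s must sum to 1 (got %.12g)", what, sum(p)))
  invisible(p)
}

#' Shannon entropy (bits)
#'
#' H(P) = sum_i p_i log2(1/p_i), with the convention 0 log(1/0) = 0.
#'
#' @param p Probability vector (non-negative, sums to 1 within 1e-9).
#' @return Entropy in bits, in \[0, log2(length(p))\].
#' @export
shannon_entropy <- function(p) {
  .check_dist(p)
  pp <- p[p > 0]
  -sum(pp * log2(pp))
}

#' Renyi entropy of order alpha (bits)
#'
#' H_alpha(P) = (1/(1 - alpha)) log2(sum_i p_i^alpha) for alpha not in
#' \{1, Inf\}. The family interpolates the classical entropies: alpha = 0
#' gives the Hartley (max) entropy log2 of the support size, alpha -> 1 the
#' Shannon entropy (returned exactly at alpha = 1), alpha = 2 the collision
#' entropy, and alpha = Inf (an explicit sentinel, never inferred from
#' magnitude) the min-entropy -log2(max p_i). For any alpha the uniform
#' distribution over N events scores log2 N; the function is non-increasing
#' in alpha and additive over product distributions.
#'
#' @param p Probability vector.
#' @param alpha Single non-negative order; `Inf` selects min-entropy.
#' @return Entropy in bits.
#' @export
renyi_entropy <- function(p, alpha) {
  .check_dist(p)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("'alpha' must be a single non-negative number")
  if (is.infinite(alpha)) return(-log2(max(p)))
  if (alpha == 1) return(shannon_entropy(p))
  if (alpha == 0) return(log2(sum(p > 0)))
  pp <- p[p > 0]                     # 0^alpha := 0
  log2(sum(pp^alpha)) / (1 - alpha)
}

#' Marcellin's asymmetric entropy
#'
#' H_W(P) = sum_i p_i (1 - p_i) / ((1 - 2 w_i) p_i + w_i^2), where
#' W = (w_1, ..., w_N) is the "worst" distribution at which the maximum is
#' attained. The measure is non-negative (the denominator is linear in p_i
#' and positive at both ends: w_i^2 at p_i = 0 and (1 - w_i)^2 at p_i = 1),
#' zero at any point mass, equals N when P = W, and is symmetric under
#' permutations only when W is uniform. W need not sum to 1.
#'
#' @param p Probability vector.
#' @param w Worst-distribution vector, same length as `p`, each component
#'   strictly inside (0, 1).
#' @return Non-negative entropy value (dimensionless).
#' @export
marcellin_entropy <- function(p, w) {
  .check_dist(p)
  if (length(w) != length(p))
    stop("'w' and 'p' must have the same length")
  if (!is.numeric(w) || anyNA(w) || any(w <= 0) || any(w >= 1))
    stop("every worst-distribution component must lie strictly in (0, 1)")
  sum(p * (1 - p) / ((1 - 2 * w) * p + w^2))
}

#' Entropy configuration
#'
#' Bundles an entropy family with its parameters for use by [second_order()],
#' [model_curve()] and the scoring/fitting front ends. Log base is fixed at 2
#' (bits) throughout.
#'
#' @param family One of `"shannon"`, `"renyi"`, `"marcellin"`.
#' @param alpha Renyi order (required iff `family = "renyi"`); `Inf` allowed
#'   as an explicit min-entropy sentinel.
#' @param weights Marcellin worst distribution over the four digram
#'   categories (required iff `family = "marcellin"`). Named vector with names
#'   `OO, OX, XO, XX` (any order), or unnamed length-4 vector taken in that
#'   canonical order.
#' @param first_order_weights Marcellin worst distribution for the two-symbol
#'   first-order term of the difference formulation; default symmetric
#'   `c(0.5, 0.5)` (the rating-stimulus designs hold the symbol split nearly
#'   constant, so this term is a near-constant offset).
#' @param formulation `"difference"` (default): family entropy of the digram
#'   distribution minus family entropy of the first-order distribution.
#'   `"conditional"`: mixture over the current symbol of the family entropy of
#'   the next-symbol conditional distribution, weighted by the digram
#'   first-symbol marginal; Marcellin then uses the conditional worst pairs
#'   (w_XX, w_XO) given X and (w_OO, w_OX) given O.
#' @return An object of class `entropy_config`.
#' @examples
#' entropy_config("marcellin",
#'   weights = c(OO = 0.33, OX = 0.69, XO = 0.68, XX = 0.30))
#' @export
entropy_config <- function(family = c("shannon", "renyi", "marcellin"),
                           alpha = NULL, weights = NULL,
                           first_order_weights = c(0.5, 0.5),
                           formulation = c("difference", "conditional")) {
  family <- match.arg(family)
  formulation <- match.arg(formulation)
  if (family == "renyi") {
    if (is.null(alpha)) stop("Renyi configuration requires 'alpha'")
    if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
      stop("'alpha' must be a single non-negative number")
  } else if (!is.null(alpha)) {
    stop("'alpha' is only meaningful for the Renyi family")
  }
  if (family == "marcellin") {
    if (is.null(weights)) stop("Marcellin configuration requires 'weights'")
    weights <- .canon_weights(weights, DIGRAMS)
    first_order_weights <- .canon_weights(first_order_weights, c("X", "O"))
  } else if (!is.null(weights)) {
    stop("'weights' is only meaningful for the Marcellin family")
  }
  structure(list(family = family, alpha = alpha, weights = weights,
                 first_order_weights = if (family == "marcellin")
                   first_order_weights else NULL,
                 formulation = formulation, log_base = 2),
            class = "entropy_config")
}

.canon_weights <- function(w, categories) {
  if (!is.numeric(w) || length(w) != length(categories) || anyNA(w))
    stop(sprintf("weights must be a numeric vector of length %d over (%s)",
                 length(categories), paste(categories, collapse = ", ")))
  if (!is.null(names(w)) && any(nzchar(names(w)))) {
    if (!setequal(names(w), categories))
      stop("weight names must be exactly (", paste(categories, collapse = ", "), ")")
    w <- w[categories]
  } else names(w) <- categories
  if (any(w <= 0) || any(w >= 1))
    stop("every weight must lie strictly in (0, 1)")
  w
}

#' @export
print.entropy_config <- function(x, ...) {
  cat("<entropy_config>", x$family, "/", x$formulation, "formulation\n")
  if (x$family == "renyi") cat("  alpha =", x$alpha, "\n")
  if (x$family == "marcellin") {
    cat("  weights:", paste(sprintf("%s=%.3g", names(x$weights), x$weights),
                            collapse = " "), "\n")
    cat("  first-order weights:",
        paste(sprintf("%.3g", x$first_order_weights), collapse = " "), "\n")
  }
  invisible(x)
}

# Family entropy of a distribution under a config; `role` selects which
# Marcellin worst distribution applies.
.family_entropy <- function(p, config,
                            role = c("digram", "first", "cond_X", "cond_O")) {
  role <- match.arg(role)
  switch(config$family,
    shannon = shannon_entropy(p),
    renyi = renyi_entropy(p, config$alpha),
    marcellin = {
      w <- switch(role,
        digram = config$weights,
        first = config$first_order_weights,
        cond_X = config$weights[c("XX", "XO")],
        cond_O = config$weights[c("OO", "OX")])
      marcellin_entropy(p, w)
    })
}

#' Second-order entropy of a sequence or of a digram/first-order pair
#'
#' The second-order entropy H2 quantifies the information contributed by the
#' second member of each adjacent symbol pair. Under the default difference
#' formulation H2 = F(digram distribution) - F(first-order distribution),
#' where F is the configured family; for Shannon this equals the conditional
#' entropy of the next symbol given the current one. The conditional
#' formulation computes that mixture of conditional entropies directly and
#' coincides with the difference form for Shannon (chain rule) whenever the
#' first-order distribution equals the digram first-symbol marginal; for
#' Renyi (alpha != 1) and Marcellin the two formulations genuinely differ.
#'
#' @param x Either a `binseq` of length >= 2 (or a string), or a list with
#'   elements `digram` (probability vector over OO, OX, XO, XX) and `first`
#'   (probability vector over X, O).
#' @param config An [entropy_config()]; default plain Shannon.
#' @return Second-order entropy value (bits for Shannon/Renyi).
#' @examples
#' second_order("XXXOOOXOXO")                     # Shannon H2
#' second_order(list(digram = expected_digram_dist(0.5), first = c(.5, .5)))
#' @export
second_order <- function(x, config = entropy_config("shannon")) {
  if (!inherits(config, "entropy_config")) stop("'config' must be an entropy_config")
  if (is.list(x) && !inherits(x, "binseq")) {
    if (is.null(x$digram) || is.null(x$first))
      stop("list input must have elements 'digram' and 'first'")
    dig <- x$digram
    first <- x$first
    if (length(dig) != 4L) stop("'digram' must have 4 components")
    if (length(first) != 2L) stop("'first' must have 2 components")
    if (is.null(names(dig))) names(dig) <- DIGRAMS else dig <- dig[DIGRAMS]
    if (is.null(names(first))) names(first) <- c("X", "O")
  } else {
    seq <- as_binseq(x)
    if (seq$n < 2L) stop("second-order entropy undefined for length < 2")
    dig <- digram_dist(seq)
    first <- first_order_dist(seq)
  }
  .check_dist(dig, what = "digram distribution")
  .check_dist(first, what = "first-order distribution")
  if (config$formulation == "difference") {
    .family_entropy(dig, config, "digram") - .family_entropy(first, config, "first")
  } else {
    marg_x <- dig[["XX"]] + dig[["XO"]]
    marg_o <- dig[["OO"]] + dig[["OX"]]
    h <- 0
    if (marg_x > 0)
      h <- h + marg_x * .family_entropy(
        c(dig[["XX"]], dig[["XO"]]) / marg_x, config, "cond_X")
    if (marg_o > 0)
      h <- h + marg_o * .family_entropy(
        c(dig[["OO"]], dig[["OX"]]) / marg_o, config, "cond_O")
    h
  }
}

#' Write an entropy configuration to JSON
#'
#' Serializes with the fixed key layout
#' `{"family": "marcellin", "weights": {"OO": .., "OX": .., "XO": .., "XX": ..},
#' "formulation": "difference"}` so fit output and scoring input interoperate.
#'
#' @param config An `entropy_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_entropy_config <- function(config, path) {
  if (!inherits(config, "entropy_config")) stop("'config' must be an entropy_config")
  obj <- list(family = config$family, formulation = config$formulation)
  if (config$family == "renyi") obj$alpha <- config$alpha
  if (config$family == "marcellin") {
    obj$weights <- as.list(config$weights)
    obj$first_order_weights <- unname(config$first_order_weights)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an entropy configuration from JSON
#'
#' @param path JSON file written by [write_entropy_config()] (or hand-written
#'   with the same keys).
#' @return An `entropy_config`.
#' @export
read_entropy_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  entropy_config(
    family = obj$family,
    alpha = obj$alpha,
    weights = if (!is.null(obj$weights)) unlist(obj$weights),
    first_order_weights = if (!is.null(obj$first_order_weights))
      unlist(obj$first_order_weights) else c(0.5, 0.5),
    formulation = if (!is.null(obj$formulation)) obj$formulation else "difference")
}
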