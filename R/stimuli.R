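# Uniform random composition of `total` into `parts` positive integers
# (stars and bars: sample parts-1 distinct cut points out of total-1).
.rand_composition <- function(total, parts) {
  if (parts == 1L) return(total)
  if (total < parts) stop("cannot split ", total, " into ", parts, " positive parts")
  cuts <- sort(sample.int(total - 1L, parts - 1L))
  diff(c(0L, cuts, total))
}

# One 21-symbol sequence with exactly r runs, n_x Xs, n_o Os, starting with
# `start`. Run lengths of the start symbol are a random composition of its
# count into ceiling(r/2) parts; the other symbol fills the floor(r/2)
# interleaved runs.
.build_fk_sequence <- function(n_x, n_o, r, start) {
  k1 <- ceiling(r / 2)
  k2 <- floor(r / 2)
  other <- if (start == "X") "O" else "X"
  c_start <- if (start == "X") n_x else n_o
  c_other <- if (start == "X") n_o else n_x
  if (c_start < k1 || c_other < k2)
    stop(sprintf("infeasible design: %d runs of '%s' from %d symbols",
                 k1, start, c_start))
  len1 <- .rand_composition(c_start, k1)
  len2 <- if (k2 > 0L) .rand_composition(c_other, k2) else integer(0)
  lens <- integer(r)
  lens[seq(1L, r, by = 2L)] <- len1
  if (k2 > 0L) lens[seq(2L, r, by = 2L)] <- len2
  syms <- rep(c(start, other), length.out = r)
  new_binseq(rep(syms, times = lens))
}

#' Generate rating-task stimulus sets (21-symbol design)
#'
#' Builds sets of ten 21-symbol binary sequences with probability of
#' alternation ranging over 0.1, 0.2, ..., 1.0 — the classical design used to
#' measure mean randomness ratings. The run count is exact at every level
#' (r = 20 pa + 1, so P(A) matches the requested level exactly, not in
#' expectation); within each set, half the sequences carry 11 Xs and 10 Os
#' and half the reverse, alternating across levels. Run lengths are sampled
#' as uniform random compositions. The starting symbol alternates across
#' set/level to balance XO against OX digrams in aggregate; at the fully
#' alternating level the majority symbol must start (the 11 singleton runs).
#'
#' @param n_sets Number of sets of ten sequences (default 4, i.e. 40 strings).
#' @param seed Optional RNG seed.
#' @return Object of class `fk_stimuli`: list with `sequences` (list of
#'   `binseq`) and `design` (data.frame with columns `set`, `pa`, `r`, `n_x`,
#'   `n_o`, `start`).
#' @export
generate_fk_set <- function(n_sets = 4, seed = NULL) {
  if (n_sets < 1) stop("'n_sets' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  seqs <- list()
  idx <- 0L
  for (s in seq_len(n_sets)) {
    for (k in 1:10) {
      pa <- k / 10
      r <- 2L * k + 1L
      majority_x <- (k %% 2L) == 1L      # half the set 11X/10O, half 10X/11O
      n_x <- if (majority_x) 11L else 10L
      n_o <- 21L - n_x
      start <- if (((s + k) %% 2L) == 0L) "X" else "O"
      if (r == 21L) start <- if (majority_x) "X" else "O"  # needs 11 runs
      idx <- idx + 1L
      seqs[[idx]] <- .build_fk_sequence(n_x, n_o, r, start)
      rows[[idx]] <- data.frame(set = s, pa = pa, r = r, n_x = n_x, n_o = n_o,
                                start = start, stringsAsFactors = FALSE)
    }
  }
  structure(list(sequences = seqs, design = do.call(rbind, rows)),
            class = "fk_stimuli")
}

#' @export
print.fk_stimuli <- function(x, ...) {
  cat(sprintf("<fk_stimuli> %d sequences (%d sets x 10 P(A) levels)\n",
              length(x$sequences), max(x$design$set)))
  invisible(x)
}

#' Enumerate the 128 canonical octograms
#'
#' All length-8 binary sequences modulo symbol complementation: of the 256
#' raw strings, each configuration appears twice (e.g. `OOOOOOOO` and
#' `XXXXXXXX`), leaving 128 canonical representatives, returned in
#' deterministic lexicographic order (O before X).
#'
#' @return List of 128 `binseq` objects.
#' @export
enumerate_octograms <- function() {
  grid <- expand.grid(rep(list(c("O", "X")), 8), stringsAsFactors = FALSE)
  all_strings <- apply(as.matrix(grid), 1, paste, collapse = "")
  canon <- vapply(all_strings,
                  function(s) as.character(canonicalize(parse_sequence(s))),
                  character(1))
  lapply(sort(unique(canon), method = "radix"), parse_sequence)
}

#' Synthetic mean-rating curve from a known entropy model
#'
#' Generates a rating curve whose shape is exactly the model curve of a known
#' configuration, min-max rescaled to the rating scale, plus optional i.i.d.
#' Gaussian noise (in rating units), clipped back to the scale. This is the
#' ground-truth generator for parameter-recovery experiments: with
#' `noise_sd = 0` a fitter should recover the generating parameters.
#'
#' @param config The generating [entropy_config()].
#' @param pa_levels P(A) levels (default 0.1, ..., 1.0).
#' @param noise_sd Gaussian noise standard deviation in rating units
#'   (default 0).
#' @param rating_scale_max Rating-scale maximum (default 10).
#' @param seed Optional RNG seed (only consumed when `noise_sd > 0`).
#' @param n_first,n_second Stimulus design symbol counts.
#' @return A [target_curve()].
#' @export
synth_rating_curve <- function(config, pa_levels = seq(0.1, 1, by = 0.1),
                               noise_sd = 0, rating_scale_max = 10,
                               seed = NULL, n_first = 11, n_second = 10) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  mc <- model_curve(config, pa_levels, n_first = n_first, n_second = n_second)
  rating <- .minmax(mc) * rating_scale_max
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    rating <- rating + stats::rnorm(length(rating), 0, noise_sd)
    rating <- pmin(pmax(rating, 0), rating_scale_max)
  }
  target_curve(pa_levels, rating, rating_scale_max = rating_scale_max)
}

#' Write sequences to a plain-text file
#'
#' One sequence per line, optionally preceded by `#` comment lines embedding
#' provenance (seed, design).
#'
#' @param sequences List of `binseq` objects (or an `fk_stimuli`).
#' @param path Output path (or `""` for stdout).
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(sequences, path, header = NULL) {
  if (inherits(sequences, "fk_stimuli")) sequences <- sequences$sequences
  lines <- vapply(sequences, as.character, character(1))
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, if (nzchar(path)) path else stdout())
  invisible(path)
}
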