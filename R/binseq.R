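# Canonical digram category order used throughout the package.
DIGRAMS <- c("OO", "OX", "XO", "XX")

new_binseq <- function(symbols) {
  structure(list(symbols = symbols, n = length(symbols)), class = "binseq")
}

#' Parse a binary sequence
#'
#' Reads a two-symbol string into a `binseq` object. Symbols are stored on the
#' canonical X/O alphabet; an alternative alphabet (e.g. `c("H","T")`) is
#' mapped positionally onto `c("X","O")`. Whitespace is stripped and input is
#' uppercased before validation, so `"xxo xo"` parses as `"XXOXO"`.
#'
#' @param text Single character string over the two alphabet symbols.
#' @param alphabet Ordered pair of distinct single-character symbol labels;
#'   the first maps to X, the second to O. Default `c("X","O")`.
#' @return A `binseq` object with elements `symbols` (character vector over
#'   X/O) and `n` (sequence length).
#' @examples
#' s <- parse_sequence("XXXOOOXOXO")
#' n_runs(s)           # 6
#' prob_alternation(s) # 5/9
#' @export
parse_sequence <- function(text, alphabet = c("X", "O")) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single character string")
  alphabet <- toupper(as.character(alphabet))
  if (length(alphabet) != 2L || alphabet[1] == alphabet[2] ||
      any(nchar(alphabet) != 1L))
    stop("'alphabet' must be two distinct single-character symbols")
  chars <- strsplit(gsub("[[:space:]]", "", toupper(text)), "", fixed = FALSE)[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  bad <- which(!(chars %in% alphabet))
  if (length(bad))
    stop(sprintf("foreign symbol '%s' at position %d", chars[bad[1]], bad[1]))
  new_binseq(c("X", "O")[match(chars, alphabet)])
}

#' Coerce to a binary sequence
#'
#' @param x A `binseq` object or a character string to parse on the default
#'   X/O alphabet.
#' @param ... Passed on to [parse_sequence()].
#' @return A `binseq` object.
#' @export
as_binseq <- function(x, ...) {
  if (inherits(x, "binseq")) return(x)
  parse_sequence(x, ...)
}

#' @export
as.character.binseq <- function(x, ...) paste(x$symbols, collapse = "")

#' @export
print.binseq <- function(x, ...) {
  cat(sprintf("<binseq n=%d r=%d> %s\n", x$n, n_runs(x), as.character(x)))
  invisible(x)
}

#' Number of runs
#'
#' A run is a maximal unbroken block of one symbol; a length-n sequence has
#' between 1 and n runs.
#'
#' @param seq A `binseq` (or string coercible to one).
#' @return Integer run count.
#' @export
n_runs <- function(seq) {
  seq <- as_binseq(seq)
  s <- seq$symbols
  if (seq$n == 1L) return(1L)
  sum(s[-1] != s[-seq$n]) + 1L
}

#' Probability of alternation
#'
#' The alternation rate P(A) = (r - 1)/(n - 1), where r is the number of runs:
#' the fraction of adjacent symbol pairs that differ. P(A) = 0 for a constant
#' sequence and 1 for a strictly alternating one.
#'
#' @param seq A `binseq` (or string).
#' @return Numeric in \[0, 1\].
#' @export
prob_alternation <- function(seq) {
  seq <- as_binseq(seq)
  if (seq$n < 2L) stop("probability of alternation undefined for length < 2")
  (n_runs(seq) - 1) / (seq$n - 1)
}

#' Digram counts
#'
#' Counts the n - 1 overlapping ordered symbol pairs (digrams) of a sequence,
#' read left to right with no wraparound. The counts satisfy
#' `c_OX + c_XO = r - 1` (alternating digrams mark run boundaries) and
#' `|c_XO - c_OX| <= 1`.
#'
#' @param seq A `binseq` (or string) of length >= 2.
#' @return Named integer vector over the categories `OO, OX, XO, XX`.
#' @export
digram_counts <- function(seq) {
  seq <- as_binseq(seq)
  if (seq$n < 2L) stop("digram counts undefined for length < 2")
  s <- seq$symbols
  pairs <- paste0(s[-seq$n], s[-1])
  out <- vapply(DIGRAMS, function(d) sum(pairs == d), integer(1))
  names(out) <- DIGRAMS
  out
}

#' First-order symbol distribution
#'
#' Relative frequencies of the two symbols, in (X, O) order.
#'
#' @param seq A `binseq` (or string).
#' @return Named probability vector `c(X = ., O = .)` summing to 1.
#' @export
first_order_dist <- function(seq) {
  seq <- as_binseq(seq)
  nx <- sum(seq$symbols == "X")
  c(X = nx / seq$n, O = (seq$n - nx) / seq$n)
}

#' Digram distribution
#'
#' Digram counts normalized by n - 1.
#'
#' @param seq A `binseq` (or string) of length >= 2.
#' @return Named probability vector over `OO, OX, XO, XX` summing to 1.
#' @export
digram_dist <- function(seq) {
  seq <- as_binseq(seq)
  digram_counts(seq) / (seq$n - 1)
}

#' Expected digram distribution at a probability-of-alternation level
#'
#' Analytic stimulus-level digram distribution for a design with alternation
#' rate `pa`: the alternating mass `pa` is split equally between XO and OX and
#' the uniform mass `1 - pa` equally between XX and OO. Within any single
#' linear sequence `|c_XO - c_OX| <= 1`, so the symmetric split is the natural
#' idealization of the design.
#'
#' @param pa Probability of alternation in \[0, 1\].
#' @param n_first,n_second Symbol counts of the design (defaults 11 and 10,
#'   the 21-symbol rating-stimulus design); used for validation of the design
#'   size only.
#' @return Named probability vector over `OO, OX, XO, XX`.
#' @examples
#' expected_digram_dist(0.7)  # c(OO=.15, OX=.35, XO=.35, XX=.15)
#' @export
expected_digram_dist <- function(pa, n_first = 11, n_second = 10) {
  if (!is.numeric(pa) || length(pa) != 1L || is.na(pa) || pa < 0 || pa > 1)
    stop("'pa' must be a single number in [0, 1]")
  if (n_first + n_second < 2) stop("design must have at least 2 symbols")
  c(OO = (1 - pa) / 2, OX = pa / 2, XO = pa / 2, XX = (1 - pa) / 2)
}

#' Symbol complement of a sequence
#'
#' @param seq A `binseq` (or string).
#' @return The `binseq` with every X swapped for O and vice versa.
#' @export
complement <- function(seq) {
  seq <- as_binseq(seq)
  new_binseq(ifelse(seq$symbols == "X", "O", "X"))
}

#' Canonical form under complementation
#'
#' Two sequences that differ only by swapping the symbol labels (e.g.
#' `TTTTTTTT` vs `HHHHHHHH`) describe the same configuration. The canonical
#' representative is the lexicographically smaller of a sequence and its
#' complement, with O ordered before X. Idempotent, and invariant under
#' complementation; the 256 length-8 strings collapse to 128 canonical forms.
#'
#' @param seq A `binseq` (or string).
#' @return The canonical `binseq`.
#' @export
canonicalize <- function(seq) {
  seq <- as_binseq(seq)
  comp <- complement(seq)
  a <- seq$symbols == "X"   # O (FALSE) sorts before X (TRUE)
  b <- comp$symbols == "X"
  d <- which(a != b)
  if (length(d) && b[d[1]] < a[d[1]]) comp else seq
}

#' Read sequences from a plain-text file
#'
#' One sequence per line; blank lines and lines starting with `#` are skipped.
#'
#' @param path File path.
#' @param alphabet Passed to [parse_sequence()].
#' @return List of `binseq` objects.
#' @export
read_sequences <- function(path, alphabet = c("X", "O")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no sequences found in ", path)
  lapply(lines, parse_sequence, alphabet = alphabet)
}
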