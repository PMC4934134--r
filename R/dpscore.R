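# Cache of segmentation-enumeration structures for the brute-force oracle,
# keyed by sequence length.
.dp_cache <- new.env(parent = emptyenv())

# Cost of segment s[i..j] given the cumulative-alternation vector `alt`
# (alt[k] = number of unequal adjacent pairs within s[1..k]):
#   uniform (constant) block  -> 1
#   alternating block, len>=3 -> 2
#   anything else             -> NA (not a valid segment)
# Length-2 non-constant blocks are excluded: admitting them would cost 2,
# exactly the same as splitting into two runs, and create pure ties.
.seg_cost <- function(alt, i, j) {
  ch <- alt[j] - alt[i]
  len <- j - i + 1L
  if (ch == 0L) 1L
  else if (ch == len - 1L && len >= 3L) 2L
  else NA_integer_
}

#' Difficulty Predictor (DP) score
#'
#' The DP score of a binary sequence is the number of uniform runs plus twice
#' the number of alternating subsequences, minimized over all ways of cutting
#' the sequence into contiguous blocks that are each either constant
#' ("uniform", cost 1) or strictly alternating with length at least 3
#' (cost 2). For example `XXXOOOXOXO` splits into `XXX | OOO | XOXO` for a
#' score of 4. Computed by an O(n^2) dynamic program over cut points. Among
#' minimal partitions, ties are broken toward fewer alternating blocks, then
#' fewer blocks overall; the score itself is unaffected by the tie-break.
#'
#' @param seq A `binseq` (or string), length >= 1.
#' @return List with `score` (integer) and `segments` (data.frame with
#'   columns `start`, `end`, `kind`).
#' @examples
#' dp_score("XXXOOOXOXO")$score  # 4
#' @export
dp_score <- function(seq) {
  seq <- as_binseq(seq)
  s <- seq$symbols
  n <- seq$n
  alt <- c(0L, cumsum(s[-1] != s[-n]))
  # best[j+1] = (cost, #alternating, #segments) of optimal partition of s[1..j]
  INF <- .Machine$integer.max %/% 4L
  cost <- c(0L, rep(INF, n))
  nalt <- c(0L, rep(INF, n))
  nseg <- c(0L, rep(INF, n))
  back <- integer(n + 1L)
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      sc <- .seg_cost(alt, i, j)
      if (is.na(sc)) next
      cc <- cost[i] + sc
      ca <- nalt[i] + (sc == 2L)
      cs <- nseg[i] + 1L
      jj <- j + 1L
      if (cc < cost[jj] ||
          (cc == cost[jj] && (ca < nalt[jj] ||
                              (ca == nalt[jj] && cs < nseg[jj])))) {
        cost[jj] <- cc; nalt[jj] <- ca; nseg[jj] <- cs; back[jj] <- i
      }
    }
  }
  # reconstruct segments
  segs <- list()
  j <- n
  while (j > 0L) {
    i <- back[j + 1L]
    segs[[length(segs) + 1L]] <- data.frame(
      start = i, end = j,
      kind = if (.seg_cost(alt, i, j) == 1L) "uniform" else "alternating",
      stringsAsFactors = FALSE)
    j <- i - 1L
  }
  segments <- do.call(rbind, rev(segs))
  rownames(segments) <- NULL
  list(score = as.integer(cost[n + 1L]), segments = segments)
}

# Incidence structure for exhaustive segmentation: for length n there are
# 2^(n-1) cut-point subsets; A[mask, pair] = 1 iff the segmentation for that
# mask contains segment (i, j) indexed by `pairs`. Built once per n.
.bf_structure <- function(n) {
  key <- as.character(n)
  cached <- get0(key, envir = .dp_cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  colnames(pairs) <- c("i", "j")
  pid <- matrix(NA_integer_, n, n)
  pid[pairs] <- seq_len(nrow(pairs))
  n_masks <- 2L^(n - 1L)
  A <- matrix(0, n_masks, nrow(pairs))
  bits <- if (n >= 2L) bitwShiftL(1L, 0:(n - 2L)) else integer(0)
  for (m in seq_len(n_masks) - 1L) {
    cuts <- if (n >= 2L) which(bitwAnd(m, bits) != 0L) else integer(0)
    bounds <- c(0L, cuts, n)
    starts <- bounds[-length(bounds)] + 1L
    ends <- bounds[-1]
    A[m + 1L, pid[cbind(starts, ends)]] <- 1
  }
  res <- list(A = A, pairs = pairs)
  assign(key, res, envir = .dp_cache)
  res
}

#' Exhaustive Difficulty Predictor (test oracle)
#'
#' Enumerates every one of the 2^(n-1) cut-point subsets, discards
#' segmentations containing an invalid block, and returns the minimum cost
#' under the same cost rules as [dp_score()]. Independent of the dynamic
#' program; intended as a correctness oracle, hence refused for n > 16.
#'
#' @param seq A `binseq` (or string), length <= 16.
#' @return Integer minimal score.
#' @export
dp_bruteforce <- function(seq) {
  seq <- as_binseq(seq)
  n <- seq$n
  if (n > 16L) stop("exhaustive oracle refuses sequences longer than 16")
  if (n == 1L) return(1L)
  s <- seq$symbols
  alt <- c(0L, cumsum(s[-1] != s[-n]))
  st <- .bf_structure(n)
  i <- st$pairs[, "i"]; j <- st$pairs[, "j"]
  ch <- alt[j] - alt[i]
  len <- j - i + 1L
  BIG <- 1e6
  segcost <- ifelse(ch == 0L, 1,
                    ifelse(ch == len - 1L & len >= 3L, 2, BIG))
  as.integer(min(st$A %*% segcost))
}
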