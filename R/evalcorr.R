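#' Rating table
#'
#' Pairs of (sequence, observed value) for the validation stage: the observed
#' value is typically the proportion of raters classifying the sequence as
#' random (in \[0, 1\]) or a mean rating. Sequences must be unique after
#' canonicalization (a sequence and its complement describe the same
#' configuration).
#'
#' @param sequence Character vector of sequences (or list of `binseq`).
#' @param observed Numeric vector of observed values, same length, finite.
#' @return data.frame of class `rating_table` with columns `sequence`
#'   (string) and `observed`.
#' @export
rating_table <- function(sequence, observed) {
  if (is.list(sequence))
    sequence <- vapply(sequence, function(s) as.character(as_binseq(s)),
                       character(1))
  sequence <- as.character(sequence)
  if (length(sequence) != length(observed) || !length(sequence))
    stop("'sequence' and 'observed' must be non-empty and of equal length")
  if (!is.numeric(observed) || any(!is.finite(observed)))
    stop("'observed' must be finite numeric")
  canon <- vapply(sequence,
                  function(s) as.character(canonicalize(parse_sequence(s))),
                  character(1))
  if (anyDuplicated(canon))
    stop("duplicate sequences after canonicalization: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "))
  structure(data.frame(sequence = sequence, observed = observed,
                       stringsAsFactors = FALSE),
            class = c("rating_table", "data.frame"))
}

#' Read a rating table from CSV
#'
#' Expects columns `sequence` and `observed`; `#` lines are ignored.
#'
#' @param path CSV file path.
#' @return A [rating_table()].
#' @export
read_rating_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(sequence = "character"))
  if (!all(c("sequence", "observed") %in% names(df)))
    stop("rating table CSV must have columns 'sequence' and 'observed'")
  rating_table(df$sequence, df$observed)
}

#' Score a rating table with configured measures
#'
#' Computes one score column per entropy configuration (via [second_order()])
#' and optionally the Difficulty Predictor, aligned with the input rows.
#' Sequences too short for a measure (length < 2 for second-order entropy)
#' get `NA` in that column and are excluded pairwise from its correlation.
#'
#' @param table A [rating_table()].
#' @param configs A single [entropy_config()] or a list of them; list names
#'   become column names (unnamed entries are named after their family).
#' @param include_dp Add a `dp` column with [dp_score()] values
#'   (default TRUE).
#' @param include_pa Add a `pa` column with [prob_alternation()] values
#'   (default FALSE).
#' @return data.frame with `sequence`, `observed`, and one column per
#'   measure.
#' @export
score_table <- function(table, configs = list(), include_dp = TRUE,
                        include_pa = FALSE) {
  if (!inherits(table, "rating_table"))
    table <- rating_table(table$sequence, table$observed)
  if (inherits(configs, "entropy_config")) configs <- list(configs)
  if (length(configs)) {
    nm <- names(configs)
    if (is.null(nm)) nm <- rep("", length(configs))
    fam <- vapply(configs, `[[`, character(1), "family")
    nm[!nzchar(nm)] <- fam[!nzchar(nm)]
    names(configs) <- make.unique(nm)
  }
  seqs <- lapply(table$sequence, parse_sequence)
  out <- data.frame(sequence = table$sequence, observed = table$observed,
                    stringsAsFactors = FALSE)
  if (include_pa)
    out$pa <- vapply(seqs, function(s)
      if (s$n >= 2) prob_alternation(s) else NA_real_, numeric(1))
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    out[[nm]] <- vapply(seqs, function(s)
      if (s$n >= 2) second_order(s, cfg) else NA_real_, numeric(1))
  }
  if (include_dp)
    out$dp <- vapply(seqs, function(s) dp_score(s)$score, numeric(1))
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, each with non-zero
#'   variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("'x' and 'y' must have equal length >= 3")
  if (anyNA(x) || anyNA(y)) stop("correlation inputs must not contain NA")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Correlate measure scores with observed ratings
#'
#' The validation protocol: score every sequence with each configured measure
#' and report its Pearson correlation with the observed values. Rows with an
#' undefined score are dropped pairwise per measure (with the used row count
#' reported).
#'
#' @inheritParams score_table
#' @return data.frame with columns `measure`, `r`, `n_used`.
#' @export
correlation_report <- function(table, configs = list(), include_dp = TRUE) {
  scores <- score_table(table, configs, include_dp = include_dp)
  cols <- setdiff(names(scores), c("sequence", "observed"))
  rows <- lapply(cols, function(cl) {
    ok <- !is.na(scores[[cl]])
    data.frame(measure = cl,
               r = pearson_r(scores[[cl]][ok], scores$observed[ok]),
               n_used = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
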