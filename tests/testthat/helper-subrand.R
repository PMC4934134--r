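# All binary strings of length n as character strings over X/O.
all_strings <- function(n, syms = c("O", "X")) {
  vapply(0:(2^n - 1), function(m) {
    bits <- bitwAnd(bitwShiftR(m, 0:(n - 1)), 1L)
    paste(syms[bits + 1L], collapse = "")
  }, character(1))
}

# Random string of length n under the current RNG.
rand_string <- function(n) paste(sample(c("X", "O"), n, replace = TRUE),
                                 collapse = "")

# Random probability vector over k categories (Dirichlet(1) via exponentials).
rand_dist <- function(k) {
  e <- stats::rexp(k)
  e / sum(e)
}

table1_weights <- c(OO = 0.33, OX = 0.69, XO = 0.68, XX = 0.30)
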