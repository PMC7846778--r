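# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)

# run code with a fixed RNG seed, restoring caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_bad("'seed' must be a single number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop_bad("'", name, "' must lie in [0, 1]")
  invisible(x)
}

# two-sided / one-sided Fisher's exact p for a 2x2 table, vectorised over rows.
# Wraps the conditional hypergeometric test; a is the top-left cell of
# matrix(c(a, b, c, d), 2, 2) with margins (a+b), (c+d) fixed.
fisher_p_2x2 <- function(a, b, c, d, alternative = "two.sided") {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    tab <- matrix(c(a[i], b[i], c[i], d[i]), nrow = 2L)
    if (any(tab < 0) || any(tab != round(tab)))
      stop_bad("contingency counts must be non-negative integers")
    out[i] <- fisher.test(tab, alternative = alternative)$p.value
  }
  out
}

odds_ratio_2x2 <- function(a, b, c, d) {
  (a * d) / (b * c)
}
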