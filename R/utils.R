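# internal helpers shared across the package

# 97.5% normal quantile used for all confidence intervals
Z975 <- 1.959964

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never perturbs user RNG streams.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# two-sided normal p-value, kept strictly inside (0, 1]
two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

# fixed 6-significant-digit formatting for report files (byte-stable output)
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
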