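# internal helpers: error signalling, seed handling, small numeric utilities

stopf <- function(fmt, ..., class = "rsfnirs_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a finite number in [%g, %g]", name, lower, upper,
          class = "rsfnirs_invalid_parameter")
  invisible(x)
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators stay pure functions of their arguments.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("`seed` must be a single finite number", class = "rsfnirs_invalid_parameter")
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

# Derive a stream seed from a master seed and integer offsets, kept inside
# the 32-bit signed range required by set.seed().
derive_seed <- function(master, ...) {
  offs <- c(...)
  x <- as.double(master) %% 2147483647
  for (o in offs) x <- (x * 48271 + as.double(o) + 1) %% 2147483647
  as.integer(x)
}

# trapezoid-rule mean value of y over the grid x (AUC normalized by the
# integration width, so a constant metric keeps its value)
trapezoid_mean <- function(x, y) {
  keep <- is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0L) return(NA_real_)
  if (length(x) == 1L) return(y)
  o <- order(x); x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) / (max(x) - min(x))
}

# round half away from zero to `digits` decimals (print convention for
# percentage tables; base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

upper_tri_pairs <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  cbind(i = i, j = j)
}
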