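# internal helpers shared across modules

# ratio with a guarded denominator: |den| below eps yields 0 rather than Inf/NaN
safe_ratio <- function(num, den, eps = 1e-12) {
  out <- num / den
  out[!is.finite(out) | abs(den) < eps] <- 0
  out
}

# correlation that maps undefined values (zero-variance input) to 0
safe_cor <- function(x, y = NULL) {
  out <- suppressWarnings(stats::cor(x, y))
  out[!is.finite(out)] <- 0
  out
}

# least-squares slope of y on x (vectorised over columns of y)
ls_slope <- function(x, y) {
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) {
    return(if (is.matrix(y)) rep(0, ncol(y)) else 0)
  }
  if (is.matrix(y)) as.numeric(crossprod(xc, y)) / denom else sum(xc * y) / denom
}

# lag-k autocorrelation per column, 0 for constant columns
col_acf <- function(m, lag) {
  n <- nrow(m)
  if (n <= lag + 1) return(rep(0, ncol(m)))
  vapply(seq_len(ncol(m)), function(j) {
    safe_cor(m[seq_len(n - lag), j], m[(lag + 1):n, j])
  }, numeric(1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
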