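# Shared fixtures: all built in code at test time.

# Small cohort configuration used where the asserted property does not
# depend on the series length or cohort size.
tiny_config <- function(...) {
  cohort_config(n_sg = 2, n_cg = 2, t_samples = 24, n_measurements = 3, ...)
}

# A feature table wrapped around an arbitrary values matrix, for GA tests
# on synthetic tables with known structure.
make_table <- function(values, target) {
  p <- ncol(values)
  structure(list(
    values = values,
    feature_names = sprintf("x%04d", seq_len(p)),
    row_index = data.frame(patient_id = sprintf("r%03d", seq_len(nrow(values))),
                           day = 1, stringsAsFactors = FALSE),
    targets = data.frame(target = as.numeric(target)),
    granularity = "patient_day", standardized = FALSE),
    class = "acg_feature_table")
}

# Matrix with a prescribed explained-variance profile, built by SVD
# composition: U diag(s) V' with orthonormal U spanning mean-zero
# vectors (so column centering is the identity) and s_k^2 proportional
# to the requested fractions. Optional per-column offsets exercise the
# centering step.
svd_composed_matrix <- function(t_samples, fractions, offsets = NULL) {
  nf <- length(fractions)
  stopifnot(t_samples > nf + 1)
  a <- matrix(rnorm(t_samples * nf), t_samples, nf)
  a <- sweep(a, 2, colMeans(a), "-")        # columns orthogonal to the constant
  u <- qr.Q(qr(a))
  v <- qr.Q(qr(matrix(rnorm(nf * nf), nf, nf)))
  s <- sqrt(fractions * 100)                 # arbitrary total variance
  x <- u %*% diag(s, nf) %*% t(v)
  if (!is.null(offsets)) x <- sweep(x, 2, offsets, "+")
  x
}

# Closed-form oracle for the cumulative-count definition: smallest k
# whose cumulative variance fraction reaches the threshold.
cumcount_oracle <- function(fractions, threshold) {
  fr <- sort(fractions, decreasing = TRUE)
  as.integer(which(cumsum(fr) >= threshold - 1e-12)[1])
}

# All feature subsets of size 1..max_size out of p features.
all_subsets <- function(p, max_size) {
  out <- as.list(seq_len(p))
  for (k in seq(2, max_size)) {
    if (k > p) break
    out <- c(out, utils::combn(p, k, simplify = FALSE))
  }
  out
}
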