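# Small in-code fixtures shared across test files.

# Wrap a space x time x subject array as a grayordinate dataset; the last
# `n_sub` rows are "subcortical", laid out on an n_sub x 1 x 1 grid.
array_dataset <- function(x, n_sub = max(1L, nrow(x) %/% 5L)) {
  v <- dim(x)[1]
  s <- dim(x)[3]
  ci <- seq_len(v - n_sub)
  si <- (v - n_sub + 1):v
  grayordinate_dataset(
    subjects = lapply(seq_len(s), function(i) x[, , i]),
    cortical_index = ci, subcortical_index = si,
    subcortical_grid_coords = cbind(seq_len(n_sub), 1L, 1L),
    grid_dims = c(n_sub, 1L, 1L)
  )
}

# Random row-normalized matrix.
rnorm_mat <- function(v, t_len) {
  normalize_timeseries(matrix(rnorm(v * t_len), v, t_len))
}

# Exact CP tensor from factor matrices and magnitudes.
cp_array <- function(a, b, c_, lambda) {
  out <- array(0, c(nrow(a), nrow(b), nrow(c_)))
  for (r in seq_along(lambda)) {
    out <- out + lambda[r] * array(outer(outer(a[, r], b[, r]), c_[, r]),
                                   dim(out))
  }
  out
}

# Columnwise-orthonormal random matrix.
rand_orthonormal <- function(n, k) qr.Q(qr(matrix(rnorm(n * k), n, k)))

# Ground-truth-like object for match_components from plain factor matrices.
fake_truth <- function(a, b, c_, lambda) {
  structure(
    list(spatial_maps = a, temporal_courses = b, subject_loadings = c_,
         magnitudes = lambda),
    class = "synthetic_ground_truth"
  )
}

# Fast optimizer settings for small unit-test problems.
test_opts <- function(max_iter = 600, ...) {
  nascar_opts(tol = 1e-6, patience = 15, decay = 0.3, min_step_frac = 1e-4,
              max_iter = max_iter, ...)
}

# A tiny two-ROI atlas on a small grid: "region" sphere containing "roi".
nested_atlas <- function() {
  generate_toy_atlas(
    c(7L, 7L, 7L),
    list(
      list(name = "region", center = c(4, 4, 4), radius = 2.5),
      list(name = "roi", center = c(4, 4, 4), radius = 1)
    )
  )
}
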