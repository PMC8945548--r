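#' Random orthogonal matrix from the Haar measure
#'
#' Draws a uniformly distributed (Haar) orthogonal matrix by QR decomposition
#' of a standard Gaussian matrix, with the column signs fixed so the diagonal
#' of R is positive (this makes the map from Gaussian draws to orthogonal
#' matrices unique and the distribution exactly Haar).
#'
#' @param n Matrix dimension.
#' @return An \code{n} x \code{n} orthogonal matrix.
#' @export
rorth <- function(n) {
  qd <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qd)
  d <- sign(diag(qr.R(qd)))
  d[d == 0] <- 1
  q * rep(d, each = n)
}

# Fisher r-to-z and back; r is clipped away from +/-1 by callers.
fisher_z <- function(r) atanh(r)
inv_fisher_z <- function(z) tanh(z)

#' @keywords internal
is_orthogonal <- function(o, tol = 1e-8) {
  max(abs(crossprod(o) - diag(ncol(o)))) < tol
}

# Lexicographic ordering of matrix rows, extending to further columns only
# while ties remain. The resulting permutation depends on row *content* only,
# so any row permutation of the input maps to the same ordered matrix. This is
# what makes the tensor decomposition exactly invariant to shuffling of the
# space axis: computations run in this canonical order.
canonical_row_order <- function(x) {
  keys <- list(x[, 1L])
  j <- 1L
  repeat {
    ord <- do.call(order, keys)
    km <- do.call(cbind, keys)
    if (!anyDuplicated(km[ord, , drop = FALSE]) || j >= ncol(x)) {
      return(ord)
    }
    j <- j + 1L
    keys[[length(keys) + 1L]] <- x[, j]
  }
}

# Rows are checked, not re-derived: callers that require normalized input use
# this to fail fast with a useful message. Orthogonal temporal transforms
# preserve row norms but not row means, so synchronized data is only
# guaranteed unit-norm; `require_centered` is for operations that genuinely
# need zero-mean rows.
check_normalized <- function(x, tol = 1e-6, what = "matrix",
                             require_centered = FALSE) {
  nr <- max(abs(sqrt(rowSums(x^2)) - 1))
  if (nr > tol) {
    stop(sprintf(
      "%s is not row-normalized (max |norm - 1| = %.2e); run normalize_timeseries() first",
      what, nr
    ), call. = FALSE)
  }
  if (require_centered) {
    mu <- max(abs(rowMeans(x)))
    if (mu > tol) {
      stop(sprintf(
        "%s rows are not zero mean (max |mean| = %.2e); run normalize_timeseries() first",
        what, mu
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# MD5 of an R object via a temporary serialization; used for config hashes in
# run records.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}
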