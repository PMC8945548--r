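#' Center and scale time series to zero mean and unit norm
#'
#' Every row (one vertex/voxel time series) is centered to mean zero and
#' scaled to unit Euclidean norm. This is the normalization required before
#' temporal synchronization: it turns inner products between homologous rows
#' into Pearson correlations.
#'
#' @param data Numeric space x time matrix with at least two time points.
#' @return Matrix of the same shape with zero-mean, unit-norm rows.
#' @export
normalize_timeseries <- function(data) {
  stopifnot(is.matrix(data), ncol(data) >= 2L)
  ctr <- data - rowMeans(data)
  nrm <- sqrt(rowSums(ctr^2))
  dead <- which(nrm <= .Machine$double.eps * ncol(data) * 16)
  if (length(dead) > 0L) {
    stop(sprintf(
      "constant (dead) time series at row(s) %s: cannot normalize",
      paste(utils::head(dead, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  ctr / nrm
}

#' Temporal synchronization of one subject to a reference
#'
#' Finds the temporal orthogonal transform \code{O} minimizing
#' \code{||reference - moving \%*\% O||_F} over all orthogonal matrices, the
#' classical orthogonal Procrustes problem. With \code{G = t(moving) \%*\%
#' reference} and SVD \code{G = U D V'}, the minimizer is \code{O = U V'}.
#' After transformation, time series in homologous rows of the two matrices
#' are maximally correlated in the summed sense, while all within-subject
#' correlations are untouched (right-multiplication by an orthogonal matrix
#' preserves inner products between rows).
#'
#' @param reference,moving Row-normalized space x time matrices of identical
#'   dimension (see \code{\link{normalize_timeseries}}).
#' @return List with elements \code{transform} (orthogonal T x T matrix) and
#'   \code{synced} (\code{moving \%*\% transform}).
#' @export
pairwise_brainsync <- function(reference, moving) {
  if (!all(dim(reference) == dim(moving))) {
    stop("reference and moving must have identical dimensions")
  }
  check_normalized(reference, what = "reference")
  check_normalized(moving, what = "moving")
  o <- procrustes_transform(reference, moving)
  list(transform = o, synced = moving %*% o)
}

# SVD core shared by the pairwise and group algorithms (reference need not be
# row-normalized here; only the public entry point enforces that).
procrustes_transform <- function(reference, moving) {
  g <- crossprod(moving, reference)
  sv <- svd(g)
  sv$u %*% t(sv$v)
}

#' Group temporal synchronization to a virtual reference subject
#'
#' Builds one "virtual reference subject" jointly with per-subject temporal
#' orthogonal transforms by alternating minimization of
#' \deqn{\sum_s || X_s O_s - ref ||_F^2}
#' subject to every row of the reference having unit norm: each iteration
#' (i) aligns every subject to the current reference with
#' \code{\link{pairwise_brainsync}} and (ii) replaces the reference by the
#' row-renormalized mean of the synced subjects (which is the exact minimizer
#' of the objective over unit-norm reference rows). Both half-steps decrease
#' the objective, so the logged objective values are non-increasing.
#'
#' The reference is initialized from the most "central" subject: the one with
#' the largest summed squared homologous-row correlation to all others. This
#' avoids biasing the group solution toward an arbitrary first subject.
#'
#' @param dataset A \code{\link{grayordinate_dataset}} with row-normalized
#'   subjects (at least two).
#' @param tol Convergence tolerance on the Frobenius change of the reference.
#' @param max_iter Maximum number of alternating iterations. Non-convergence
#'   is reported via \code{converged = FALSE}, not an error.
#' @return An object of class \code{sync_result}: list with
#'   \code{transforms} (per-subject orthogonal matrices), \code{synced}
#'   (dataset of transformed subjects), \code{reference},
#'   \code{n_iterations}, \code{converged} and \code{objective} (logged
#'   per-iteration values of the group objective).
#' @export
group_brainsync <- function(dataset, tol = 1e-6, max_iter = 20L) {
  stopifnot(inherits(dataset, "grayordinate_dataset"))
  xs <- dataset$subjects
  s <- length(xs)
  if (s < 2L) stop("group synchronization needs at least 2 subjects")
  for (i in seq_len(s)) check_normalized(xs[[i]], what = sprintf("subject %d", i))

  # Centrality: sum over other subjects of the squared homologous-row
  # correlations (rows are unit norm, so the row dot product is the
  # correlation).
  centr <- numeric(s)
  for (i in seq_len(s - 1L)) {
    for (j in seq(i + 1L, s)) {
      cij <- sum(rowSums(xs[[i]] * xs[[j]])^2)
      centr[i] <- centr[i] + cij
      centr[j] <- centr[j] + cij
    }
  }
  ref <- xs[[which.max(centr)]]

  transforms <- vector("list", s)
  synced <- xs
  objective <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(s)) {
      transforms[[i]] <- procrustes_transform(ref, xs[[i]])
      synced[[i]] <- xs[[i]] %*% transforms[[i]]
    }
    m <- Reduce(`+`, synced) / s
    nrm <- sqrt(rowSums(m^2))
    keep <- nrm > 1e-12
    new_ref <- ref
    new_ref[keep, ] <- m[keep, , drop = FALSE] / nrm[keep]
    objective <- c(objective, sum(vapply(
      synced, function(y) sum((y - new_ref)^2), numeric(1)
    )))
    delta <- sqrt(sum((new_ref - ref)^2))
    ref <- new_ref
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  out <- dataset
  out$subjects <- synced
  structure(
    list(
      transforms = transforms,
      synced = out,
      reference = ref,
      n_iterations = it,
      converged = converged,
      objective = objective
    ),
    class = "sync_result"
  )
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf(
    "sync_result: %d subjects, %d iteration(s), converged = %s, final objective = %.6g\n",
    length(x$transforms), x$n_iterations, x$converged,
    utils::tail(x$objective, 1)
  ))
  invisible(x)
}

#' Check that synchronization preserved functional connectivity
#'
#' On normalized data (zero-mean, unit-norm rows) the full-window
#' correlation between two rows is their inner product, and inner products
#' are exactly invariant under right multiplication by an orthogonal
#' matrix. This utility recomputes both connectivity matrices — inner
#' products of rows scaled to unit norm — and returns the maximum absolute
#' elementwise deviation, which should be below about 1e-8 for any genuine
#' orthogonal synchronization.
#'
#' @param original,synced Space x time matrices before and after
#'   synchronization.
#' @return The maximum absolute difference between the two connectivity
#'   matrices.
#' @export
connectivity_preservation_check <- function(original, synced) {
  stopifnot(all(dim(original) == dim(synced)))
  conn <- function(x) {
    x <- x / sqrt(rowSums(x^2))
    tcrossprod(x)
  }
  max(abs(conn(original) - conn(synced)))
}
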