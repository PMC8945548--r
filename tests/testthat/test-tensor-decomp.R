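test_that("build_tensor stacks subjects along the third axis", {
  set.seed(21)
  x <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  ds <- array_dataset(x, n_sub = 1)
  tn <- build_tensor(ds, synced = TRUE)
  expect_equal(dim(tn$values), c(4L, 3L, 2L))
  expect_identical(tn$values[, , 1], ds$subjects[[1]])
  expect_identical(tn$values[, , 2], ds$subjects[[2]])

  # degenerate single subject
  ds1 <- ds
  ds1$subjects <- ds$subjects[1]
  ds1$subject_ids <- ds$subject_ids[1]
  expect_equal(dim(build_tensor(ds1, TRUE)$values), c(4L, 3L, 1L))

  # spot-check random triples
  x2 <- array(rnorm(20 * 15 * 6), c(20, 15, 6))
  ds2 <- array_dataset(x2)
  tn2 <- build_tensor(ds2, TRUE)
  for (k in 1:100) {
    i <- sample(20, 1); t_ <- sample(15, 1); s <- sample(6, 1)
    expect_identical(tn2$values[i, t_, s], ds2$subjects[[s]][i, t_])
  }
})

test_that("build_tensor refuses unsynchronized data", {
  ds <- array_dataset(array(rnorm(24), c(4, 3, 2)), n_sub = 1)
  expect_error(build_tensor(ds, synced = FALSE), "synchron")
})

test_that("exact rank-1 tensor is recovered to high precision", {
  set.seed(22)
  a <- rand_orthonormal(60, 1)
  b <- rand_orthonormal(40, 1)
  cc <- rand_orthonormal(8, 1)
  tn <- build_tensor(array_dataset(cp_array(a, b, cc, 5)), TRUE)
  d <- nascar_decompose(tn, 1, test_opts(), seed = 7)
  expect_lt(abs(d$lambda - 5) / 5, 0.01)
  expect_gt(abs(sum(d$components[[1]]$spatial * a)), 0.999)
  expect_gt(abs(sum(d$components[[1]]$temporal * b)), 0.999)
  expect_gt(abs(sum(d$components[[1]]$subject * cc)), 0.999)
  # unit norms, sign convention, ordering invariants
  cp <- d$components[[1]]
  expect_equal(sqrt(sum(cp$spatial^2)), 1, tolerance = 1e-8)
  expect_equal(sqrt(sum(cp$temporal^2)), 1, tolerance = 1e-8)
  expect_equal(sqrt(sum(cp$subject^2)), 1, tolerance = 1e-8)
  expect_gt(cp$spatial[which.max(abs(cp$spatial))], 0)
})

test_that("zero tensor gives all-zero magnitudes", {
  z <- array(0, c(20, 10, 4))
  d <- nascar_decompose(build_tensor(array_dataset(z), TRUE), 2,
                        test_opts(), seed = 1)
  expect_equal(d$lambda, c(0, 0))
})

test_that("noisy orthogonal rank-3 tensor is recovered", {
  set.seed(23)
  a <- rand_orthonormal(80, 3)
  b <- rand_orthonormal(50, 3)
  cc <- rand_orthonormal(10, 3)
  lam <- c(3, 2, 1)
  x <- cp_array(a, b, cc, lam)
  noise <- array(rnorm(length(x)), dim(x))
  x <- x + noise * sqrt(0.01 * sum(x^2) / sum(noise^2))
  d <- nascar_decompose(build_tensor(array_dataset(x), TRUE), 3,
                        test_opts(), seed = 3)
  m <- match_components(d, fake_truth(a, b, cc, lam))
  expect_true(all(m$spatial >= 0.99))
  expect_true(all(m$temporal >= 0.99))
  expect_true(all(m$subject >= 0.99))
  expect_true(all(abs(d$lambda[m$est_index] - lam) / lam <= 0.05))
  expect_true(all(diff(d$fit_history) <= 1e-8))
})

test_that("component matching resolves sign and permutation indeterminacy", {
  set.seed(24)
  a <- rand_orthonormal(30, 4)
  b <- rand_orthonormal(20, 4)
  cc <- rand_orthonormal(6, 4)
  lam <- c(4, 3, 2, 1)
  mk_decomp <- function(a, b, cc, lam) {
    comps <- lapply(seq_along(lam), function(r) {
      structure(list(magnitude = lam[r], spatial = a[, r], temporal = b[, r],
                     subject = cc[, r]), class = "network_component")
    })
    structure(list(components = comps, lambda = lam,
                   rank_requested = length(lam),
                   fit_history = numeric(0), seed = 1L),
              class = "cp_decomposition")
  }
  truth <- fake_truth(a, b, cc, lam)

  # exact: identity matching, congruence 1
  m <- match_components(mk_decomp(a, b, cc, lam), truth)
  expect_equal(m$est_index, 1:4)
  expect_equal(m$spatial, rep(1, 4), tolerance = 1e-12)

  # flip signs of component 2 in two modes: reconstruction unchanged
  a2 <- a; b2 <- b
  a2[, 2] <- -a2[, 2]; b2[, 2] <- -b2[, 2]
  m2 <- match_components(mk_decomp(a2, b2, cc, lam), truth)
  expect_equal(m2$spatial, rep(1, 4), tolerance = 1e-12)
  expect_equal(m2$sign[2], -1)

  # permuted order: greedy matching recovers the permutation and agrees
  # with the exhaustive assignment over all 4! permutations
  p <- c(3, 1, 4, 2)
  mp <- match_components(mk_decomp(a[, p], b[, p], cc[, p], lam[p]), truth)
  expect_equal(mp$est_index, order(p))
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  cosm <- function(u, v) abs(sum(u * v))
  score_of <- function(assign) {
    prod(vapply(1:4, function(j) {
      i <- assign[j]
      cosm(a[, p][, i], a[, j]) * cosm(b[, p][, i], b[, j]) *
        cosm(cc[, p][, i], cc[, j])
    }, numeric(1)))
  }
  best <- perms[which.max(apply(perms, 1, score_of)), ]
  expect_equal(mp$est_index, unname(best))
})

test_that("explained variance matches closed forms", {
  set.seed(25)
  a <- rand_orthonormal(30, 2)
  b <- rand_orthonormal(20, 2)
  cc <- rand_orthonormal(6, 2)
  x <- cp_array(a, b, cc, c(2, 1))
  tn <- build_tensor(array_dataset(x), TRUE)

  # exact decomposition of the noiseless tensor -> 1
  d2 <- nascar_decompose(tn, 2, test_opts(), seed = 5)
  expect_equal(explained_variance(d2, tn), 1, tolerance = 1e-6)

  # rank-1 truncation of the orthogonal lambda = (2, 1) tensor -> 4/5,
  # cross-checked by direct residual computation
  d1 <- nascar_decompose(tn, 1, test_opts(), seed = 5)
  ev <- explained_variance(d1, tn)
  expect_equal(ev, 4 / 5, tolerance = 1e-6)
  cp <- d1$components[[1]]
  xhat <- cp_array(cbind(cp$spatial), cbind(cp$temporal), cbind(cp$subject),
                   d1$lambda)
  expect_equal(ev, 1 - sum((x - xhat)^2) / sum(x^2), tolerance = 1e-10)

  # zero-component decomposition -> 0
  d0 <- structure(list(components = list(), lambda = numeric(0)),
                  class = "cp_decomposition")
  expect_equal(explained_variance(d0, tn), 0)

  # zero tensor -> error
  tz <- build_tensor(array_dataset(array(0, c(10, 8, 2))), TRUE)
  expect_error(explained_variance(d0, tz), "zero")
})

test_that("space-axis shuffling is exactly undone by inverse shuffling", {
  set.seed(26)
  v <- 50
  x <- array(rnorm(v * 30 * 5), c(v, 30, 5))
  d1 <- nascar_decompose(build_tensor(array_dataset(x), TRUE), 3,
                         test_opts(), seed = 9)
  p <- sample(v)
  d2 <- nascar_decompose(build_tensor(array_dataset(x[p, , ]), TRUE), 3,
                         test_opts(), seed = 9)
  expect_identical(d1$lambda, d2$lambda)
  for (r in 1:3) {
    unshuffled <- numeric(v)
    unshuffled[p] <- d2$components[[r]]$spatial
    expect_identical(d1$components[[r]]$spatial, unshuffled)
    expect_identical(d1$components[[r]]$temporal, d2$components[[r]]$temporal)
    expect_identical(d1$components[[r]]$subject, d2$components[[r]]$subject)
  }
})

test_that("decomposition rejects invalid inputs", {
  x <- array(rnorm(240), c(10, 8, 3))
  tn <- build_tensor(array_dataset(x), TRUE)
  expect_error(nascar_decompose(tn, 0), "rank")
  expect_error(nascar_decompose(tn, 24), "rank")
  tn$values[1, 1, 1] <- NaN
  expect_error(nascar_decompose(tn, 1), "NA")
})
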