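# minimal hand-built models for closed-form checks
toy_model <- function(center, shape, vars = paste0("v", seq_along(center))) {
  structure(list(taxon = "toy", center = setNames(center, vars),
                 shape = matrix(shape, length(center), length(center),
                                dimnames = list(vars, vars)),
                 inclusion = 0.9, variables = vars,
                 n_fit = NA_integer_, seed = NA_integer_,
                 log_volume = NA_real_),
            class = "ellipsoid_model")
}

test_that("1-D MVE matches the exhaustive shortest-interval oracle", {
  x <- matrix(as.numeric(0:9), ncol = 1)
  m <- fit_mve(x, inclusion = 0.9, seed = 1)
  half_width <- sqrt(m$shape[1, 1])
  inside <- sum(abs(x - m$center) <= half_width + 1e-9)
  expect_gte(inside, 9)
  # oracle: shortest interval covering any 9 of the 10 sorted values
  s <- sort(x[, 1])
  oracle <- min(s[9:10] - s[1:2]) / 2
  expect_lte(half_width, oracle + 1e-9)
  expect_equal(half_width, oracle, tolerance = 1e-9)
})

test_that("points on a circle at full inclusion recover the circumcircle", {
  th <- 2 * pi * (0:11) / 12
  r <- 2.5
  pts <- cbind(r * cos(th), r * sin(th)) + 1 # centred at (1, 1)
  m <- fit_mve(pts, inclusion = 1.0, seed = 1)
  expect_equal(unname(m$center), c(1, 1), tolerance = 1e-6)
  expect_equal(ellipsoid_distance(m, pts), rep(1, 12), tolerance = 1e-6)
})

test_that("small-instance MVE equals exhaustive subset enumeration", {
  for (seed in 1:4) {
    set.seed(seed)
    x <- matrix(rnorm(16), 8, 2)
    m <- fit_mve(x, inclusion = 0.9, seed = 1) # h = 8; C(8,3) = 56 subsets
    h <- 8
    # independent plain-R oracle over all 56 subsets
    best <- Inf
    for (sub in asplit(combn(8, 3), 2)) {
      S <- x[sub, , drop = FALSE]
      C <- cov(S)
      Ci <- tryCatch(solve(C), error = function(e) NULL)
      if (is.null(Ci) || det(C) <= 0) next
      ctr <- colMeans(S)
      d2 <- mahalanobis(x, ctr, C)
      s <- sort(d2)[h]
      best <- min(best, s^(2 / 2) * sqrt(det(C)))
    }
    expect_equal(sqrt(det(m$shape)), best, tolerance = 1e-9)
  }
})

test_that("MVE coverage and volume monotonicity in the inclusion level", {
  set.seed(77)
  x <- matrix(rnorm(80), 40, 2)
  vols <- vapply(c(0.75, 0.90, 1.0), function(incl) {
    m <- fit_mve(x, inclusion = incl, seed = 5)
    d <- ellipsoid_distance(m, x)
    expect_gte(sum(d <= 1 + 1e-9), ceiling(incl * 40))
    ellipsoid_volume(m)
  }, 0)
  expect_true(all(diff(vols) >= 0))
})

test_that("fitting is deterministic given the seed", {
  set.seed(1)
  x <- matrix(rnorm(300), ncol = 3)
  expect_identical(fit_mve(x, seed = 42), fit_mve(x, seed = 42))
})

test_that("suitability surfaces follow the closed-form Mahalanobis kernel", {
  s <- grid_stack(5, 5)
  m <- toy_model(c(3.03, 9), diag(2), vars = c("alpha", "beta"))
  sr <- mahalanobis_raster(m, s)
  # cell (3,3): alpha = 3.03, beta = 9 -> distance 0, suitability 1
  expect_equal(sr$distance[3, 3], 0)
  expect_equal(sr$suitability[3, 3], 1)
  # identity shape, one unit along one axis
  m1 <- toy_model(c(3.03, 10), diag(2), vars = c("alpha", "beta"))
  sr1 <- mahalanobis_raster(m1, s)
  expect_equal(sr1$distance[3, 3], 1, tolerance = 1e-12)
  expect_equal(sr1$suitability[3, 3], exp(-0.5), tolerance = 1e-12)

  # random stack vs naive per-cell loop oracle
  set.seed(13)
  rs <- env_stack(list(u = matrix(rnorm(25), 5, 5),
                       v = matrix(rnorm(25), 5, 5)))
  shp <- crossprod(matrix(rnorm(4), 2)) + diag(2)
  mm <- toy_model(c(0.2, -0.1), shp, vars = c("u", "v"))
  sr2 <- mahalanobis_raster(mm, rs)
  Sinv <- solve(mm$shape)
  for (i in 1:5) for (j in 1:5) {
    xv <- c(rs$layers$u[i, j], rs$layers$v[i, j]) - mm$center
    expect_equal(sr2$distance[i, j], sqrt(drop(xv %*% Sinv %*% xv)),
                 tolerance = 1e-10)
  }
  # NA propagation
  rs$layers$u[2, 2] <- NA
  rs <- env_stack(rs$layers)
  expect_true(is.na(mahalanobis_raster(mm, rs)$suitability[2, 2]))
})

test_that("suitability is invariant under affine reparameterization", {
  set.seed(19)
  x <- matrix(rnorm(60), 30, 2)
  A <- matrix(c(1.5, 0.4, -0.2, 0.9), 2)
  b <- c(3, -1)
  y <- x %*% t(A) + rep(b, each = 30)
  mx <- fit_mve(x, seed = 3)
  my <- fit_mve(y, seed = 3)
  test_pts <- matrix(rnorm(20), 10, 2)
  expect_equal(ellipsoid_distance(my, test_pts %*% t(A) + rep(b, each = 10)),
               ellipsoid_distance(mx, test_pts), tolerance = 1e-8)
})

test_that("Gamma thresholds recover a known distance distribution", {
  m <- toy_model(0, 1)
  set.seed(23)
  d <- matrix(rexp(10000), ncol = 1) # |x| are Exponential(1) distances
  ts <- gamma_thresholds(m, d)
  expect_equal(ts$gamma_shape, 1, tolerance = 0.05)
  expect_equal(unname(ts$cutoffs["0.75"]), -log(0.25), tolerance = 0.05)
  expect_true(all(diff(ts$cutoffs) > 0)) # strictly increasing in quantile

  expect_error(gamma_thresholds(m, matrix(rep(2, 100), ncol = 1)),
               "constant")
  expect_error(gamma_thresholds(m, matrix(1:4, ncol = 1)), "at least 5")
})

test_that("binary maps nest with the threshold and preserve NA", {
  m <- toy_model(0, 1)
  set.seed(29)
  ts <- gamma_thresholds(m, matrix(rexp(10000), ncol = 1))
  sr <- structure(list(distance = matrix(c(0.5, 1.5, 3.0, NA), 2, 2),
                       suitability = NULL),
                  class = "suitability_raster")
  b75 <- binary_map(sr, ts, 0.75)
  b99 <- binary_map(sr, ts, 0.99)
  expect_equal(sum(b75, na.rm = TRUE), 1) # only the 0.5 cell at ~1.386
  expect_true(all(b99 >= b75, na.rm = TRUE)) # nested cell sets
  expect_true(is.na(b75[2, 2]))
  expect_error(binary_map(sr, ts, 0.5), "unknown quantile")

  sr0 <- structure(list(distance = matrix(0, 2, 2)),
                   class = "suitability_raster")
  expect_true(all(binary_map(sr0, ts, 0.75) == 1))
})

test_that("models serialize to JSON and back", {
  set.seed(31)
  m <- fit_mve(matrix(rnorm(60), ncol = 2), seed = 2, taxon = "t",
               variables = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".json")
  write_ellipsoid(m, f)
  m2 <- read_ellipsoid(f)
  expect_equal(m2$center, m$center)
  expect_equal(m2$shape, m$shape)
  expect_equal(m2$inclusion, m$inclusion)
})
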