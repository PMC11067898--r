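# lag-1 spatial autocorrelation estimate (row-neighbour correlation)
lag1_cor <- function(m) {
  cor(as.vector(m[-nrow(m), ]), as.vector(m[-1, ]))
}

test_that("simulated layers are standardized with tunable smoothness", {
  s0 <- simulate_env(40, 40, n_vars = 2, smoothness = 0, seed = 3)
  s5 <- simulate_env(40, 40, n_vars = 2, smoothness = 5, seed = 3)
  for (l in s0$layers) {
    expect_lt(abs(mean(l)), 1e-8)
    expect_equal(sd(l), 1, tolerance = 1e-8)
  }
  expect_lt(abs(lag1_cor(s0$layers$env1)), 0.05) # white noise
  expect_gt(lag1_cor(s5$layers$env1), 0.5)       # smooth field
  expect_error(simulate_env(20, 20, smoothness = 10), "kernel radius")
  expect_identical(simulate_env(30, 30, seed = 9), simulate_env(30, 30, seed = 9))
})

test_that("niche evolution scenarios produce their defining geometries", {
  tr <- read_newick_text("(a:1,b:1);")
  root <- structure(list(taxon = "root", center = c(env1 = 0, env2 = 0),
                         shape = diag(0.09, 2), inclusion = 0.9,
                         variables = c("env1", "env2"), n_fit = NA_integer_,
                         seed = 1L, log_volume = NA_real_),
                    class = "ellipsoid_model")
  dimnames(root$shape) <- list(root$variables, root$variables)

  cons <- evolve_niches(tr, root, scenario_config("conservatism"), seed = 1)
  expect_equal(cons$a$center, root$center)
  expect_equal(cons$b$shape, root$shape)

  part <- evolve_niches(tr, root, scenario_config("partitioning"), seed = 1)
  for (tx in c("a", "b"))
    expect_lt(ellipsoid_volume(part[[tx]]), ellipsoid_volume(root))
  off_a <- part$a$center - root$center
  off_b <- part$b$center - root$center
  expect_lt(sum(off_a * off_b), 0) # opposite sides of the split plane
  # children stay inside the ancestor: boundary points of each child
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  for (tx in c("a", "b")) {
    ch <- part[[tx]]
    ev <- eigen(ch$shape, symmetric = TRUE)
    bound <- t(ch$center + ev$vectors %*% diag(sqrt(ev$values)) %*%
                 rbind(cos(th), sin(th)))
    expect_true(all(ellipsoid_distance(root, bound) <= 1 + 1e-9))
  }

  div <- evolve_niches(tr, root, scenario_config("divergence", offset = 6),
                       seed = 2)
  moved <- div$a$center - root$center
  # displaced by exactly the configured Mahalanobis offset...
  expect_equal(sqrt(drop(moved %*% solve(root$shape) %*% moved)), 6,
               tolerance = 1e-9)
  expect_equal(div$b$center, root$center)
  # ...which exceeds the sum of the sampled-niche boundary radii, so the
  # two true ellipsoids at the sampling inclusion level cannot intersect
  expect_gt(6, 2 * sqrt(qchisq(0.95, df = 2)))
})

test_that("brownian jitter perturbs centers while scenarios stay seeded", {
  tr <- read_newick_text("(a:1,b:1);")
  root <- structure(list(taxon = "root", center = c(env1 = 0, env2 = 0),
                         shape = diag(0.09, 2), inclusion = 0.9,
                         variables = c("env1", "env2"), n_fit = NA_integer_,
                         seed = 1L, log_volume = NA_real_),
                    class = "ellipsoid_model")
  dimnames(root$shape) <- list(root$variables, root$variables)
  cfg <- scenario_config("conservatism", step_sd = 0.5)
  j1 <- evolve_niches(tr, root, cfg, seed = 4)
  j2 <- evolve_niches(tr, root, cfg, seed = 4)
  expect_identical(j1, j2)
  expect_false(identical(j1$a$center, root$center))
  expect_false(identical(j1$a$center, j1$b$center))
})

test_that("occurrence sampling respects M, the cutoff and the cell mean", {
  w <- cached_world("conservatism", seed = 23)
  occ <- w$occurrences$taxon1
  expect_equal(nrow(occ), 100)
  expect_true(all(point_in_area(w$areas$taxon1, cbind(occ$lon, occ$lat))))
  td <- attr(occ, "true_distance")
  expect_true(all(td <= attr(occ, "cutoff")))

  # sampling is uniform over acceptable cells: the empirical mean of the
  # sampled environmental values matches the acceptable-cell mean
  m <- w$true_models$taxon1
  cells <- area_cells(w$stack, w$areas$taxon1)
  vals <- stack_values(w$stack, cells)
  acc <- vals[ellipsoid_distance(m, vals) <= attr(occ, "cutoff"), ,
              drop = FALSE]
  big <- sample_occurrences(m, w$areas$taxon1, w$stack, n = 4000, seed = 31)
  got <- colMeans(extract_values(w$stack, big)$values)
  se <- apply(acc, 2, sd) / sqrt(4000)
  expect_true(all(abs(got - colMeans(acc)) <= 3 * se + 1e-6))

  # a niche wholly absent from M is refused
  far <- m; far$center <- c(env1 = 50, env2 = 50)
  expect_error(sample_occurrences(far, w$areas$taxon1, w$stack, n = 10),
               "acceptance probability")
})

test_that("worlds regenerate bit-identically from their configuration", {
  cfg <- scenario_config("divergence", n_rows = 40, n_cols = 40, n_occ = 30,
                         seed = 77)
  w1 <- make_world(cfg)
  w2 <- make_world(do.call(scenario_config, w1$truth_log))
  expect_identical(w1$stack$layers, w2$stack$layers)
  expect_identical(w1$occurrences, w2$occurrences)
  expect_identical(w1$true_models, w2$true_models)
  # Ms are geometrically disjoint and occurrences sit inside their own M
  expect_false(any(point_in_area(w1$areas$taxon1,
                                 cbind(w1$occurrences$taxon2$lon,
                                       w1$occurrences$taxon2$lat))))
})

test_that("world artifacts round trip through the standard formats", {
  w <- make_world(scenario_config("conservatism", n_rows = 25, n_cols = 25,
                                  n_occ = 20, seed = 5))
  d <- withr::local_tempdir()
  write_world(w, d)
  occ <- read_occurrences(file.path(d, "occurrences.csv"))
  expect_equal(nrow(occ), 40)
  st <- read_env_stack(file.path(d, "layers", c("env1.asc", "env2.asc")))
  expect_equal(st$layers$env1, w$stack$layers$env1, ignore_attr = TRUE)
  areas <- read_polygons(file.path(d, "areas.geojson"))
  expect_named(areas, c("taxon1", "taxon2"))
  tr <- read_newick(file.path(d, "tree.nwk"))
  expect_equal(sort(tr$tip.label), c("taxon1", "taxon2"))
})

test_that("fitted models recover the true niche centre at moderate n", {
  w <- cached_world("conservatism", seed = 29, n_occ = 200)
  m <- fit_mve(extract_values(w$stack, w$occurrences$taxon1, "taxon1"),
               seed = 1)
  err <- sqrt(drop(t(m$center - w$true_models$taxon1$center) %*%
                     solve(w$true_models$taxon1$shape) %*%
                     (m$center - w$true_models$taxon1$center)))
  expect_lt(err, 0.5) # Mahalanobis units of the true shape
})
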