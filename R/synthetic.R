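#' Simulate smooth environmental raster layers
#'
#' Each layer is seeded white noise convolved with a Gaussian kernel of
#' the stated radius (edge-renormalised), optionally plus a latitudinal
#' gradient, then standardised to mean 0, sd 1 over non-NA cells. The
#' result mimics the smooth, spatially autocorrelated surfaces of real
#' climate layers without imitating any particular data set's covariance
#' structure.
#'
#' @param n_rows,n_cols grid size (>= 20 each).
#' @param n_vars number of layers (>= 2).
#' @param smoothness Gaussian kernel radius in cells (0 = iid noise).
#' @param gradient amplitude of a north-south linear gradient added to
#'   every layer before standardisation (default 0).
#' @param seed integer seed.
#' @param origin,cell_size grid georeferencing (defaults: 1 degree cells
#'   anchored at lon 0, lat 0 descending).
#' @return An [env_stack] with layers `env1..envK`.
#' @export
simulate_env <- function(n_rows, n_cols, n_vars = 2, smoothness = 4,
                         gradient = 0, seed = 1L,
                         origin = c(0, 0), cell_size = 1) {
  stopifnot(n_rows >= 20, n_cols >= 20, n_vars >= 2)
  if (smoothness >= min(n_rows, n_cols) / 2)
    stop("kernel radius must be below half the smallest grid dimension")
  with_seed_if(seed, {
    layers <- lapply(seq_len(n_vars), function(v) {
      m <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
      if (smoothness > 0) m <- gaussian_blur(m, smoothness)
      if (gradient != 0)
        m <- m + seq(-gradient, gradient, length.out = n_rows)
      (m - mean(m)) / sd(m)
    })
    names(layers) <- paste0("env", seq_len(n_vars))
    env_stack(layers, origin = origin, cell_size = cell_size)
  })
}

# separable Gaussian blur with exact edge renormalisation via banded
# row-stochastic smoothing matrices
gaussian_blur <- function(m, radius) {
  band <- function(n) {
    k <- stats::dnorm(-radius:radius, sd = max(radius / 2, 0.5))
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - radius):(i + radius)
      ok <- j >= 1 & j <= n
      B[i, j[ok]] <- k[ok]
    }
    B / rowSums(B)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Scenario configuration for a simulated niche-evolution world
#'
#' Encodes the three canonical ways a pair of allopatric descendants can
#' relate to the ancestral niche: `"partitioning"` (each descendant
#' occupies a different sub-ellipsoid of the ancestor's niche),
#' `"conservatism"` (both inherit the ancestral niche unchanged) and
#' `"divergence"` (one descendant's niche centre shifts into novel
#' environmental space).
#'
#' @param scenario one of `"partitioning"`, `"conservatism"`,
#'   `"divergence"`.
#' @param n_taxa number of tip taxa (default 2).
#' @param n_occ occurrences sampled per taxon (default 100).
#' @param n_rows,n_cols raster size (default 80 x 80).
#' @param n_vars environmental variables (default 2).
#' @param smoothness kernel radius in cells (default 2).
#' @param niche_width per-axis scale of the true niche in standardised
#'   environmental units (default 0.3); the true shape matrix is
#'   `niche_width^2 * I`.
#' @param offset divergence displacement of the shifted tip's centre, in
#'   Mahalanobis units of the root shape (default 6; with the default
#'   inclusion level the two true ellipsoids then do not intersect).
#' @param step_sd Brownian jitter of niche centres per unit branch length,
#'   Mahalanobis units (default 0 = none).
#' @param inclusion inclusion level used for fitted models (default 0.90).
#' @param seed integer master seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("conservatism", "partitioning",
                                         "divergence"),
                            n_taxa = 2, n_occ = 100, n_rows = 80,
                            n_cols = 80, n_vars = 2, smoothness = 2,
                            niche_width = 0.3, offset = 6, step_sd = 0,
                            inclusion = 0.90, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_taxa >= 2, offset >= 0, n_occ >= n_vars + 1)
  structure(as.list(environment()), class = "scenario_config")
}

#' Evolve true ellipsoid niches along a tree under a scenario
#'
#' Conservatism: every tip inherits the root niche unchanged.
#' Partitioning: at each (binary) internal node the current ellipsoid is
#' split along its widest axis into two disjoint sub-ellipsoids wholly
#' inside it, so tips tile the ancestral niche. Divergence: one
#' designated tip's centre is displaced by `offset` Mahalanobis units
#' along a random direction; all others inherit the root. With
#' `step_sd > 0`, Brownian jitter of centres (sd `step_sd * sqrt(branch
#' length)` Mahalanobis units per branch) is superimposed.
#'
#' @param tree a `phylo` object.
#' @param root_model the ancestral `ellipsoid_model` (fields `center`,
#'   `shape` suffice).
#' @param config a [scenario_config()].
#' @param diverge_tip tip label displaced under the divergence scenario
#'   (default: first tip).
#' @param seed integer seed (default: from config).
#' @return Named list of per-tip true `ellipsoid_model`s.
#' @export
evolve_niches <- function(tree, root_model, config,
                          diverge_tip = tree$tip.label[1],
                          seed = config$seed) {
  validate_tree(tree)
  d <- length(root_model$center)
  tips <- tree$tip.label
  with_seed_if(seed, {
    models <- switch(config$scenario,
      conservatism = setNames(rep(list(root_model), length(tips)), tips),
      divergence = {
        A <- t(chol(root_model$shape))
        z <- rnorm(d)
        disp <- as.numeric(A %*% z) / sqrt(sum(z^2)) * config$offset
        out <- setNames(rep(list(root_model), length(tips)), tips)
        shifted <- root_model
        shifted$center <- root_model$center + disp
        out[[diverge_tip]] <- shifted
        out
      },
      partitioning = partition_niches(tree, root_model))
    if (config$step_sd > 0) models <- brownian_jitter(tree, models,
                                                      root_model,
                                                      config$step_sd)
    for (tx in tips) models[[tx]]$taxon <- tx
    models
  })
}

# recursive halving of the ellipsoid along its widest principal axis
partition_niches <- function(tree, root_model) {
  n_tip <- length(tree$tip.label)
  ch <- child_list(tree)
  out <- vector("list", n_tip)
  descend <- function(node, model) {
    kids <- ch[[node]]
    if (is.null(kids)) { out[[node]] <<- model; return(invisible()) }
    if (length(kids) != 2)
      stop("partitioning scenario requires a binary tree")
    eig <- eigen(model$shape, symmetric = TRUE)
    u <- eig$vectors[, 1]; a <- sqrt(eig$values[1]) # widest semi-axis
    for (s in c(-1, 1)) {
      kid_model <- model
      kid_model$center <- model$center + s * 0.5 * a * u
      # split axis shrinks to 0.45 a (halves disjoint: centres 1.0 a apart,
      # extents 0.9 a); perpendicular axes shrink to sqrt(0.5) so the
      # offset sub-ellipsoid stays inside the parent: with centre offset
      # 0.5, split semi-axis 0.45 and perpendicular scale b, the parent
      # Mahalanobis radius of a child boundary point is
      # (0.5 + 0.45 c)^2 + b^2 (1 - c^2), maximised over c in [-1, 1];
      # b^2 = 0.5 keeps that maximum at 0.92 < 1
      vals <- eig$values
      vals[1] <- (0.45 * a)^2
      vals[-1] <- 0.5 * vals[-1]
      kid_model$shape <- eig$vectors %*% diag(vals, length(vals)) %*%
        t(eig$vectors)
      descend(kids[if (s < 0) 1 else 2], kid_model)
    }
  }
  descend(n_tip + 1L, root_model)
  setNames(out[seq_len(n_tip)], tree$tip.label)
}

brownian_jitter <- function(tree, models, root_model, step_sd) {
  d <- length(root_model$center)
  A <- t(chol(root_model$shape))
  n_tip <- length(tree$tip.label)
  ch <- child_list(tree)
  edge_len <- function(child)
    tree$edge.length[tree$edge[, 2] == child]
  walk <- function(node, disp) {
    for (c in ch[[node]]) {
      step <- as.numeric(A %*% rnorm(d)) * step_sd * sqrt(edge_len(c))
      if (c <= n_tip) {
        tx <- tree$tip.label[c]
        models[[tx]]$center <<- models[[tx]]$center + disp + step
      } else walk(c, disp + step)
    }
  }
  walk(n_tip + 1L, rep(0, d))
  models
}

#' Sample virtual occurrences of a species inside its accessible area
#'
#' Draws grid cells uniformly from the accessible area, accepting those
#' whose environmental vector lies within the true niche (Mahalanobis
#' distance wrt the true shape below the chi-based cutoff at
#' `cutoff_quantile`), until `n` records are accepted; each record is the
#' cell centre plus sub-cell uniform jitter. True distances are logged.
#'
#' @param model the true `ellipsoid_model`.
#' @param area the taxon's [accessible_area].
#' @param stack an [env_stack].
#' @param n records to sample.
#' @param cutoff_quantile inclusion level of the sampling cutoff
#'   (default 0.95).
#' @param seed integer seed.
#' @return An `occurrence_df` with attributes `true_distance` (per record)
#'   and `cutoff`.
#' @export
sample_occurrences <- function(model, area, stack, n,
                               cutoff_quantile = 0.95, seed = 1L) {
  d <- length(model$center)
  cutoff <- sqrt(qchisq(cutoff_quantile, df = d))
  cells <- area_cells(stack, area)
  if (length(cells) == 0L) stop("accessible area holds no usable cells")
  vals <- stack_values(select_variables(stack, model$variables), cells)
  dist <- ellipsoid_distance(model, vals)
  ok <- which(dist <= cutoff)
  if (length(ok) / length(cells) < 1e-4)
    stop("acceptance probability below 1e-4: true niche barely present ",
         "inside the accessible area")
  ctr <- cell_centers(stack)
  with_seed_if(seed, {
    pick <- ok[sample.int(length(ok), n, replace = TRUE)]
    jit <- matrix(runif(2 * n, -stack$cell_size / 2, stack$cell_size / 2),
                  n, 2)
    pts <- ctr[cells[pick], , drop = FALSE] + jit
    # jitter may not carry a record across the M boundary
    outside <- !point_in_area(area, pts)
    pts[outside, ] <- ctr[cells[pick[outside]], , drop = FALSE]
    occ <- occurrence_df(taxon = model$taxon %||% "virtual",
                         lon = pts[, 1], lat = pts[, 2])
    attr(occ, "true_distance") <- dist[pick]
    attr(occ, "cutoff") <- cutoff
    occ
  })
}

#' Generate a complete virtual niche-evolution world
#'
#' Composes [simulate_env()], a Yule tree (or a supplied tree), true
#' niche evolution under the configured scenario, disjoint rectangular
#' accessible areas (vertical strips, emulating allopatric breeding
#' ranges) and occurrence sampling, with full ground truth retained. A
#' fixed config (including its seed) regenerates the world bit-identically.
#'
#' @param config a [scenario_config()].
#' @param tree optional `phylo`; default is a Yule tree on `n_taxa` tips.
#' @return A list of class `synthetic_world`: `stack`, `tree`,
#'   `true_models`, `areas`, `occurrences` (list of `occurrence_df`),
#'   `truth_log`.
#' @export
make_world <- function(config, tree = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed_if(config$seed, {
    # anchor the grid so any simulated size stays inside valid lon/lat
    cs <- min(1, 168 / max(config$n_rows, config$n_cols))
    stack <- simulate_env(config$n_rows, config$n_cols, config$n_vars,
                          smoothness = config$smoothness, seed = NULL,
                          origin = c(-80, 84), cell_size = cs)
    if (is.null(tree)) {
      tree <- ape::rphylo(config$n_taxa, birth = 1, death = 0)
      tree$tip.label <- paste0("taxon", seq_len(config$n_taxa))
    }
    root <- structure(
      list(taxon = "root",
           center = setNames(rep(0, config$n_vars), names(stack$layers)),
           shape = diag(config$niche_width^2, config$n_vars) |>
             (\(m) { dimnames(m) <- list(names(stack$layers),
                                         names(stack$layers)); m })(),
           inclusion = config$inclusion,
           variables = names(stack$layers), n_fit = NA_integer_,
           seed = config$seed, log_volume = NA_real_),
      class = "ellipsoid_model")
    true_models <- evolve_niches(tree, root, config, seed = NULL)
    areas <- strip_areas(stack, tree$tip.label)
    occurrences <- lapply(tree$tip.label, function(tx)
      sample_occurrences(true_models[[tx]], areas[[tx]], stack,
                         n = config$n_occ, seed = NULL))
    names(occurrences) <- tree$tip.label
    structure(list(stack = stack, tree = tree, true_models = true_models,
                   areas = areas, occurrences = occurrences,
                   truth_log = unclass(config)),
              class = "synthetic_world")
  })
}

# disjoint vertical-strip accessible areas, one per taxon
strip_areas <- function(stack, taxa) {
  k <- length(taxa)
  lon0 <- stack$origin[1] - stack$cell_size / 2
  lon1 <- lon0 + stack$n_cols * stack$cell_size
  lat0 <- stack$origin[2] + stack$cell_size / 2
  lat1 <- lat0 - stack$n_rows * stack$cell_size
  width <- (lon1 - lon0) / k
  gap <- stack$cell_size / 4 # strict geometric disjointness
  areas <- lapply(seq_len(k), function(i) {
    xl <- lon0 + (i - 1) * width + gap
    xr <- lon0 + i * width - gap
    accessible_area(taxa[i], rbind(c(xl, lat1), c(xr, lat1),
                                   c(xr, lat0), c(xl, lat0)))
  })
  setNames(areas, taxa)
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %s: %d taxa, %d x %d grid, %d vars\n",
              x$truth_log$scenario, length(x$true_models),
              x$stack$n_rows, x$stack$n_cols, length(x$stack$layers)))
  invisible(x)
}

#' Write all artifacts of a synthetic world to disk in standard formats
#'
#' Emits the occurrence CSV, per-layer ASCII grids, accessible-area
#' GeoJSON, Newick tree and a JSON truth log under `dir`.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  occ <- do.call(rbind, world$occurrences)
  write_occurrences(occ, file.path(dir, "occurrences.csv"))
  write_env_stack(world$stack, file.path(dir, "layers"))
  write_polygons(world$areas, file.path(dir, "areas.geojson"))
  write_newick(world$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(world$truth_log, file.path(dir, "truth_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
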