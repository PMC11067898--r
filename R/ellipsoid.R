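#' Fit a minimum volume ellipsoid niche model
#'
#' Estimates the fundamental niche of a taxon as the smallest-volume
#' ellipsoid in environmental space covering a stated fraction of its
#' occurrence points (default 90%, which tolerates vagrants and residual
#' georeferencing error). The search is the classical resampling MVE:
#' random (d+1)-point subsets propose (mean, covariance) candidates; each
#' candidate covariance is inflated by the h-th smallest squared
#' Mahalanobis distance so the candidate covers h = ceil(inclusion * n)
#' points, and the candidate with minimum volume wins. All C(n, d+1)
#' subsets are enumerated when there are no more of them than `n_subsets`.
#'
#' @param values n x d matrix of environmental vectors (NA rows dropped).
#' @param inclusion fraction of points the ellipsoid must cover
#'   (default 0.90).
#' @param n_subsets number of random candidate subsets (default 5000).
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param taxon optional label.
#' @param variables optional column names (defaults to `colnames(values)`).
#' @return An object of class `ellipsoid_model`: `center` (d-vector),
#'   `shape` (d x d SPD matrix; the niche boundary is the unit level set
#'   of the induced Mahalanobis distance), `inclusion`, `variables`,
#'   `n_fit`, `seed`, `log_volume`. At least `ceil(inclusion * n)` fitting
#'   points satisfy `(x - center)' shape^-1 (x - center) <= 1`.
#' @export
fit_mve <- function(values, inclusion = 0.90, n_subsets = 5000, seed = 1L,
                    taxon = NA_character_, variables = NULL) {
  if (inherits(values, "env_matrix")) {
    if (is.na(taxon)) taxon <- values$taxon
    if (is.null(variables)) variables <- values$variables
    values <- values$values
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  values <- values[stats::complete.cases(values), , drop = FALSE]
  n <- nrow(values); d <- ncol(values)
  if (n <= d) stop("need at least d + 1 = ", d + 1, " points, got ", n)
  if (all(apply(values, 2, var) == 0)) stop("all points identical")
  stopifnot(inclusion > 0, inclusion <= 1)
  h <- ceiling(inclusion * n)
  if (is.null(variables)) variables <- colnames(values)
  if (is.null(variables)) variables <- paste0("V", seq_len(d))

  k <- d + 1
  n_all <- choose(n, k)
  subsets <- if (n_all <= n_subsets) {
    t(combn(n, k)) - 1L
  } else {
    with_seed_if(seed, t(replicate(n_subsets, sample.int(n, k))) - 1L)
  }
  storage.mode(subsets) <- "integer"
  res <- .mve_search(values, subsets, as.integer(h))
  structure(
    list(taxon = taxon, center = setNames(as.numeric(res$center), variables),
         shape = matrix(res$shape, d, d, dimnames = list(variables, variables)),
         inclusion = inclusion, variables = variables, n_fit = n,
         seed = seed, log_volume = res$log_volume),
    class = "ellipsoid_model")
}

#' @export
print.ellipsoid_model <- function(x, ...) {
  cat(sprintf("<ellipsoid_model> %s: d = %d, inclusion = %.2f, n_fit = %d\n",
              x$taxon, length(x$center), x$inclusion, x$n_fit))
  cat("  center:", paste(sprintf("%.3f", x$center), collapse = ", "), "\n")
  cat(sprintf("  volume: %.4g\n", ellipsoid_volume(x)))
  invisible(x)
}

#' Volume of an ellipsoid model
#'
#' Volume of the unit Mahalanobis level set `{x : (x-c)' S^-1 (x-c) <= 1}`,
#' i.e. the unit-ball volume times `sqrt(det(S))`.
#'
#' @param model an `ellipsoid_model` (or a d x d shape matrix).
#' @return Scalar volume.
#' @export
ellipsoid_volume <- function(model) {
  S <- if (inherits(model, "ellipsoid_model")) model$shape else as.matrix(model)
  d <- nrow(S)
  unit_ball <- pi^(d / 2) / gamma(d / 2 + 1)
  unit_ball * sqrt(det(S))
}

#' Mahalanobis distance of points to an ellipsoid model
#' @param model an `ellipsoid_model`.
#' @param values n x d matrix on the model's variables.
#' @return Vector of distances `sqrt((x-c)' S^-1 (x-c))`; the niche
#'   boundary is at distance 1.
#' @export
ellipsoid_distance <- function(model, values) {
  values <- as.matrix(values)
  if (!is.null(colnames(values)))
    values <- values[, model$variables, drop = FALSE]
  if (ncol(values) != length(model$center))
    stop("value matrix has ", ncol(values), " columns; model has ",
         length(model$center), " variables")
  sqrt(pmax(as.numeric(.mahal_sq(values, unname(model$center),
                                 unname(model$shape))), 0))
}

#' Mahalanobis suitability surface of an ellipsoid model
#'
#' Evaluates, for every non-NA cell of the stack, the Mahalanobis
#' distance of the cell's environmental vector to the fitted ellipsoid
#' and maps it to a suitability in (0, 1] with the Gaussian kernel
#' `exp(-distance^2 / 2)` (strictly decreasing in distance; 1 exactly at
#' the niche centre). A linear transform `1 - d/d_max` is available.
#'
#' @param model an `ellipsoid_model`.
#' @param stack an [env_stack] whose layers include the model's variables.
#' @param transform `"gaussian"` (default) or `"linear"`.
#' @return A list of class `suitability_raster` with matrices `distance`
#'   and `suitability` (NA cells preserved) plus the grid metadata.
#' @export
mahalanobis_raster <- function(model, stack,
                               transform = c("gaussian", "linear")) {
  transform <- match.arg(transform)
  if (!all(model$variables %in% names(stack$layers)))
    stop("stack lacks model variable(s): ",
         paste(setdiff(model$variables, names(stack$layers)), collapse = ", "))
  ok <- !as.vector(stack$na_mask)
  vals <- stack_values(select_variables(stack, model$variables))[ok, ,
                                                                 drop = FALSE]
  dist_v <- rep(NA_real_, stack$n_rows * stack$n_cols)
  dist_v[ok] <- ellipsoid_distance(model, vals)
  dmat <- matrix(dist_v, stack$n_rows, stack$n_cols)
  suit <- switch(transform,
    gaussian = exp(-dmat^2 / 2),
    linear = {
      dmax <- max(dmat, na.rm = TRUE)
      pmax(1 - dmat / dmax, 0)
    })
  structure(list(distance = dmat, suitability = suit, taxon = model$taxon,
                 origin = stack$origin, cell_size = stack$cell_size,
                 transform = transform),
            class = "suitability_raster")
}

#' Gamma-quantile distance thresholds for binary maps
#'
#' Occurrence-to-ellipsoid distances are right-skewed; a Gamma
#' distribution is fitted to them by maximum likelihood and its quantiles
#' give the distance cutoffs at the requested data-inclusion levels.
#'
#' @param model an `ellipsoid_model`.
#' @param occ_values n x d matrix of the occurrence environmental vectors.
#' @param quantiles inclusion levels (default 0.75, 0.85, 0.90, 0.95,
#'   0.99).
#' @return A list of class `threshold_set` with `gamma_shape`,
#'   `gamma_rate` and `cutoffs` (named by quantile, strictly increasing).
#' @export
gamma_thresholds <- function(model, occ_values,
                             quantiles = c(0.75, 0.85, 0.90, 0.95, 0.99)) {
  if (inherits(occ_values, "env_matrix")) occ_values <- occ_values$values
  dists <- ellipsoid_distance(model, occ_values)
  if (length(dists) < 5) stop("need at least 5 occurrence distances")
  if (var(dists) == 0) stop("constant distances; Gamma fit degenerate")
  nz <- dists == 0
  if (any(nz)) {
    message(sum(nz), " zero distance(s) jittered by machine epsilon")
    dists[nz] <- .Machine$double.eps
  }
  fit <- fitdistrplus::fitdist(dists, "gamma", method = "mle")
  shape <- unname(fit$estimate["shape"]); rate <- unname(fit$estimate["rate"])
  cutoffs <- qgamma(quantiles, shape = shape, rate = rate)
  names(cutoffs) <- format(quantiles)
  structure(list(gamma_shape = shape, gamma_rate = rate,
                 quantiles = quantiles, cutoffs = cutoffs),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> Gamma(shape = %.3f, rate = %.3f)\n",
              x$gamma_shape, x$gamma_rate))
  print(round(x$cutoffs, 4))
  invisible(x)
}

#' Binary presence map from a thresholded suitability surface
#'
#' @param sr a `suitability_raster`.
#' @param ts a `threshold_set`.
#' @param q one of the threshold quantiles in `ts`.
#' @return A 0/1 matrix (NA preserved): 1 where distance <= cutoff(q).
#' @export
binary_map <- function(sr, ts, q) {
  i <- match(q, ts$quantiles)
  if (is.na(i)) stop("unknown quantile ", q, "; available: ",
                     paste(ts$quantiles, collapse = ", "))
  cutoff <- ts$cutoffs[i]
  out <- (sr$distance <= cutoff) * 1
  out
}

#' Serialize an ellipsoid model to JSON
#' @param model an `ellipsoid_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ellipsoid <- function(model, path) {
  jsonlite::write_json(
    list(taxon = model$taxon, variables = model$variables,
         center = unname(model$center), shape = unname(model$shape),
         inclusion = model$inclusion, n_fit = model$n_fit,
         seed = model$seed, log_volume = model$log_volume),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read an ellipsoid model from JSON
#' @param path JSON file written by [write_ellipsoid()].
#' @return An `ellipsoid_model`.
#' @export
read_ellipsoid <- function(path) {
  x <- jsonlite::fromJSON(path)
  d <- length(x$center)
  shape <- matrix(unlist(x$shape), d, d, byrow = TRUE,
                  dimnames = list(x$variables, x$variables))
  structure(list(taxon = x$taxon,
                 center = setNames(as.numeric(x$center), x$variables),
                 shape = shape, inclusion = x$inclusion,
                 variables = x$variables, n_fit = x$n_fit, seed = x$seed,
                 log_volume = x$log_volume),
            class = "ellipsoid_model")
}
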