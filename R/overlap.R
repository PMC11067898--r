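#' Schoener's D overlap between two suitability surfaces
#'
#' Each surface is normalised to sum to 1 over the comparison extent
#' (cells where a surface is NA inside the extent contribute 0 and are
#' counted), then `D = 1 - 0.5 * sum(|p_a - p_b|)`: 1 for identical
#' surfaces, 0 for disjoint supports.
#'
#' @param sa,sb `suitability_raster` objects on the same grid, or bare
#'   numeric vectors of suitabilities over the extent.
#' @param extent integer vector of linear cell indices defining the
#'   comparison extent (default: cells where either surface is non-NA).
#'   The recommended extent for a taxon pair is the union of the two
#'   accessible areas' non-NA cells.
#' @return Schoener's D in `[0, 1]`.
#' @export
schoeners_d <- function(sa, sb, extent = NULL) {
  va <- if (inherits(sa, "suitability_raster")) as.vector(sa$suitability) else as.numeric(sa)
  vb <- if (inherits(sb, "suitability_raster")) as.vector(sb$suitability) else as.numeric(sb)
  if (!is.null(extent)) { va <- va[extent]; vb <- vb[extent] }
  if (length(va) != length(vb)) stop("surfaces are not on the same grid/extent")
  keep <- !is.na(va) | !is.na(vb)
  va <- va[keep]; vb <- vb[keep]
  n_na <- sum(is.na(va)) + sum(is.na(vb))
  if (n_na > 0) message(n_na, " NA cell value(s) inside extent treated as 0")
  va[is.na(va)] <- 0; vb[is.na(vb)] <- 0
  if (sum(va) == 0 || sum(vb) == 0)
    stop("a surface sums to 0 over the comparison extent")
  pa <- va / sum(va); pb <- vb / sum(vb)
  1 - 0.5 * sum(abs(pa - pb))
}

# suitability of a model over a set of environmental vectors
suitability_at <- function(model, values) {
  exp(-ellipsoid_distance(model, values)^2 / 2)
}

#' Null distribution of Schoener's D from background models
#'
#' The background-similarity side of a niche equivalency test: niche
#' models are repeatedly fitted to random points drawn from one species'
#' accessible area and compared (Schoener's D over the shared extent) to
#' the other species' fixed model, giving the distribution of overlap
#' expected if the species were sampling its background at random.
#'
#' @param model_fixed the fixed `ellipsoid_model`.
#' @param area_random [accessible_area] the random models are drawn from.
#' @param stack an [env_stack].
#' @param n_points points per random model (>= d + 1); conventionally the
#'   occurrence count of the area's own species.
#' @param n_reps number of random models (default 100).
#' @param seed integer seed; the vector is bit-identical across runs for
#'   a fixed seed.
#' @param extent integer cell indices of the comparison extent (default:
#'   all non-NA cells of the stack).
#' @param inclusion,n_subsets passed to [fit_mve()] for the null models.
#' @return Numeric vector of `n_reps` D values.
#' @export
background_null <- function(model_fixed, area_random, stack, n_points,
                            n_reps = 100, seed = 1L, extent = NULL,
                            inclusion = 0.90, n_subsets = 500) {
  cells <- area_cells(stack, area_random)
  d <- length(model_fixed$center)
  if (n_points < d + 1) stop("n_points must be at least d + 1")
  if (length(cells) < n_points)
    stop("accessible area holds ", length(cells),
         " usable cells; need >= ", n_points)
  if (is.null(extent)) extent <- which(!as.vector(stack$na_mask))
  ext_vals <- stack_values(select_variables(stack, model_fixed$variables),
                           extent)
  fixed_suit <- suitability_at(model_fixed, ext_vals)
  cell_vals <- stack_values(select_variables(stack, model_fixed$variables),
                            cells)
  with_seed_if(seed, {
    vapply(seq_len(n_reps), function(r) {
      for (try in 1:10) {
        pick <- sample.int(length(cells), n_points)
        m <- tryCatch(
          fit_mve(cell_vals[pick, , drop = FALSE], inclusion = inclusion,
                  n_subsets = n_subsets, seed = NULL,
                  variables = model_fixed$variables),
          error = function(e) NULL)
        if (!is.null(m))
          return(schoeners_d(fixed_suit, suitability_at(m, ext_vals)))
      }
      stop("10 consecutive singular background fits in rep ", r)
    }, numeric(1))
  })
}

#' Rank p-value of an observed overlap against a null distribution
#'
#' `p = (1 + #\{null <= d_obs\}) / (N + 1)`; ties count into the lower
#' tail (conservative for divergence claims) and the +1 correction keeps
#' both tails reachable. Small p: observed overlap lower than background
#' expectation (divergence); large p: higher (conservatism).
#'
#' @param d_obs observed Schoener's D.
#' @param null numeric vector of null D values.
#' @return p-value in (0, 1].
#' @export
rank_pvalue <- function(d_obs, null) {
  if (length(null) == 0L) stop("empty null distribution")
  (1 + sum(null <= d_obs)) / (length(null) + 1)
}

#' Score a two-direction equivalency test on the -2..+2 scale
#'
#' With two-tailed alpha (default 0.05, cut points 0.025 and 0.975):
#' -2 when both p-values fall below alpha/2 (niche divergence supported
#' against both backgrounds); -1 when exactly one does and the other is
#' central; +2 when both exceed 1 - alpha/2 (overlap higher than either
#' background expects: strong conservatism); +1 when exactly one does;
#' 0 otherwise. The contradictory pattern (one tail low, the other high)
#' scores 0 with `conflict = TRUE`.
#'
#' @param p_a,p_b the two rank p-values.
#' @param alpha two-tailed significance level (default 0.05).
#' @return Integer score in -2..2 with attribute `conflict` (logical).
#' @export
score_comparison <- function(p_a, p_b, alpha = 0.05) {
  stopifnot(p_a > 0, p_a <= 1, p_b > 0, p_b <= 1, alpha > 0, alpha < 1)
  lo <- alpha / 2; hi <- 1 - alpha / 2
  low <- c(p_a < lo, p_b < lo)
  high <- c(p_a > hi, p_b > hi)
  conflict <- any(low) && any(high)
  score <- if (all(low)) -2L
  else if (all(high)) 2L
  else if (conflict) 0L
  else if (any(low)) -1L
  else if (any(high)) 1L
  else 0L
  structure(score, conflict = conflict)
}

#' Niche equivalency test for one taxon pair
#'
#' Computes the observed Schoener's D between the two taxa's suitability
#' surfaces over the union of their accessible areas, the two background
#' null distributions (each taxon's model vs random models from the other
#' taxon's M), both rank p-values and the -2..+2 score.
#'
#' @param model_a,model_b `ellipsoid_model`s.
#' @param area_a,area_b the taxa's [accessible_area]s.
#' @param stack an [env_stack].
#' @param n_points_a,n_points_b points per null model drawn in each M
#'   (default: each model's own `n_fit`).
#' @param n_reps null models per direction (default 100).
#' @param alpha two-tailed level (default 0.05).
#' @param seed integer seed.
#' @param inclusion,n_subsets passed to [fit_mve()] for null models.
#' @return A list of class `comparison_result` with `taxon_a`, `taxon_b`,
#'   `d_obs`, `null_from_ma`, `null_from_mb`, `p_a`, `p_b`, `score`,
#'   `conflict`.
#' @export
compare_pair <- function(model_a, model_b, area_a, area_b, stack,
                         n_points_a = model_a$n_fit,
                         n_points_b = model_b$n_fit,
                         n_reps = 100, alpha = 0.05, seed = 1L,
                         inclusion = 0.90, n_subsets = 500) {
  extent <- sort(union(area_cells(stack, area_a), area_cells(stack, area_b)))
  if (length(extent) == 0L) stop("empty comparison extent")
  ext_vals <- stack_values(select_variables(stack, model_a$variables), extent)
  suit_a <- suitability_at(model_a, ext_vals)
  suit_b <- suitability_at(model_b, ext_vals)
  d_obs <- schoeners_d(suit_a, suit_b)
  # null_from_ma: model_b (fixed) vs random models from taxon a's M
  null_a <- background_null(model_b, area_a, stack, n_points = n_points_a,
                            n_reps = n_reps, seed = seed, extent = extent,
                            inclusion = inclusion, n_subsets = n_subsets)
  null_b <- background_null(model_a, area_b, stack, n_points = n_points_b,
                            n_reps = n_reps, seed = seed + 1L, extent = extent,
                            inclusion = inclusion, n_subsets = n_subsets)
  p_a <- rank_pvalue(d_obs, null_a)
  p_b <- rank_pvalue(d_obs, null_b)
  sc <- score_comparison(p_a, p_b, alpha = alpha)
  structure(list(taxon_a = model_a$taxon, taxon_b = model_b$taxon,
                 d_obs = d_obs, null_from_ma = null_a, null_from_mb = null_b,
                 p_a = p_a, p_b = p_b, score = as.integer(sc),
                 conflict = attr(sc, "conflict")),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s vs %s: D = %.3f, p = (%.3f, %.3f), score %+d%s\n",
              x$taxon_a, x$taxon_b, x$d_obs, x$p_a, x$p_b, x$score,
              if (x$conflict) " [conflict]" else ""))
  invisible(x)
}

#' All pairwise niche equivalency tests
#'
#' Runs [compare_pair()] for every unordered pair of taxa and assembles a
#' lower-triangular score matrix (the layout conventionally used to
#' report such comparisons) plus the full per-pair results.
#'
#' @param models named list of `ellipsoid_model`s.
#' @param areas named list of [accessible_area]s (same names).
#' @param stack an [env_stack].
#' @param n_reps,alpha,seed,inclusion,n_subsets see [compare_pair()].
#' @return A list of class `score_matrix` with `taxa`, `scores` (matrix,
#'   lower triangle filled), `p_values` (per-pair data frame) and
#'   `results` (list of `comparison_result`).
#' @export
pairwise_matrix <- function(models, areas, stack, n_reps = 100, alpha = 0.05,
                            seed = 1L, inclusion = 0.90, n_subsets = 500) {
  taxa <- names(models)
  if (length(taxa) < 2) stop("need at least 2 taxa")
  if (!all(taxa %in% names(areas)))
    stop("missing accessible area(s) for: ",
         paste(setdiff(taxa, names(areas)), collapse = ", "))
  g <- length(taxa)
  scores <- matrix(NA_integer_, g, g, dimnames = list(taxa, taxa))
  results <- list()
  rows <- list()
  pair_id <- 0L
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    pair_id <- pair_id + 1L
    a <- taxa[i]; b <- taxa[j]
    res <- compare_pair(models[[a]], models[[b]], areas[[a]], areas[[b]],
                        stack, n_reps = n_reps, alpha = alpha,
                        seed = seed + 2L * pair_id, inclusion = inclusion,
                        n_subsets = n_subsets)
    scores[j, i] <- res$score
    results[[paste(a, b, sep = ":")]] <- res
    rows[[pair_id]] <- data.frame(taxon_a = a, taxon_b = b, d_obs = res$d_obs,
                                  p_a = res$p_a, p_b = res$p_b,
                                  score = res$score, conflict = res$conflict)
  }
  structure(list(taxa = taxa, scores = scores,
                 p_values = do.call(rbind, rows), results = results),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d taxa, %d pairwise comparisons\n",
              length(x$taxa), nrow(x$p_values)))
  m <- x$scores
  m[is.na(m)] <- ""
  print(as.data.frame(m), quote = FALSE)
  invisible(x)
}

#' Count pairs per score class in a score matrix
#' @param scores a `score_matrix` or a plain numeric matrix of scores
#'   (NA = untested).
#' @return Named integer vector with counts for scores -2..2 and the
#'   number of untested pairs (`blank`).
#' @export
count_scores <- function(scores) {
  m <- if (inherits(scores, "score_matrix")) scores$scores else as.matrix(scores)
  v <- m[lower.tri(m)]
  out <- vapply(-2:2, function(s) sum(v == s, na.rm = TRUE), integer(1))
  names(out) <- as.character(-2:2)
  c(out, blank = sum(is.na(v)))
}
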