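#' Extract environmental values at occurrence points
#'
#' Nearest-cell-centre lookup of every layer of a stack at a set of
#' points. Points on NA cells (or off-grid) are dropped and their count
#' logged as an attribute.
#'
#' @param stack an [env_stack].
#' @param pts two-column lon/lat matrix or an `occurrence_df`.
#' @param taxon optional label stored in the result.
#' @return A list of class `env_matrix` with `taxon`, `points` (matrix of
#'   retained points), `values` (n x d matrix) and `variables`; the number
#'   of dropped points is the attribute `n_dropped`.
#' @export
extract_values <- function(stack, pts, taxon = NA_character_) {
  if (inherits(pts, "occurrence_df")) {
    if (is.na(taxon) && nrow(pts) > 0) taxon <- pts$taxon[1]
    pts <- cbind(pts$lon, pts$lat)
  }
  pts <- as.matrix(pts)
  if (nrow(pts) == 0L) stop("no points given")
  idx <- cell_index(stack, pts)
  na_cell <- is.na(idx) | as.vector(stack$na_mask)[pmax(idx, 1L)]
  if (all(na_cell)) stop("all points fall on NA or off-grid cells")
  vals <- stack_values(stack, idx[!na_cell])
  out <- structure(
    list(taxon = taxon, points = pts[!na_cell, , drop = FALSE],
         values = vals, variables = names(stack$layers)),
    class = "env_matrix")
  attr(out, "n_dropped") <- sum(na_cell)
  out
}

#' @export
print.env_matrix <- function(x, ...) {
  cat(sprintf("<env_matrix> %s: %d points x %d variables\n",
              x$taxon, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Principal component analysis of environmental values with per-component
#' variable contributions
#'
#' Runs PCA on the pooled environmental matrix (centred; unit-variance
#' scaled by default, appropriate when variables carry incommensurate
#' units) and reports, per component, each variable's percent contribution
#' `100 * loading^2 / sum(loading^2)`. This is the usual way of reading
#' "relative variable importance" off a PCA.
#'
#' @param values numeric matrix (rows = observations) or an `env_matrix`.
#' @param scale unit-variance scale the columns (default `TRUE`).
#' @return A list of class `pca_importance` with `loadings` (d x d),
#'   `explained_fraction` (length d, non-increasing, sums to 1),
#'   `contributions` (d x d percent matrix, columns = components) and
#'   `top_contributors` (per component, variables sorted by contribution).
#' @export
pca_importance <- function(values, scale = TRUE) {
  if (inherits(values, "env_matrix")) values <- values$values
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  keep <- apply(values, 2, function(v) var(v) > 0)
  if (any(!keep))
    message(sum(!keep), " zero-variance column(s) dropped: ",
            paste(colnames(values)[!keep], collapse = ", "))
  values <- values[, keep, drop = FALSE]
  d <- ncol(values)
  if (d < 2) stop("fewer than 2 usable columns")
  if (nrow(values) <= d) stop("need more observations than variables")
  pc <- prcomp(values, center = TRUE, scale. = scale)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  contrib <- 100 * sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/")
  top <- lapply(seq_len(ncol(contrib)), function(j) {
    ord <- order(contrib[, j], decreasing = TRUE)
    data.frame(variable = rownames(contrib)[ord],
               percent = contrib[ord, j], row.names = NULL)
  })
  names(top) <- colnames(pc$rotation)
  structure(list(loadings = pc$rotation, explained_fraction = expl,
                 contributions = contrib, top_contributors = top,
                 center = pc$center,
                 scale = if (isTRUE(scale)) pc$scale else NULL),
            class = "pca_importance")
}

#' @export
print.pca_importance <- function(x, ...) {
  cat("<pca_importance>\n  explained:",
      paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = " "),
      "\n")
  for (j in seq_len(min(2, length(x$top_contributors)))) {
    t1 <- x$top_contributors[[j]][1:2, ]
    cat(sprintf("  PC%d top: %s (%.1f%%), %s (%.1f%%)\n", j,
                t1$variable[1], t1$percent[1], t1$variable[2], t1$percent[2]))
  }
  invisible(x)
}
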