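#' LDA confusion matrix of environmental group assignment
#'
#' Fits a linear discriminant analysis to labelled environmental vectors
#' and predicts the same rows (resubstitution), tabulating how often
#' records of each taxon are assigned back to their own taxon versus to
#' another. Row-normalised percentages: the diagonal is each taxon's
#' assignment accuracy; off-diagonal mass shows which taxa's environments
#' nest inside others'.
#'
#' @param values numeric matrix of environmental vectors.
#' @param labels taxon label per row.
#' @param prior `"proportional"` (group sizes, default) or `"uniform"`.
#' @param cv use leave-one-out cross-validation instead of resubstitution
#'   (default `FALSE`).
#' @return A list of class `confusion_matrix` with `labels`, `percent`
#'   (g x g row-stochastic, rows sum to 100) and `counts`.
#' @export
lda_confusion <- function(values, labels, prior = c("proportional", "uniform"),
                          cv = FALSE) {
  prior <- match.arg(prior)
  values <- as.matrix(values)
  labels <- factor(labels)
  g <- nlevels(labels)
  if (g < 2) stop("need at least 2 groups")
  tab <- table(labels)
  if (any(tab < 2)) stop("group(s) with fewer than 2 rows: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  if (any(tab <= ncol(values)))
    message("group(s) smaller than the number of variables; ",
            "pooled covariance used (standard LDA regularization)")
  pr <- if (prior == "uniform") rep(1 / g, g) else as.numeric(tab) / length(labels)
  if (cv) {
    fit <- MASS::lda(values, grouping = labels, prior = pr, CV = TRUE)
    pred <- fit$class
  } else {
    fit <- MASS::lda(values, grouping = labels, prior = pr)
    pred <- predict(fit, values)$class
  }
  counts <- table(true = labels, predicted = factor(pred, levels = levels(labels)))
  percent <- 100 * sweep(unclass(counts), 1, rowSums(counts), "/")
  structure(list(labels = levels(labels), percent = percent,
                 counts = unclass(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (row %, rows = true taxon)\n")
  print(round(x$percent, 1))
  invisible(x)
}

#' Seeded k-means assignment with restarts
#'
#' @param values numeric matrix.
#' @param k number of clusters (>= 1).
#' @param seed integer seed.
#' @param n_init random restarts (default 25).
#' @return A list with `cluster` (per-row ids), `wss` (total
#'   within-cluster sum of squares W_k) and `centers`.
#' @export
kmeans_assign <- function(values, k, seed = 1L, n_init = 25) {
  values <- as.matrix(values)
  stopifnot(k >= 1, nrow(values) >= k)
  fit <- with_seed_if(seed, {
    if (k == 1) {
      ctr <- matrix(colMeans(values), 1)
      list(cluster = rep(1L, nrow(values)),
           tot.withinss = sum(sweep(values, 2, ctr[1, ])^2),
           centers = ctr)
    } else {
      kmeans(values, centers = k, nstart = n_init, iter.max = 50)
    }
  })
  list(cluster = fit$cluster, wss = fit$tot.withinss, centers = fit$centers)
}

#' Gap statistic for choosing the number of k-means clusters
#'
#' Compares `log W_k` of the data to its expectation under B reference
#' data sets drawn uniformly over each feature's observed range
#' (Tibshirani et al.'s simplest reference). `Gap(k) = mean_b log W_k^(b)
#' - log W_k`; `se(k) = sd_b(log W_k^(b)) * sqrt(1 + 1/B)`. The selected
#' `k_best` is the smallest k with `Gap(k) >= Gap(k+1) - se(k+1)` (1-SE
#' rule), or `k_max` if none qualifies.
#'
#' @param values numeric matrix.
#' @param k_max largest k considered (>= 2).
#' @param B number of reference sets (default 100).
#' @param seed integer seed; the whole computation is reproducible
#'   bit-identically for a fixed seed.
#' @param n_init k-means restarts per fit (default 25).
#' @return A list of class `gap_stat` with `k_values`, `gap`, `se`,
#'   `log_w`, `k_best`.
#' @export
gap_statistic <- function(values, k_max, B = 100, seed = 1L, n_init = 25) {
  values <- as.matrix(values)
  stopifnot(k_max >= 2, nrow(values) > k_max)
  if (all(apply(values, 2, var) == 0)) stop("degenerate data: all rows identical")
  ks <- seq_len(k_max)
  with_seed_if(seed, {
    wk <- function(x, k) {
      if (k == 1) sum(sweep(x, 2, colMeans(x))^2)
      else kmeans(x, centers = k, nstart = n_init, iter.max = 50)$tot.withinss
    }
    log_w <- vapply(ks, function(k) log(wk(values, k)), 0)
    rng <- apply(values, 2, range)
    log_w_ref <- matrix(NA_real_, B, k_max)
    for (b in seq_len(B)) {
      ref <- vapply(seq_len(ncol(values)), function(j)
        runif(nrow(values), rng[1, j], rng[2, j]), numeric(nrow(values)))
      log_w_ref[b, ] <- vapply(ks, function(k) log(wk(ref, k)), 0)
    }
    gap <- colMeans(log_w_ref) - log_w
    se <- apply(log_w_ref, 2, sd) * sqrt(1 + 1 / B)
    ok <- which(gap[-k_max] >= gap[-1] - se[-1])
    k_best <- if (length(ok)) min(ok) else k_max
    structure(list(k_values = ks, gap = gap, se = se, log_w = log_w,
                   k_best = as.integer(k_best)),
              class = "gap_stat")
  })
}

#' @export
print.gap_stat <- function(x, ...) {
  cat(sprintf("<gap_stat> k_best = %d\n", x$k_best))
  print(data.frame(k = x$k_values, gap = round(x$gap, 4),
                   se = round(x$se, 4)))
  invisible(x)
}
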