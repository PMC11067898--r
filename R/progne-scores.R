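#' Published pairwise niche-comparison scores for Progne martins
#'
#' The published interspecific niche-equivalency score matrix for the
#' nine species of the martin genus *Progne* (background-similarity tests
#' on the -2..+2 scale; lower triangle, blank = no significant signal in
#' either direction, i.e. score 0 under the reporting convention used).
#' Shipped as a plain-text table; useful as a worked real-data example of
#' the score bookkeeping that [count_scores()] performs.
#'
#' @param blank_as_zero recode blank (untested/unreported) cells as 0
#'   (default `FALSE`, keeping them NA).
#' @return A 9 x 9 integer matrix with taxon dimnames, lower triangle
#'   holding the reported scores.
#' @export
progne_scores <- function(blank_as_zero = FALSE) {
  path <- system.file("extdata", "progne_interspecific_scores.csv",
                      package = "nichellipse", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$taxon
  storage.mode(m) <- "integer"
  if (blank_as_zero) m[lower.tri(m)][is.na(m[lower.tri(m)])] <- 0L
  m
}
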