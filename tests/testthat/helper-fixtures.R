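# Fixtures are built in code; nothing binary ships with the tests.

# deterministic 2-layer stack whose values are simple functions of the cell
# position, so expected extractions can be worked out by hand
grid_stack <- function(n_rows = 10, n_cols = 10, origin = c(0, 0),
                       cell_size = 1) {
  a <- outer(seq_len(n_rows), seq_len(n_cols), function(r, c) r + c / 100)
  b <- outer(seq_len(n_rows), seq_len(n_cols), function(r, c) r * c)
  env_stack(list(alpha = a, beta = b), origin = origin, cell_size = cell_size)
}

# axis-aligned rectangular accessible area
rect_area <- function(taxon, xmin, xmax, ymin, ymax) {
  accessible_area(taxon, rbind(c(xmin, ymin), c(xmax, ymin),
                               c(xmax, ymax), c(xmin, ymax)))
}

# small memoised worlds so several test files can share one build
.world_cache <- new.env(parent = emptyenv())
cached_world <- function(scenario, seed, ...) {
  key <- paste(scenario, seed, ...)
  if (is.null(.world_cache[[key]])) {
    args <- utils::modifyList(
      list(scenario = scenario, n_rows = 60, n_cols = 60, n_occ = 100,
           seed = seed),
      list(...))
    .world_cache[[key]] <- make_world(do.call(scenario_config, args))
  }
  .world_cache[[key]]
}

# independent even-odd ray-casting oracle (scalar, textbook form)
pip_oracle <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# exhaustive minimum-change count for a binary character on a tree, with
# uncertain tips free to take either state (independent of the package's
# Fitch/Hartigan code)
min_changes_oracle <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1):max(tree$edge)
  unc <- which(tip_states == "uncertain")
  best <- Inf
  states <- c("present", "absent")
  for (ia in seq_len(2^length(internal)) - 1) {
    int_lab <- states[as.integer(intToBits(ia))[seq_along(internal)] + 1]
    names(int_lab) <- internal
    for (it in seq_len(2^length(unc)) - 1) {
      lab <- tip_states
      if (length(unc))
        lab[unc] <- states[as.integer(intToBits(it))[seq_along(unc)] + 1]
      full <- c(lab, int_lab)
      names(full) <- c(seq_len(n_tip), internal)
      ch <- sum(full[as.character(tree$edge[, 1])] !=
                  full[as.character(tree$edge[, 2])])
      best <- min(best, ch)
    }
  }
  best
}
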