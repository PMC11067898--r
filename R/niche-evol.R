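#' Accessibility-aware niche bin table for one environmental variable
#'
#' Discretises one environmental variable into equal-width bins spanning
#' the union of all taxa's accessible (M) value ranges and codes every
#' taxon x bin cell as `"present"`, `"absent"` or `"uncertain"`:
#' a bin is present when it intersects the taxon's occupied interval
#' (a central quantile range of its occurrence values), uncertain when it
#' lies wholly outside the taxon's accessible value range (the taxon never
#' had access to those conditions, so nothing can be said), and absent
#' otherwise. Absent bins strictly between two present bins are recoded
#' present (niches are assumed interval-shaped). Conditioning on
#' accessibility keeps reconstruction from mistaking biogeographic
#' artefacts for niche limits.
#'
#' @param occ_values named list: per taxon, numeric vector of occurrence
#'   values of the variable.
#' @param m_values named list: per taxon, numeric vector of the variable's
#'   values over the taxon's accessible-area cells.
#' @param n_bins number of equal-width bins (default 20, >= 3).
#' @param trim total quantile mass trimmed off the occupied interval
#'   (default 0.05, i.e. the 2.5%–97.5% range; 0 disables).
#' @param variable optional variable name.
#' @return A list of class `niche_bin_table` with `variable`, `bin_edges`
#'   (length n_bins + 1) and `states` (taxon x bin character matrix).
#' @export
build_bin_table <- function(occ_values, m_values, n_bins = 20, trim = 0.05,
                            variable = NA_character_) {
  stopifnot(n_bins >= 3, trim >= 0, trim < 1)
  taxa <- names(occ_values)
  if (is.null(taxa) || !setequal(taxa, names(m_values)))
    stop("occ_values and m_values must be named lists over the same taxa")
  if (any(!vapply(occ_values, length, 0L)) || any(!vapply(m_values, length, 0L)))
    stop("every taxon needs occurrence and M values")
  rng <- range(unlist(m_values), na.rm = TRUE)
  if (diff(rng) == 0) stop("degenerate global range")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  states <- matrix("absent", length(taxa), n_bins,
                   dimnames = list(taxa, paste0("bin", seq_len(n_bins))))
  for (tx in taxa) {
    occ <- quantile(occ_values[[tx]], c(trim / 2, 1 - trim / 2), na.rm = TRUE,
                    names = FALSE)
    if (occ[1] > occ[2]) stop("empty occupied interval for ", tx)
    mr <- range(m_values[[tx]], na.rm = TRUE)
    if (mr[1] > rng[2] || mr[2] < rng[1])
      stop("M range of ", tx, " disjoint from the global range")
    for (b in seq_len(n_bins)) {
      lo <- edges[b]; hi <- edges[b + 1]
      if (occ[1] <= hi && occ[2] >= lo) states[tx, b] <- "present"
      else if (mr[1] >= hi || mr[2] <= lo) states[tx, b] <- "uncertain"
    }
    # interval smoothing: absent strictly between two presents -> present
    pres <- which(states[tx, ] == "present")
    if (length(pres) >= 2)
      states[tx, setdiff(seq(min(pres), max(pres)),
                         which(states[tx, ] != "absent"))] <- "present"
    if (!any(states[tx, ] == "present"))
      stop("taxon ", tx, " has no present bin")
  }
  structure(list(variable = variable, bin_edges = edges, states = states),
            class = "niche_bin_table")
}

#' @export
print.niche_bin_table <- function(x, ...) {
  cat(sprintf("<niche_bin_table> %s: %d taxa x %d bins\n", x$variable,
              nrow(x$states), ncol(x$states)))
  key <- c(present = "#", absent = ".", uncertain = "?")
  for (tx in rownames(x$states))
    cat(sprintf("  %-18s %s\n", tx, paste(key[x$states[tx, ]], collapse = "")))
  invisible(x)
}

# ---- Fitch/Hartigan parsimony --------------------------------------------

# state sets encoded as integers: 1 = {present}, 2 = {absent}, 3 = {both}
.enc <- c(present = 1L, absent = 2L, uncertain = 3L)

# children lists in the ape edge ordering
child_list <- function(tree) {
  n_node <- max(tree$edge)
  ch <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge)))
    ch[[tree$edge[e, 1]]] <- c(ch[[tree$edge[e, 1]]], tree$edge[e, 2])
  ch
}

# minimum-change reconstruction for one binary character with missing data.
# Downpass (Hartigan/Fitch): intersection of child sets if non-empty, else
# union (+1 change). Preorder resolution: root takes its downpass set; a
# child inherits the parent state when compatible, else its own singleton;
# nodes whose choice is arbitrary are flagged ambiguous. Ties in the
# resolved labelling break toward "present".
fitch_bin <- function(tree, tip_sets) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_node <- max(tree$edge)
  ch <- child_list(tree)
  down <- integer(n_node)
  down[seq_len(n_tip)] <- tip_sets
  changes <- 0L
  # recursive postorder over internal nodes (trees here are small)
  post <- integer(0)
  visit <- function(nd) {
    for (c in ch[[nd]]) if (c > n_tip) visit(c)
    post <<- c(post, nd)
  }
  visit(root)
  set_bits <- function(s) switch(s, c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
  bits <- matrix(FALSE, n_node, 2)
  for (i in seq_len(n_tip)) bits[i, ] <- set_bits(down[i])
  for (nd in post) {
    acc <- c(TRUE, TRUE)
    for (c in ch[[nd]]) {
      inter <- acc & bits[c, ]
      if (any(inter)) acc <- inter
      else { acc <- acc | bits[c, ]; changes <- changes + 1L }
    }
    bits[nd, ] <- acc
  }
  # preorder resolution
  resolved <- integer(n_node)       # 1 present, 2 absent
  ambiguous <- logical(n_node)
  pick <- function(b) if (b[1]) 1L else 2L   # tie -> present
  rb <- bits[root, ]
  resolved[root] <- pick(rb)
  ambiguous[root] <- all(rb)
  pre <- rev(post)
  for (nd in pre) {
    for (c in ch[[nd]]) {
      cb <- bits[c, ]
      if (cb[resolved[nd]]) {
        resolved[c] <- resolved[nd]
        ambiguous[c] <- all(cb) && ambiguous[nd] && c > n_tip
      } else {
        resolved[c] <- pick(cb)
        ambiguous[c] <- FALSE
      }
      if (c <= n_tip && all(cb)) ambiguous[c] <- TRUE # uncertain tip
    }
  }
  list(changes = changes, resolved = resolved, ambiguous = ambiguous)
}

#' Ancestral niche reconstruction over environmental bins
#'
#' For each bin of a [build_bin_table()] table, reconstructs
#' presence/absence at every internal node of the tree by minimum-change
#' (Fitch/Hartigan) parsimony, treating `uncertain` tips as missing
#' (compatible with both states). Nodes whose minimum-change state is not
#' unique are labelled `ambiguous` in `node_states`; branch gains and
#' losses are counted on a canonical minimum-change resolution (ties
#' resolved toward presence, children inheriting the parental state when
#' compatible).
#'
#' @param table a `niche_bin_table`.
#' @param tree a `phylo` object whose tips equal the table's taxa.
#' @return A list of class `ancestral_states` with `tree`, `node_states`
#'   (node x bin character matrix over present/absent/ambiguous; tip rows
#'   repeat the input coding), `resolved` (node x bin, present/absent),
#'   `changes` (per-bin minimum change counts; NA for bins skipped because
#'   every tip is uncertain) and `branch_changes` (per-edge data frame of
#'   bins gained and lost).
#' @export
reconstruct_bins <- function(table, tree) {
  stopifnot(inherits(table, "niche_bin_table"))
  validate_tree(tree)
  taxa <- rownames(table$states)
  if (!setequal(taxa, tree$tip.label))
    stop("table taxa and tree tips differ")
  states <- table$states[tree$tip.label, , drop = FALSE]
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  n_bin <- ncol(states)
  node_states <- matrix(NA_character_, n_node, n_bin,
                        dimnames = list(NULL, colnames(states)))
  resolved <- matrix(NA_character_, n_node, n_bin,
                     dimnames = list(NULL, colnames(states)))
  changes <- rep(NA_integer_, n_bin)
  lab <- c("present", "absent")
  for (b in seq_len(n_bin)) {
    tips <- .enc[states[, b]]
    if (all(tips == 3L)) {
      message("bin ", b, " skipped: all tips uncertain")
      next
    }
    fr <- fitch_bin(tree, tips)
    changes[b] <- fr$changes
    ns <- lab[fr$resolved]
    ns[fr$ambiguous] <- "ambiguous"
    ns[seq_len(n_tip)] <- states[, b]          # tips keep their input coding
    node_states[, b] <- ns
    resolved[, b] <- lab[fr$resolved]
  }
  edge <- tree$edge
  gained <- lost <- integer(nrow(edge))
  for (e in seq_len(nrow(edge))) {
    p <- resolved[edge[e, 1], ]; c <- resolved[edge[e, 2], ]
    ok <- !is.na(p) & !is.na(c)
    gained[e] <- sum(p[ok] == "absent" & c[ok] == "present")
    lost[e] <- sum(p[ok] == "present" & c[ok] == "absent")
  }
  branch_changes <- data.frame(parent = edge[, 1], child = edge[, 2],
                               gained = gained, lost = lost)
  structure(list(tree = tree, node_states = node_states, resolved = resolved,
                 changes = changes, branch_changes = branch_changes,
                 variable = table$variable),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf("<ancestral_states> %s: %d bins, total min changes %d\n",
              x$variable, length(x$changes), sum(x$changes, na.rm = TRUE)))
  invisible(x)
}

#' Per-branch niche expansion/contraction summary
#'
#' Tallies, for every branch, the bins gained (niche expansion) and lost
#' (contraction) along it, and flags each terminal taxon as
#' contraction-dominated when its terminal branch lost more bins than it
#' gained.
#'
#' @param anc an `ancestral_states` object.
#' @return A list with `branches` (parent, child, label, gained, lost,
#'   net) and `taxa` (taxon, gained, lost, contraction_dominated).
#' @export
summarize_evolution <- function(anc) {
  stopifnot(inherits(anc, "ancestral_states"))
  bc <- anc$branch_changes
  n_tip <- length(anc$tree$tip.label)
  bc$label <- ifelse(bc$child <= n_tip, anc$tree$tip.label[bc$child],
                     paste0("node", bc$child))
  bc$net <- bc$gained - bc$lost
  term <- bc[bc$child <= n_tip, ]
  taxa <- data.frame(taxon = term$label, gained = term$gained,
                     lost = term$lost,
                     contraction_dominated = term$lost > term$gained,
                     row.names = NULL)
  list(branches = bc[, c("parent", "child", "label", "gained", "lost", "net")],
       taxa = taxa)
}
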