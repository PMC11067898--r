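test_that("bin tables code presence, absence and inaccessibility", {
  # taxon a: occupied interval [2.1, 4.9], M range [0, 6]; taxon b spans all
  occ <- list(a = c(2.1, 4.9), b = c(1.5, 9.5))
  m <- list(a = c(0, 6), b = c(0, 10))
  tab <- build_bin_table(occ, m, n_bins = 10, trim = 0)
  expect_equal(unname(tab$states["a", ]),
               c("absent", "absent", "present", "present", "present",
                 "absent", rep("uncertain", 4)))
  expect_equal(unname(tab$states["b", ]),
               c("absent", rep("present", 9)))

  # taxon occupying the full global range: all bins present
  tab2 <- build_bin_table(list(a = c(0, 10), b = c(0, 10)),
                          list(a = c(0, 10), b = c(0, 10)),
                          n_bins = 5, trim = 0)
  expect_true(all(tab2$states == "present"))

  # M covering only the lower half: upper bins uncertain
  tab3 <- build_bin_table(list(a = c(1, 2), b = c(1, 9)),
                          list(a = c(0, 5), b = c(0, 10)),
                          n_bins = 10, trim = 0)
  expect_true(all(tab3$states["a", 6:10] == "uncertain"))

  # quantile trim shrinks the occupied run against outliers
  vals <- c(rep(5, 98), 0, 10)
  t_trim <- build_bin_table(list(a = vals, b = c(0, 10)),
                            list(a = c(0, 10), b = c(0, 10)),
                            n_bins = 10, trim = 0.05)
  expect_lt(sum(t_trim$states["a", ] == "present"), 10)

  # present runs are contiguous per taxon
  for (tx in rownames(tab$states)) {
    pres <- unname(which(tab$states[tx, ] == "present"))
    expect_equal(pres, seq(min(pres), max(pres)))
  }
})

test_that("grafting a sister taxon at the branch midpoint preserves paths", {
  tr <- read_newick_text("((dominicensis:2,sinaloae:1.5):1,subis:3);")
  g <- graft_taxon(tr, "cryptoleuca", "dominicensis")
  expect_equal(ape::Ntip(g), 4)
  # sister's terminal branch split in half; new tip gets the other half
  cd <- ape::cophenetic.phylo(g)
  expect_equal(cd["cryptoleuca", "dominicensis"], 2) # 1 + 1
  d_old <- ape::cophenetic.phylo(tr)
  expect_equal(cd[rownames(d_old), colnames(d_old)], d_old,
               tolerance = 1e-12)

  expect_error(graft_taxon(tr, "subis", "dominicensis"), "already present")
  expect_error(graft_taxon(tr, "x", "nope"), "not found")
  tr0 <- read_newick_text("((a:0,b:1):1,c:2);")
  expect_warning(graft_taxon(tr0, "x", "a"), "zero-length")
})

test_that("parsimony reconstruction handles constant and single-loss bins", {
  tr <- read_newick_text("((a:1,b:1):1,(c:1,(d:1,e:1):1):1);")
  tab <- structure(list(
    variable = "v", bin_edges = 0:3,
    states = matrix("present", 5, 3,
                    dimnames = list(c("a", "b", "c", "d", "e"), NULL))),
    class = "niche_bin_table")
  anc <- reconstruct_bins(tab, tr)
  expect_true(all(anc$changes == 0))
  expect_true(all(anc$node_states[, 1] == "present"))
  expect_true(all(anc$branch_changes$gained == 0 &
                    anc$branch_changes$lost == 0))

  # one tip absent: root present, a single loss on that terminal branch
  tab$states["d", 2] <- "absent"
  anc2 <- reconstruct_bins(tab, tr)
  expect_equal(anc2$changes[2], 1L)
  root <- length(tr$tip.label) + 1L
  expect_equal(anc2$node_states[root, 2], "present")
  lost_edge <- anc2$branch_changes[anc2$branch_changes$lost > 0, ]
  expect_equal(nrow(lost_edge), 1)
  expect_equal(lost_edge$child, match("d", tr$tip.label))
})

test_that("a balanced split leaves the root ambiguous with one change", {
  tr <- read_newick_text("((a:1,b:1):1,(c:1,d:1):1);")
  tab <- structure(list(
    variable = "v", bin_edges = 0:2,
    states = matrix(c("present", "present", "absent", "absent"), 4, 1,
                    dimnames = list(c("a", "b", "c", "d"), NULL))),
    class = "niche_bin_table")
  anc <- reconstruct_bins(tab, tr)
  expect_equal(anc$changes[1], 1L)
  expect_equal(anc$node_states[5, 1], "ambiguous") # root
  expect_equal(sum(anc$branch_changes$gained + anc$branch_changes$lost), 1)
  internal <- anc$branch_changes$child > 4
  expect_equal(sum(anc$branch_changes$lost[internal]), 1)
})

test_that("Fitch change counts equal exhaustive enumeration", {
  states <- c("present", "absent", "uncertain")
  set.seed(17)
  for (rep in 1:12) {
    n_tip <- sample(3:6, 1)
    tr <- ape::rphylo(n_tip, 1, 0)
    tip_states <- sample(states, n_tip, replace = TRUE,
                         prob = c(0.4, 0.4, 0.2))
    if (all(tip_states == "uncertain")) tip_states[1] <- "present"
    tab <- structure(list(variable = "v", bin_edges = 0:2,
                          states = matrix(tip_states, n_tip, 1,
                                          dimnames = list(tr$tip.label, NULL))),
                     class = "niche_bin_table")
    anc <- reconstruct_bins(tab, tr)
    expect_equal(anc$changes[1], min_changes_oracle(tr, tip_states),
                 info = paste("rep", rep))
    # the canonical resolution attains the same count
    expect_equal(sum(anc$branch_changes$gained + anc$branch_changes$lost),
                 anc$changes[1])
  }
})

test_that("reconstruction is invariant to tip order permutation", {
  tr <- read_newick_text("((a:1,b:1):1,(c:1,(d:1,e:1):1):1);")
  st <- c(a = "present", b = "absent", c = "present", d = "uncertain",
          e = "absent")
  mk <- function(ord) structure(
    list(variable = "v", bin_edges = 0:2,
         states = matrix(st[ord], 5, 1, dimnames = list(ord, NULL))),
    class = "niche_bin_table")
  a1 <- reconstruct_bins(mk(names(st)), tr)
  a2 <- reconstruct_bins(mk(rev(names(st))), tr)
  expect_identical(a1$node_states, a2$node_states)
  expect_identical(a1$changes, a2$changes)
})

test_that("all-uncertain bins are skipped with a report", {
  tr <- read_newick_text("((a:1,b:1):1,c:1);")
  tab <- structure(list(variable = "v", bin_edges = 0:3,
                        states = matrix(c(rep("uncertain", 3),
                                          rep("present", 3)), 3, 2,
                                        dimnames = list(c("a", "b", "c"),
                                                        NULL)),
                        class = "niche_bin_table"),
                   class = "niche_bin_table")
  expect_message(anc <- reconstruct_bins(tab, tr), "skipped")
  expect_true(is.na(anc$changes[1]))
  expect_equal(anc$changes[2], 0L)
})

test_that("evolution summaries count gains/losses as Hamming distances", {
  tr <- read_newick_text("((a:1,b:1):1,c:1);")
  tab <- structure(list(variable = "v", bin_edges = 0:4,
                        states = matrix(c("present", "absent", "present",
                                          "present", "present", "present",
                                          "absent", "absent", "present",
                                          "absent", "present", "present"),
                                        3, 4,
                                        dimnames = list(c("a", "b", "c"),
                                                        NULL))),
                   class = "niche_bin_table")
  anc <- reconstruct_bins(tab, tr)
  sm <- summarize_evolution(anc)
  for (e in seq_len(nrow(anc$branch_changes))) {
    p <- anc$resolved[anc$branch_changes$parent[e], ]
    c_ <- anc$resolved[anc$branch_changes$child[e], ]
    expect_equal(sm$branches$gained[e] + sm$branches$lost[e],
                 sum(p != c_))
  }
})

test_that("range-partitioning descendants read as niche contraction", {
  w <- cached_world("partitioning", seed = 19)
  taxa <- names(w$occurrences)
  # examine the environmental axis the ancestral niche was split along
  iv <- which.max(abs(w$true_models[[1]]$center - w$true_models[[2]]$center))
  occ_vals <- lapply(taxa, function(tx)
    extract_values(w$stack, w$occurrences[[tx]], tx)$values[, iv])
  m_vals <- lapply(taxa, function(tx)
    stack_values(w$stack, area_cells(w$stack, w$areas[[tx]]))[, iv])
  names(occ_vals) <- names(m_vals) <- taxa
  tab <- build_bin_table(occ_vals, m_vals, n_bins = 30, trim = 0)
  anc <- reconstruct_bins(tab, w$tree)
  sm <- summarize_evolution(anc)
  expect_true(all(sm$taxa$contraction_dominated))
})
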