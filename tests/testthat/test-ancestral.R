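# A hand-built posterior matrix stands in for an MCMC trace: assignment
# logic is deterministic given the per-node state posteriors.
toy_assignments <- function() {
  tree <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  post <- rbind("5" = c(0.01, 0.99), "6" = c(0.02, 0.98), "7" = c(0.5, 0.5))
  tree$clade_pp <- c(NA, 0.95, NA)  # root, then the two inner nodes
  list(tree = tree, post = post)
}

test_that("corrected posteriors follow the product rule and threshold", {
  ta <- toy_assignments()
  asn <- assign_nodes(ta$post, ta$tree, threshold = 0.95)
  # root: pp 1 so corrected = raw 0.99 -> called
  expect_equal(asn$corrected1[1], 0.99)
  expect_equal(asn$decision[1], "state-1")
  # node with clade support 0.95: 0.98 x 0.95 = 0.931 -> ambiguous
  expect_equal(asn$corrected1[2], 0.98 * 0.95)
  expect_equal(asn$decision[2], "ambiguous")
  # flat posterior stays ambiguous regardless of support
  expect_equal(asn$decision[3], "ambiguous")
  expect_true(all(asn$corrected1 <= asn$p_state1 + 1e-15))
  expect_error(assign_nodes(ta$post, ta$tree, threshold = 0.4), "0.5")
  expect_error(assign_nodes(ta$post, ta$tree, threshold = 1.01), "0.5")
})

test_that("raising the threshold never creates new definite calls", {
  ta <- toy_assignments()
  lo <- assign_nodes(ta$post, ta$tree, threshold = 0.9)
  hi <- assign_nodes(ta$post, ta$tree, threshold = 0.99)
  became_definite <- lo$decision == "ambiguous" & hi$decision != "ambiguous"
  expect_false(any(became_definite))
})

test_that("stem propagation holds node probabilities constant along stems", {
  ta <- toy_assignments()
  asn <- assign_nodes(ta$post, ta$tree)
  tips <- c(A = "1", B = "1", C = "0", D = "0")
  stems <- propagate_stems(asn, ta$tree, tip_states = tips)
  # node 6 (age 2) subtends the stem [2, 3): constant value anywhere on it
  for (age in c(2.0, 2.3, 2.7, 2.999)) {
    q <- stem_probabilities(stems, age)
    expect_equal(q$p_state1[q$node == 6], 0.98)
  }
  # at a node's exact age the node's own stem is read, not its daughters'
  q1 <- stem_probabilities(stems, 2)
  expect_true(6 %in% q1$node)
  expect_false(7 %in% q1$node)  # daughter stem [1, 2) excludes age 2
  expect_error(stem_probabilities(stems, 99), "root age")
  # values change only at node ages
  ages <- sort(unique(ta$tree$node_age))
  probe <- seq(0.05, root_age(ta$tree) - 0.05, by = 0.05)
  sig <- vapply(probe, function(a) {
    q <- stem_probabilities(stems, a)
    paste(q$node[order(q$node)], round(q$p_state1[order(q$node)], 6),
          collapse = ";")
  }, character(1))
  change_at <- probe[which(sig[-1] != sig[-length(sig)]) + 1]
  expect_true(all(vapply(change_at, function(a)
    any(abs(a - ages) < 0.051), logical(1))))
})

test_that("origin dating returns the stem top of the oldest passing clade", {
  ta <- toy_assignments()
  asn <- assign_nodes(ta$post, ta$tree)
  # root passes -> origin at root age
  org <- date_origin(asn, ta$tree, derived_state = "1")
  expect_true(org$detected)
  expect_equal(org$age, root_age(ta$tree))

  # only a mid-depth node passes -> origin at that node's stem top
  post2 <- rbind("5" = c(0.5, 0.5), "6" = c(0.5, 0.5), "7" = c(0.01, 0.99))
  tree2 <- ta$tree; tree2$clade_pp <- rep(NA_real_, 3)
  asn2 <- assign_nodes(post2, tree2)
  org2 <- date_origin(asn2, tree2, derived_state = "1")
  expect_equal(org2$node, 7)
  expect_equal(org2$age, 2)  # parent (node 6) sits at age 2

  # nothing passes -> undetected
  post3 <- matrix(0.5, 3, 2, dimnames = list(5:7, NULL))
  asn3 <- assign_nodes(post3, tree2)
  org3 <- date_origin(asn3, tree2, derived_state = "1")
  expect_false(org3$detected)
  expect_true(is.na(org3$age))
})

test_that("origin dating on the fixture recovers the planted stem age", {
  fx <- load_fixture(fixture_dir())
  planted <- ape::getMRCA(fx$tree, names(fx$ranges)[fx$ranges == "F"])
  stem_top <- fx$tree$node_age[fx$tree$edge[match(planted, fx$tree$edge[, 2]), 1]]
  hab <- habitat_as_trait(fx$tree, fx$ranges,
                          mcmc_config("test", seed = 271))
  org <- date_origin(hab$assignments, fx$tree, trait = "habitat",
                     derived_state = "1", tip_states = hab$states)
  expect_true(org$detected)
  expect_equal(org$age, stem_top, tolerance = 1e-6)
})

test_that("lineage timeline conserves counts and matches tree structure", {
  ta <- toy_assignments()
  asn <- assign_nodes(ta$post, ta$tree)
  tips <- c(A = "1", B = "1", C = "0", D = "0")
  tl <- lineage_timeline(asn, ta$tree, tip_states = tips, interval = 0.5)
  expect_equal(tl$total, tl[[2]] + tl[[3]] + tl$ambiguous)
  expect_equal(tl$total[tl$age == 0], 4)               # all tips
  expect_equal(tl$total[tl$age == 2.5], 2)             # just below the root
  expect_error(lineage_timeline(asn, ta$tree, tip_states = tips,
                                interval = 0), "> 0")
})

test_that("timeline totals never decrease toward the present on a birth-only tree", {
  tree <- simulate_tree(40, 100, birth = 0.1, death = 0, seed = 91)
  post <- matrix(0.5, tree$Nnode, 2,
                 dimnames = list(length(tree$tip.label) + seq_len(tree$Nnode),
                                 NULL))
  asn <- assign_nodes(post, tree)
  tips <- setNames(rep("1", 40), tree$tip.label)
  tl <- lineage_timeline(asn, tree, tip_states = tips, interval = 10)
  # ages ascend in the output, so totals must be non-increasing with age
  expect_true(all(diff(tl$total) <= 0))
})
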