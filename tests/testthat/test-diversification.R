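test_that("stem rates follow log(N)/t with input validation", {
  expect_equal(stem_rate(1, 5), 0)
  expect_equal(stem_rate(1, 123.4), 0)
  expect_equal(stem_rate(10, 20), log(10) / 20)
  expect_equal(stem_rate(10, 20, log_base = "10"), log10(10) / 20)
  expect_error(stem_rate(0, 5), ">= 1")
  expect_error(stem_rate(2.5, 5), ">= 1")
  expect_error(stem_rate(10, 0), "> 0")
  # decreasing in stem age for fixed N > 1
  expect_true(all(diff(stem_rate(10, c(5, 10, 20, 40))) < 0))
})

test_that("rate-ratio summaries average defined ratios only", {
  ev <- data.frame(event = c("D1", "D2", "D3"), node = 1:3, age = c(3, 2, 1),
                   ratio = c(2, 6, NA))
  s <- rate_ratio_summary(ev)
  expect_equal(s$mean_ratio, 4)
  expect_equal(s$geometric_mean_ratio, sqrt(12))
  expect_equal(s$n_undefined, 1)
  ev1 <- data.frame(event = "D1", node = 1, age = 3, ratio = 1)
  expect_equal(rate_ratio_summary(ev1)$mean_ratio, 1)
  expect_error(rate_ratio_summary(ev[3, ]), "undefined")
  expect_error(rate_ratio_summary(ev[0, ]), "no divergence events")
})

# Truth-based assignments: internal node habitats known from simulation.
truth_assignments <- function(tree) {
  nh <- attr(tree, "node_habitat")
  ntip <- length(tree$tip.label)
  data.frame(node = ntip + seq_len(tree$Nnode),
             p_state0 = as.numeric(nh == "N"),
             p_state1 = as.numeric(nh == "F"),
             decision = ifelse(nh == "F", "state-1", "state-0"))
}

test_that("divergence events are found exactly where habitats split", {
  fx <- load_fixture(fixture_dir())
  hab <- habitat_as_trait(fx$tree, fx$ranges, mcmc_config("test", seed = 651))
  ev <- find_divergence_events(hab$assignments, fx$tree, fx$species_counts,
                               tip_states = hab$states)
  planted <- ape::getMRCA(fx$tree, names(fx$ranges)[fx$ranges == "F"])
  parent <- fx$tree$edge[match(planted, fx$tree$edge[, 2]), 1]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$node, parent)
  expect_equal(ev$event, "D1")
  expect_true(ev$ratio_defined)

  # all-fireprone assignments yield no events
  all1 <- hab$assignments
  all1$p_state1 <- 1; all1$p_state0 <- 0; all1$decision <- "state-1"
  tips1 <- setNames(rep("1", length(fx$tree$tip.label)), fx$tree$tip.label)
  ev0 <- find_divergence_events(all1, fx$tree, fx$species_counts,
                                tip_states = tips1)
  expect_equal(nrow(ev0), 0)

  # raising the threshold can only drop events
  ev99 <- find_divergence_events(hab$assignments, fx$tree, fx$species_counts,
                                 tip_states = hab$states, threshold = 0.99)
  expect_true(all(ev99$node %in% ev$node))

  # missing species counts are reported by tip name
  sc <- fx$species_counts[-1]
  expect_error(find_divergence_events(hab$assignments, fx$tree, sc,
                                      tip_states = hab$states),
               names(fx$species_counts)[1])
})

test_that("the fireprone side is always the ratio numerator", {
  tree <- simulate_tree(60, 113, seed = 841,
                        habitat = list(birth_mult = 4, q_NF = 0.01,
                                       q_FN = 0.005))
  asn <- truth_assignments(tree)
  tips <- setNames(ifelse(attr(tree, "habitat") == "F", "1", "0"),
                   names(attr(tree, "habitat")))
  counts <- setNames(rep(1L, length(tree$tip.label)), tree$tip.label)
  ev <- find_divergence_events(asn, tree, counts, tip_states = tips)
  skip_if(nrow(ev) == 0)
  for (r in seq_len(nrow(ev))) {
    expect_equal(ev$R_fire[r], stem_rate(ev$N_fire[r], ev$t_fire[r]))
    expect_equal(ev$ratio[r] * ev$R_nonfire[r], ev$R_fire[r],
                 tolerance = 1e-12)
  }
})

test_that("estimated rate ratios grow with the fireprone birth multiplier", {
  mean_ratio <- function(k) {
    rs <- vapply(1:6, function(i) {
      tree <- simulate_tree(60, 113, seed = 800 + 10 * k + i,
                            habitat = list(birth_mult = k, q_NF = 0.01,
                                           q_FN = 0.005))
      asn <- truth_assignments(tree)
      tips <- setNames(ifelse(attr(tree, "habitat") == "F", "1", "0"),
                       names(attr(tree, "habitat")))
      counts <- setNames(rep(1L, length(tree$tip.label)), tree$tip.label)
      ev <- find_divergence_events(asn, tree, counts, tip_states = tips)
      if (!nrow(ev) || all(is.na(ev$ratio))) return(NA_real_)
      mean(ev$ratio, na.rm = TRUE)
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }
  ms <- vapply(c(1, 2, 4), mean_ratio, numeric(1))
  expect_true(all(diff(ms) > 0))
  # a 4x birth-rate contrast lands in the expected ratio band
  expect_gt(ms[3], 2)
  expect_lt(ms[3], 8)
})
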