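test_that("rate matrices place rates off-diagonal with zero row sums", {
  expect_equal(unname(build_rate_matrix(mk_model(0, 0))), matrix(0, 2, 2))
  Q <- build_rate_matrix(mk_model(0.02, 0.05))
  expect_equal(unname(Q), matrix(c(-0.02, 0.05, 0.02, -0.05), 2, 2))
  expect_error(mk_model(-0.1, 0.2), ">= 0")

  # dependent pair model: 8 free cells, 4 structural zeros (double flips)
  pm <- pair_model(seq(0.01, 0.08, by = 0.01))
  Qp <- build_rate_matrix(pm)
  expect_equal(rowSums(Qp), rep(0, 4), ignore_attr = TRUE)
  expect_equal(Qp["00", "11"], 0)
  expect_equal(Qp["11", "00"], 0)
  expect_equal(Qp["01", "10"], 0)
  expect_equal(Qp["10", "01"], 0)
  expect_equal(sum(Qp[upper.tri(Qp) | lower.tri(Qp)] > 0), 8)
})

test_that("transition probabilities match the 2-state closed form", {
  Q <- build_rate_matrix(mk_model(0.05, 0.05))
  expect_equal(unname(transition_probs(Q, 0)), diag(2))
  P <- transition_probs(Q, 10)
  expect_equal(P[1, 1], 0.5 * (1 + exp(-2 * 0.05 * 10)), tolerance = 1e-12)
  expect_error(transition_probs(Q, -1), ">= 0")

  # asymmetric rates converge to the stationary distribution
  Qa <- build_rate_matrix(mk_model(0.02, 0.05))
  Pinf <- transition_probs(Qa, 1e4)
  expect_equal(unname(Pinf[1, ]), c(5 / 7, 2 / 7), tolerance = 1e-10)
  expect_equal(unname(Pinf[2, ]), c(5 / 7, 2 / 7), tolerance = 1e-10)

  # row-stochastic across a (q, t) grid
  for (q in c(0.001, 0.1, 2)) for (t in c(0.1, 10, 200)) {
    P <- transition_probs(build_rate_matrix(mk_model(q, q / 2)), t)
    expect_equal(rowSums(P), c(1, 1), ignore_attr = TRUE, tolerance = 1e-10)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("pruning likelihood reproduces simple limits", {
  cherry <- parse_newick("(A:1,B:1);")
  # zero rates: both tips share the root state, uniform prior gives 1/2
  expect_equal(exp(prune_log_likelihood(cherry, c(A = "1", B = "1"),
                                        mk_model(0, 0))), 0.5)
  # saturated rates: tips independent uniform, 1/4
  expect_equal(exp(prune_log_likelihood(cherry, c(A = "1", B = "1"),
                                        mk_model(50, 50))), 0.25,
               tolerance = 1e-6)
  expect_error(prune_log_likelihood(cherry, c(A = "1"), mk_model(1, 1)),
               "missing")
  expect_warning(
    ll <- prune_log_likelihood(cherry, c(A = "ambiguous", B = "ambiguous"),
                               mk_model(0.1, 0.1)),
    "all tips ambiguous")
  expect_equal(ll, 0)
})

test_that("pruning equals the enumeration oracle on random trees", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    tree <- random_chronogram(n, seed = 1000 + i)
    m <- mk_model(runif(1, 0.01, 0.6), runif(1, 0.01, 0.6))
    st <- setNames(sample(c("0", "1", "ambiguous"), n, replace = TRUE),
                   tree$tip.label)
    ours <- prune_log_likelihood(tree, st, m)
    orc <- enum_loglik(tree, allowed_from_binary(st, tree$tip.label),
                       build_rate_matrix(m), rep(0.5, 2))
    expect_lt(abs(ours - orc), 1e-10)
  }
})

test_that("likelihood is invariant to tip order", {
  tree <- random_chronogram(6, seed = 5)
  m <- mk_model(0.1, 0.3)
  st <- setNames(c("0", "1", "1", "0", "ambiguous", "1"), tree$tip.label)
  ll1 <- prune_log_likelihood(tree, st, m)
  ll2 <- prune_log_likelihood(tree, st[sample(names(st))], m)
  expect_equal(ll1, ll2)
})

test_that("independent pair likelihood equals the product of marginals", {
  tree <- random_chronogram(12, seed = 8, crown = 50)
  stA <- simulate_trait(tree, mk_model(0.05, 0.02), seed = 1)$tip_states
  stB <- simulate_trait(tree, mk_model(0.01, 0.04), seed = 2)$tip_states
  joint <- setNames(as.list(paste0(stA, stB)), names(stA))
  pm <- pair_model(c(gain_a = 0.05, loss_a = 0.02, gain_b = 0.01,
                     loss_b = 0.04), dependent = FALSE)
  expect_equal(prune_log_likelihood(tree, joint, pm),
               prune_log_likelihood(tree, stA, mk_model(0.05, 0.02)) +
                 prune_log_likelihood(tree, stB, mk_model(0.01, 0.04)),
               tolerance = 1e-10)
})

test_that("clumped tip data favor low rates", {
  tree <- random_chronogram(16, seed = 9, crown = 50)
  st <- setNames(rep("1", 16), tree$tip.label)
  expect_gt(prune_log_likelihood(tree, st, mk_model(1e-4, 1e-4)),
            prune_log_likelihood(tree, st, mk_model(2, 2)))
})

test_that("pruning agrees with an external Mk implementation", {
  skip_if_not_installed("phytools")
  tree <- random_chronogram(15, seed = 12, crown = 80)
  m <- mk_model(0.04, 0.09)
  st <- simulate_trait(tree, m, seed = 3)$tip_states
  skip_if(length(unique(st)) < 2)
  Q <- build_rate_matrix(m)
  ft <- phytools::fitMk(structure(tree, class = "phylo"),
                        setNames(factor(st, levels = c("0", "1")), names(st)),
                        fixedQ = Q, pi = "equal")
  expect_equal(prune_log_likelihood(tree, st, m), unclass(logLik(ft)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("trait simulation is seed-reproducible and respects the model", {
  tree <- random_chronogram(10, seed = 21)
  m <- mk_model(0.1, 0.1)
  s1 <- simulate_trait(tree, m, seed = 7)
  s2 <- simulate_trait(tree, m, seed = 7)
  expect_identical(s1, s2)
  s3 <- simulate_trait(tree, m, seed = 8)
  expect_false(identical(s1$tip_states, s3$tip_states))

  # zero rates with the root pinned to state 1: every tip is 1
  frozen <- simulate_trait(tree, mk_model(0, 0, root_prior = c(0, 1)), seed = 1)
  expect_true(all(frozen$tip_states == "1"))
})

test_that("one-branch simulation frequencies match transition probabilities", {
  # 5000 cherries with 10-My branches and root pinned at 0: the 10,000 tip
  # outcomes are independent one-branch simulations
  cherry <- parse_newick("(A:10,B:10);")
  m <- mk_model(0.02, 0.05, root_prior = c(1, 0))
  hits <- 0
  for (i in 1:5000) hits <- hits +
    sum(simulate_trait(cherry, m, seed = i)$tip_states == "1")
  p <- transition_probs(build_rate_matrix(m), 10)[1, 2]
  n <- 10000
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 3 * se)
})
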