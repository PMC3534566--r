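PAIR_STATES <- c("00", "01", "10", "11")

#' Two-state Mk model of a binary trait
#'
#' Continuous-time Markov model with instantaneous gain rate `q01`
#' (state 0 to 1) and loss rate `q10`, in events per My.
#'
#' @param q01,q10 non-negative transition rates (events/My).
#' @param root_prior `"uniform"` (default), `"stationary"`, or a length-2
#'   probability vector over states `(0, 1)`.
#' @return an object of class `mk_model`.
#' @export
mk_model <- function(q01, q10, root_prior = "uniform") {
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
  structure(list(states = c("0", "1"), rates = c(q01 = q01, q10 = q10),
                 root_prior = root_prior),
            class = c("mk_model", "trait_model"))
}

#' Four-state model of a pair of binary traits
#'
#' Joint states are `00, 01, 10, 11` (first digit = trait A, second =
#' trait B). The dependent model has 8 free single-step rates `q12, q13,
#' q21, q24, q31, q34, q42, q43` (the conventional numbering of the joint
#' states as 1--4); simultaneous double transitions (`00<->11`, `01<->10`) have rate 0
#' structurally. The independent model ties these to 4 free rates: trait-A
#' gain/loss and trait-B gain/loss, each identical in both backgrounds of
#' the other trait.
#'
#' @param rates for `dependent = TRUE` a named or positional vector of the 8
#'   rates above; for `dependent = FALSE` a vector of 4 rates
#'   `(gain_a, loss_a, gain_b, loss_b)`.
#' @param dependent logical flag selecting the 8-rate or tied 4-rate model.
#' @param root_prior as in [mk_model()], over the 4 joint states.
#' @return an object of class `pair_model`.
#' @export
pair_model <- function(rates, dependent = TRUE, root_prior = "uniform") {
  n <- if (dependent) 8L else 4L
  if (length(rates) != n) stop("expected ", n, " rates")
  if (any(rates < 0)) stop("rates must be >= 0")
  nm <- if (dependent) c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
        else c("gain_a", "loss_a", "gain_b", "loss_b")
  if (!is.null(names(rates)) && all(nm %in% names(rates))) rates <- rates[nm]
  structure(list(states = PAIR_STATES, rates = setNames(as.numeric(rates), nm),
                 dependent = dependent, root_prior = root_prior),
            class = c("pair_model", "trait_model"))
}

# Off-diagonal cell map (row, col, free-rate index), all 1-based.
# One map per model family; the MCMC kernel ties Q cells to free rates
# through this structure.
rate_cells <- function(model) {
  if (inherits(model, "mk_model")) {
    cbind(i = c(1, 2), j = c(2, 1), rate = c(1, 2))
  } else if (inherits(model, "pair_model")) {
    # states 1=00, 2=01, 3=10, 4=11; single-step transitions only
    cells <- cbind(i = c(1, 1, 2, 2, 3, 3, 4, 4),
                   j = c(2, 3, 1, 4, 1, 4, 2, 3))
    if (model$dependent) {
      cbind(cells, rate = 1:8)
    } else {
      # cell order above: 1->2(gain_b) 1->3(gain_a) 2->1(loss_b) 2->4(gain_a)
      #                   3->1(loss_a) 3->4(gain_b) 4->2(loss_a) 4->3(loss_b)
      rate <- c(3, 1, 4, 1, 2, 3, 2, 4)
      cbind(cells, rate = rate)
    }
  } else stop("unknown model class")
}

#' Instantaneous rate matrix of a trait model
#'
#' @param model an [mk_model()] or [pair_model()].
#' @return square matrix with the model's rates off-diagonal and the diagonal
#'   set so each row sums to zero; state names on dimnames.
#' @export
build_rate_matrix <- function(model) {
  k <- length(model$states)
  Q <- matrix(0, k, k, dimnames = list(model$states, model$states))
  cells <- rate_cells(model)
  for (r in seq_len(nrow(cells)))
    Q[cells[r, 1], cells[r, 2]] <- model$rates[cells[r, 3]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probabilities over a time interval
#'
#' Computes `exp(Q t)` by scaling-and-squaring.
#'
#' @param Q a rate matrix (rows sum to 0, off-diagonal >= 0).
#' @param t duration in My, `t >= 0`.
#' @return row-stochastic matrix of transition probabilities.
#' @export
transition_probs <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  P <- expm_cpp(as.matrix(Q), t)
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  P
}

root_prior_vec <- function(model) {
  rp <- model$root_prior
  k <- length(model$states)
  if (is.character(rp)) {
    if (rp == "uniform") return(rep(1 / k, k))
    if (rp == "stationary") {
      Q <- build_rate_matrix(model)
      # left null vector of Q, normalized
      e <- eigen(t(Q))
      i <- which.min(abs(e$values))
      v <- abs(Re(e$vectors[, i]))
      if (sum(v) == 0) return(rep(1 / k, k))
      return(v / sum(v))
    }
    stop("unknown root prior '", rp, "'")
  }
  if (length(rp) != k || any(rp < 0)) stop("invalid root prior vector")
  rp / sum(rp)
}

# Partial-likelihood row per tip: 1 for each state compatible with the
# observation; ambiguity coding gives 1 in every permitted state.
tip_partials <- function(states, model) {
  k <- length(model$states)
  ntip <- length(states)
  part <- matrix(0, ntip, k)
  if (k == 2) {
    for (i in seq_len(ntip)) {
      part[i, ] <- switch(states[[i]],
        "0" = c(1, 0), "1" = c(0, 1), "ambiguous" = c(1, 1),
        stop("unknown state '", states[[i]], "'"))
    }
  } else {
    # states given as joint codes, or as pairs c(a, b) with per-trait ambiguity
    for (i in seq_len(ntip)) {
      s <- states[[i]]
      if (length(s) == 2) {
        a_ok <- if (s[1] == "ambiguous") c(0, 1) else as.integer(s[1])
        b_ok <- if (s[2] == "ambiguous") c(0, 1) else as.integer(s[2])
        for (a in a_ok) for (b in b_ok)
          part[i, match(paste0(a, b), PAIR_STATES)] <- 1
      } else if (s == "ambiguous") {
        part[i, ] <- 1
      } else {
        part[i, match(s, PAIR_STATES)] <- 1
      }
    }
  }
  part
}

# Postorder edge representation shared by the likelihood and MCMC kernels.
tree_kernel_data <- function(tree) {
  phy <- ape::reorder.phylo(tree, "postorder")
  list(edge = phy$edge - 1L,  # 0-based for C++
       elen = phy$edge.length,
       ntip = length(phy$tip.label),
       nnode_tot = length(phy$tip.label) + phy$Nnode,
       root = length(phy$tip.label),  # 0-based id of ntip+1
       tip_order = phy$tip.label)
}

# states: for mk models a named character vector over tips; for pair models a
# named list (or data frame columns combined upstream).
states_for_tree <- function(states, tip_labels) {
  if (is.null(names(states))) stop("tip states must be named by taxon")
  miss <- setdiff(tip_labels, names(states))
  if (length(miss)) stop("missing taxon in trait data: ", paste(miss, collapse = ", "))
  states[tip_labels]
}

#' Pruning-algorithm log-likelihood of tip states under a trait model
#'
#' Felsenstein's post-order pruning over the chronogram. Ambiguous tips
#' contribute a partial likelihood of 1 in every permitted state; the root is
#' combined with the model's root prior.
#'
#' @param tree a `chronogram`.
#' @param states named character vector of tip states (`"0"`, `"1"`,
#'   `"ambiguous"` for Mk models; joint codes `"00"`... or length-2 vectors in
#'   a named list for pair models).
#' @param model an [mk_model()] or [pair_model()].
#' @return the log-likelihood (natural log).
#' @export
prune_log_likelihood <- function(tree, states, model) {
  kd <- tree_kernel_data(tree)
  states <- states_for_tree(states, kd$tip_order)
  if (all(vapply(states, function(s) identical(s, "ambiguous") ||
                 all(s == "ambiguous"), logical(1))))
    warning("all tips ambiguous: likelihood is 1 (log-likelihood 0)")
  part <- tip_partials(states, model)
  Q <- build_rate_matrix(model)
  ctmc_loglik_cpp(kd$edge, kd$elen, kd$ntip, kd$nnode_tot, kd$root, part,
                  unname(Q), root_prior_vec(model))
}

#' Simulate a trait along a chronogram
#'
#' Draws the root state from the model's root prior and evolves states down
#' each branch with transition probabilities `exp(Q * branch length)`.
#'
#' @inheritParams prune_log_likelihood
#' @param seed integer seed; the simulation is bit-reproducible given
#'   `(tree, model, seed)`.
#' @return list with `tip_states` (named character vector) and `node_states`
#'   (latent internal-node states, named by ape node id) for recovery tests.
#' @export
simulate_trait <- function(tree, model, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  phy <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(phy$tip.label)
  k <- length(model$states)
  Q <- build_rate_matrix(model)
  state <- integer(ntip + phy$Nnode)
  state[ntip + 1L] <- sample.int(k, 1, prob = root_prior_vec(model))
  # cladewise order guarantees parents precede children
  Pcache <- list()
  for (e in seq_len(nrow(phy$edge))) {
    t <- phy$edge.length[e]
    key <- format(t, digits = 15)
    P <- Pcache[[key]]
    if (is.null(P)) { P <- transition_probs(Q, t); Pcache[[key]] <- P }
    state[phy$edge[e, 2]] <- sample.int(k, 1, prob = P[state[phy$edge[e, 1]], ])
  }
  tips <- setNames(model$states[state[seq_len(ntip)]], phy$tip.label)
  nodes <- setNames(model$states[state[(ntip + 1L):(ntip + phy$Nnode)]],
                    ntip + seq_len(phy$Nnode))
  list(tip_states = tips, node_states = nodes)
}
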