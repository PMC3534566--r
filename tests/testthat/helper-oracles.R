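# Independent oracles used across the suite. They avoid the package's
# likelihood kernels: transition matrices come from Matrix::expm and the
# likelihood is an explicit sum over all internal-node state assignments.

expm_oracle <- function(Q, t) {
  as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
}

# Brute-force CTMC likelihood: enumerate states at every internal node.
# tip_allowed: list over tips of allowed state indices.
enum_loglik <- function(tree, tip_allowed, Q, root_prior) {
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  k <- nrow(Q)
  nint <- phy$Nnode
  Ps <- lapply(seq_len(nrow(phy$edge)),
               function(e) expm_oracle(Q, phy$edge.length[e]))
  total <- 0
  combos <- as.matrix(do.call(expand.grid, rep(list(seq_len(k)), nint)))
  for (r in seq_len(nrow(combos))) {
    node_state <- combos[r, ]
    state_of <- function(nd) node_state[nd - ntip]
    # tip ambiguity: sum over the allowed tip states inside the product
    prob <- root_prior[state_of(ntip + 1L)]
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      P <- Ps[[e]]
      if (ch <= ntip) {
        prob <- prob * sum(P[state_of(par), tip_allowed[[ch]]])
      } else {
        prob <- prob * P[state_of(par), state_of(ch)]
      }
    }
    total <- total + prob
  }
  log(total)
}

allowed_from_binary <- function(states, tip_labels) {
  lapply(states[tip_labels], function(s)
    switch(s, "0" = 1L, "1" = 2L, "ambiguous" = 1:2))
}

# Exact conditional node-state posterior P(node = s | tips) by enumeration.
enum_node_posterior <- function(tree, tip_allowed, Q, root_prior) {
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  k <- nrow(Q)
  nint <- phy$Nnode
  Ps <- lapply(seq_len(nrow(phy$edge)),
               function(e) expm_oracle(Q, phy$edge.length[e]))
  combos <- as.matrix(do.call(expand.grid, rep(list(seq_len(k)), nint)))
  post <- matrix(0, nint, k)
  total <- 0
  for (r in seq_len(nrow(combos))) {
    node_state <- combos[r, ]
    state_of <- function(nd) node_state[nd - ntip]
    prob <- root_prior[state_of(ntip + 1L)]
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      if (ch <= ntip) prob <- prob * sum(Ps[[e]][state_of(par), tip_allowed[[ch]]])
      else prob <- prob * Ps[[e]][state_of(par), state_of(ch)]
    }
    total <- total + prob
    for (i in seq_len(nint)) post[i, node_state[i]] <- post[i, node_state[i]] + prob
  }
  rownames(post) <- ntip + seq_len(nint)
  post / total
}

# Brute-force DEC likelihood: enumerate node ranges AND the cladogenesis
# scenario chosen at every internal node; branch transitions via expm of the
# anagenetic generator. States: 1 = null, 2 = F, 3 = N, 4 = FN.
enum_dec_loglik <- function(tree, tip_ranges, model) {
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  Q <- dec_generator(model)
  ranges <- c("0", "F", "N", "FN")
  Ps <- lapply(seq_len(nrow(phy$edge)),
               function(e) expm_oracle(Q, phy$edge.length[e]))
  scen <- function(rg) {
    if (rg == "F") return(list(list(l = "F", r = "F", w = 1)))
    if (rg == "N") return(list(list(l = "N", r = "N", w = 1)))
    if (rg == "FN") {
      prs <- list(c("F","N"), c("N","F"), c("F","FN"), c("FN","F"),
                  c("N","FN"), c("FN","N"))
      return(lapply(prs, function(p) list(l = p[1], r = p[2], w = 1/6)))
    }
    list()
  }
  kids_of <- lapply(seq_len(ntip + phy$Nnode),
                    function(nd) phy$edge[phy$edge[, 1] == nd, 2])
  edge_of <- match(seq_len(ntip + phy$Nnode), phy$edge[, 2])
  rp <- c(0, rep(1/3, 3))
  tipr <- tip_ranges[phy$tip.label]
  ints <- ntip + seq_len(phy$Nnode)
  combos <- as.matrix(do.call(expand.grid, rep(list(c("F", "N", "FN")), phy$Nnode)))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    nrg <- setNames(combos[r, ], ints)
    # recursive sum over scenario choices
    subtotal <- function(nd) {
      # returns sum over scenarios below node nd of products of branch
      # transition probs, given nd's range
      rg <- nrg[[as.character(nd)]]
      s <- 0
      for (sc in scen(rg)) {
        term <- sc$w
        ks <- kids_of[[nd]]
        tops <- c(sc$l, sc$r)
        for (j in 1:2) {
          ch <- ks[j]
          P <- Ps[[edge_of[ch]]]
          bottom <- match(tops[j], ranges)
          if (ch <= ntip) {
            term <- term * P[bottom, match(tipr[ch], ranges)]
          } else {
            term <- term * P[bottom, match(nrg[[as.character(ch)]], ranges)] *
              subtotal(ch)
          }
        }
        s <- s + term
      }
      s
    }
    total <- total + rp[match(nrg[[as.character(ntip + 1L)]], ranges)] *
      subtotal(ntip + 1L)
  }
  log(total)
}

random_chronogram <- function(n_tips, seed, crown = 10) {
  simulate_tree(n_tips, crown_age = crown, birth = 0.3, death = 0, seed = seed)
}

fixture_dir <- function() {
  dir <- file.path(tempdir(), "fireclades-fixture")
  if (!file.exists(file.path(dir, "tree.nwk"))) make_fixture(dir, seed = 4242)
  dir
}

clade_tips_of <- function(tree, node) ape::extract.clade(tree, node)$tip.label
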