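DEC_RANGES <- c("0", "F", "N", "FN")  # "0" = null range (extinct everywhere)

#' Two-area dispersal-extinction-cladogenesis model
#'
#' Areas are F (fireprone) and N (non-fireprone); occupiable ranges are
#' `F`, `N` and `FN`. Dispersal is "unconstrained": `d_FN` (F gains N ...
#' i.e. an F-lineage expands into N? no -- `d_FN` is the rate of expansion
#' from F into the joint range FN) and `d_NF` (expansion from N into FN) are
#' estimated independently; `e_F`, `e_N` are per-area extirpation rates.
#'
#' @param d_FN,d_NF range-expansion (dispersal) rates per My.
#' @param e_F,e_N per-area extirpation rates per My.
#' @param root_prior `"uniform"` over `{F, N, FN}` or a length-3 probability
#'   vector in that order.
#' @return an object of class `dec_model`.
#' @export
dec_model <- function(d_FN, d_NF, e_F = 0, e_N = 0, root_prior = "uniform") {
  r <- c(d_FN = d_FN, d_NF = d_NF, e_F = e_F, e_N = e_N)
  if (any(r < 0)) stop("rates must be >= 0")
  structure(list(rates = r, root_prior = root_prior), class = "dec_model")
}

#' Anagenetic generator of a DEC model
#'
#' Transition-rate matrix over `{0, F, N, FN}` (`0` = null range, absorbing):
#' `F -> FN` at `d_FN`, `N -> FN` at `d_NF`, `FN -> F` at `e_N`,
#' `FN -> N` at `e_F`, `F -> 0` at `e_F`, `N -> 0` at `e_N`.
#'
#' @param model a [dec_model()].
#' @return 4x4 rate matrix with rows summing to zero.
#' @export
dec_generator <- function(model) {
  r <- model$rates
  Q <- matrix(0, 4, 4, dimnames = list(DEC_RANGES, DEC_RANGES))
  Q["F", "FN"] <- r["d_FN"]
  Q["N", "FN"] <- r["d_NF"]
  Q["FN", "F"] <- r["e_N"]
  Q["FN", "N"] <- r["e_F"]
  Q["F", "0"] <- r["e_F"]
  Q["N", "0"] <- r["e_N"]
  diag(Q) <- -rowSums(Q)
  Q
}

# Ordered-daughter cladogenesis scenarios for each parent range, equiprobable.
# Single-area parents: identical (within-area sympatric) inheritance.
# FN parents: vicariance (F|N both orders) and peripheral isolation
# (one daughter keeps FN, the other a single area), 6 scenarios at 1/6 each.
dec_scenarios <- function(range) {
  switch(range,
    "F" = list(list(l = "F", r = "F", w = 1)),
    "N" = list(list(l = "N", r = "N", w = 1)),
    "FN" = {
      prs <- list(c("F", "N"), c("N", "F"), c("F", "FN"), c("FN", "F"),
                  c("N", "FN"), c("FN", "N"))
      lapply(prs, function(p) list(l = p[1], r = p[2], w = 1 / 6))
    },
    stop("no cladogenesis scenarios for range '", range, "'"))
}

dec_root_prior <- function(model) {
  rp <- model$root_prior
  if (is.character(rp) && rp == "uniform") {
    v <- c(0, 1, 1, 1) / 3
  } else {
    if (length(rp) != 3 || any(rp < 0)) stop("root prior must cover {F, N, FN}")
    v <- c(0, rp / sum(rp))
  }
  names(v) <- DEC_RANGES
  v
}

check_tip_ranges <- function(tree, tip_ranges) {
  tr <- tip_ranges[tree$tip.label]
  if (anyNA(tr) || is.null(names(tip_ranges)))
    stop("tip ranges must be named and cover every tip")
  bad <- setdiff(unique(tr), c("F", "N", "FN"))
  if (length(bad)) stop("unknown tip range token: ", paste(bad, collapse = ", "))
  tr
}

#' DEC log-likelihood of tip ranges on a chronogram
#'
#' Pruning over ranges with anagenetic `exp(Qt)` along branches and the
#' equiprobable DEC cladogenesis scenario set at each (strictly bifurcating)
#' node; the null range contributes zero likelihood and the root is combined
#' with the root prior over `{F, N, FN}`.
#'
#' @param tree a strictly bifurcating `chronogram`.
#' @param tip_ranges named character vector over tips with values in
#'   `{"F", "N", "FN"}`.
#' @param model a [dec_model()].
#' @param constrain_node,constrain_range optionally fix one internal node
#'   (ape id) to a single range, used for marginal reconstructions.
#' @return the log-likelihood.
#' @export
dec_log_likelihood <- function(tree, tip_ranges, model,
                               constrain_node = NULL, constrain_range = NULL) {
  ntip <- length(tree$tip.label)
  tab <- tabulate(tree$edge[, 1])
  if (any(tab[tab > 0] != 2))
    stop("DEC requires a strictly bifurcating tree (polytomy found)")
  tr <- check_tip_ranges(tree, tip_ranges)
  Q <- dec_generator(model)
  phy <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + phy$Nnode
  D <- matrix(0, nn, 4, dimnames = list(NULL, DEC_RANGES))
  for (i in seq_len(ntip)) D[i, tr[i]] <- 1
  logscale <- 0
  # branch-bottom partials E for each child, combined at the parent
  E <- matrix(0, nn, 4)
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  done <- logical(nn)
  for (e in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[e, 2]
    if (ch > ntip && !done[ch]) {
      D[ch, ] <- dec_combine(ch, children, phy, E)
      if (!is.null(constrain_node) && ch == constrain_node) {
        keep <- DEC_RANGES == constrain_range
        D[ch, !keep] <- 0
      }
      s <- max(D[ch, ])
      if (s <= 0) return(-Inf)
      D[ch, ] <- D[ch, ] / s
      logscale <- logscale + log(s)
      done[ch] <- TRUE
    }
    P <- transition_probs(Q, phy$edge.length[e])
    E[ch, ] <- as.numeric(P %*% D[ch, ])
  }
  root <- ntip + 1L
  D[root, ] <- dec_combine(root, children, phy, E)
  if (!is.null(constrain_node) && root == constrain_node)
    D[root, DEC_RANGES != constrain_range] <- 0
  L <- sum(dec_root_prior(model) * D[root, ])
  if (L <= 0) return(-Inf)
  log(L) + logscale
}

dec_combine <- function(node, children, phy, E) {
  kids <- phy$edge[children[[as.character(node)]], 2]
  out <- numeric(4)
  names(out) <- DEC_RANGES
  for (r in c("F", "N", "FN")) {
    for (s in dec_scenarios(r)) {
      out[r] <- out[r] + s$w * E[kids[1], match(s$l, DEC_RANGES)] *
                               E[kids[2], match(s$r, DEC_RANGES)]
    }
  }
  out
}

#' Fit a DEC model by maximum likelihood and reconstruct ancestral ranges
#'
#' Rates are estimated by bounded multi-start BFGS in log-rate space
#' (bounds 1e-9 to 10 per My, 5 starts). Marginal ancestral-range
#' probabilities are obtained by constraining each node to each range and
#' renormalizing the likelihoods; dispersal events are read along branches
#' where the most-probable range of a daughter includes an area absent from
#' its parent's most-probable range.
#'
#' @param tree a strictly bifurcating `chronogram` (>= 4 tips).
#' @param tip_ranges named ranges over tips, both areas represented.
#' @param symmetric_d constrain `d_FN = d_NF`.
#' @param n_starts number of optimizer starts.
#' @param seed seed for the random starts.
#' @return a `dec_fit` list: `model` (fitted rates), `logLik`, `node_probs`
#'   (internal nodes x `{F, N, FN}`), `node_ml` (most-probable range per
#'   node), `events` (data frame: node, age, direction), `convergence`.
#' @export
fit_dec <- function(tree, tip_ranges, symmetric_d = FALSE, n_starts = 5,
                    seed = 1) {
  ntip <- length(tree$tip.label)
  if (ntip < 4) stop("fit_dec requires >= 4 tips")
  tr <- check_tip_ranges(tree, tip_ranges)
  areas <- unique(unlist(strsplit(unname(tr), "")))
  if (!all(c("F", "N") %in% areas))
    stop("both areas must be represented among the tips")
  npar <- if (symmetric_d) 3L else 4L
  unpack <- function(p) {
    r <- exp(p)
    if (symmetric_d) dec_model(r[1], r[1], r[2], r[3])
    else dec_model(r[1], r[2], r[3], r[4])
  }
  nll <- function(p) -dec_log_likelihood(tree, tr, unpack(p))
  set.seed(seed)
  best <- NULL
  lb <- log(1e-9); ub <- log(10)
  for (s in seq_len(n_starts)) {
    p0 <- runif(npar, log(1e-4), log(1))
    fit <- tryCatch(
      optim(p0, nll, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(factr = 1e-8 / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("DEC optimizer failed to converge from any start")
  model <- unpack(best$par)
  ll <- -best$value

  # marginal range probabilities by constrained renormalization
  nodes <- ntip + seq_len(tree$Nnode)
  np <- matrix(0, length(nodes), 3, dimnames = list(nodes, c("F", "N", "FN")))
  for (i in seq_along(nodes)) {
    lls <- vapply(c("F", "N", "FN"), function(r)
      dec_log_likelihood(tree, tr, model, constrain_node = nodes[i],
                         constrain_range = r), numeric(1))
    w <- exp(lls - max(lls))
    np[i, ] <- w / sum(w)
  }
  ml <- colnames(np)[max.col(np)]
  names(ml) <- nodes

  events <- dec_events(tree, ml, tr)
  structure(list(model = model, logLik = ll, node_probs = np, node_ml = ml,
                 events = events, convergence = best$convergence),
            class = "dec_fit")
}

# Dispersal/divergence events: nodes where one daughter's most-probable
# range holds an area absent from the other daughter's. Covers both the
# anagenetic gain (parent F, daughter FN) and the vicariant split
# (parent FN dividing into F | N) readings of a colonization.
dec_events <- function(tree, node_ml, tip_ranges) {
  ntip <- length(tree$tip.label)
  range_of <- function(nd) {
    if (nd <= ntip) tip_ranges[tree$tip.label[nd]] else node_ml[as.character(nd)]
  }
  out <- list()
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    if (length(kids) != 2) next
    r1 <- strsplit(unname(range_of(kids[1])), "")[[1]]
    r2 <- strsplit(unname(range_of(kids[2])), "")[[1]]
    for (j in 1:2) {
      ra <- if (j == 1) r1 else r2
      rb <- if (j == 1) r2 else r1
      for (g in setdiff(ra, rb)) {
        out[[length(out) + 1]] <- data.frame(
          node = nd, child = kids[j], age = tree$node_age[nd],
          direction = paste0(paste(rb, collapse = ""), "->", g))
      }
    }
  }
  if (!length(out))
    return(data.frame(node = integer(), child = integer(),
                      age = numeric(), direction = character()))
  ev <- do.call(rbind, out)
  ev[order(-ev$age), , drop = FALSE]
}

#' Habitat reconstructed as a heritable binary trait
#'
#' Alternative to the DEC reconstruction: maps ranges to a binary trait
#' (`F` = 1 fireprone, `N` = 0, `FN` = ambiguous) and runs the same
#' MCMC ancestral-state machinery used for the seed-storage traits.
#'
#' @inheritParams fit_dec
#' @param config an [mcmc_config()].
#' @param threshold corrected-posterior decision threshold.
#' @return a list with the `mcmc_trace` and the `node_assignment` table.
#' @export
habitat_as_trait <- function(tree, tip_ranges, config = mcmc_config(),
                             threshold = 0.95) {
  tr <- check_tip_ranges(tree, tip_ranges)
  states <- setNames(ifelse(tr == "F", "1", ifelse(tr == "N", "0", "ambiguous")),
                     names(tr))
  trace <- run_chain(tree, states, mk_model(0.1, 0.1), config)
  assignments <- assign_nodes(trace, tree, trait = "habitat",
                              threshold = threshold)
  list(trace = trace, assignments = assignments, states = states)
}

#' @export
print.dec_fit <- function(x, ...) {
  r <- x$model$rates
  cat(sprintf("DEC fit: d_FN=%.4g d_NF=%.4g e_F=%.4g e_N=%.4g  logLik=%.3f\n",
              r[1], r[2], r[3], r[4], x$logLik))
  cat(sprintf("  %d dispersal event(s) inferred\n", nrow(x$events)))
  invisible(x)
}
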