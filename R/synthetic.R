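#' Simulate an ultrametric chronogram
#'
#' Birth-death simulation conditioned on the number of extant tips
#' (via [ape::rphylo()]), rescaled so the crown age equals `crown_age`.
#' Optionally the birth rate is linked to a jointly simulated two-state
#' habitat (fireprone `F` / non-fireprone `N`): fireprone lineages speciate
#' at `birth * habitat$birth_mult` (pure-birth in that mode). Used for
#' sister-clade diversification tests.
#'
#' @param n_tips number of extant tips (>= 4).
#' @param crown_age target crown age in My (default 113, the family-level
#'   chronogram scale the package is designed around).
#' @param birth,death per-lineage rates per My.
#' @param seed integer seed (mandatory; simulation is bit-reproducible).
#' @param habitat `NULL`, or a list with `birth_mult` (fireprone birth-rate
#'   multiplier), `q_NF` and `q_FN` (habitat switching rates per My), and
#'   optionally `root_state` (`"N"` default).
#' @return a `chronogram`; when `habitat` is given, tip habitat states are
#'   attached as attribute `"habitat"` and latent branch states drive the
#'   speciation rates.
#' @export
simulate_tree <- function(n_tips, crown_age = 113, birth = 0.1, death = 0,
                          seed, habitat = NULL) {
  stopifnot(!missing(seed))
  if (n_tips < 4) stop("n_tips must be >= 4")
  set.seed(seed)
  if (is.null(habitat)) {
    phy <- ape::rphylo(n_tips, birth = birth, death = death)
  } else {
    phy <- sim_bisse_yule(n_tips, birth, habitat)
  }
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * (crown_age / depth)
  hb <- attr(phy, "habitat")
  nh <- attr(phy, "node_habitat")
  out <- as_chronogram(phy)
  if (!is.null(hb)) attr(out, "habitat") <- hb
  if (!is.null(nh)) attr(out, "node_habitat") <- nh
  out
}

# Pure-birth simulation with habitat-dependent speciation, Gillespie style.
# Lineages carry a habitat state; fireprone lineages speciate faster.
sim_bisse_yule <- function(n_tips, birth, habitat) {
  mult <- habitat$birth_mult
  qNF <- habitat$q_NF
  qFN <- habitat$q_FN
  root_state <- if (is.null(habitat$root_state)) "N" else habitat$root_state
  # lineage records
  max_ln <- 2 * n_tips + 10
  start <- state <- numeric(max_ln)
  pnode <- integer(max_ln)   # node a lineage descends from (0 = crown root)
  endnode <- integer(max_ln) # node a lineage ends in (0 = extant tip)
  st_code <- c(N = 1, F = 2)
  node_time <- numeric(max_ln)
  node_kids <- vector("list", max_ln)
  # start from the crown: two lineages at time 0
  nln <- 2L; nnd <- 0L
  start[1:2] <- 0; pnode[1:2] <- 0L
  state[1:2] <- st_code[root_state]
  t <- 0
  active <- c(1L, 2L)
  repeat {
    lam <- ifelse(state[active] == 2, birth * mult, birth)
    flip <- ifelse(state[active] == 2, qFN, qNF)
    tot <- sum(lam) + sum(flip)
    dt <- rexp(1, tot)
    t <- t + dt
    if (length(active) >= n_tips) break
    w <- c(lam, flip)
    pick <- sample.int(2 * length(active), 1, prob = w)
    if (pick <= length(active)) {  # speciation
      ln <- active[pick]
      nnd <- nnd + 1L
      node_time[nnd] <- t
      endnode[ln] <- nnd
      k1 <- nln + 1L; k2 <- nln + 2L; nln <- nln + 2L
      start[c(k1, k2)] <- t
      pnode[c(k1, k2)] <- nnd
      state[c(k1, k2)] <- state[ln]
      node_kids[[nnd]] <- c(k1, k2)
      active <- c(active[-pick], k1, k2)
    } else {  # habitat flip
      ln <- active[pick - length(active)]
      state[ln] <- 3L - state[ln]
    }
  }
  T_end <- t
  # habitat of each splitting lineage at its speciation: a lineage's state
  # stops changing once it splits, so its final state is the one at the split
  node_state <- integer(max_ln)
  for (ln in seq_len(nln))
    if (endnode[ln] > 0L) node_state[endnode[ln]] <- state[ln]
  # build Newick recursively from the two crown lineages; internal labels
  # carry the latent habitat for recovery tests
  tipn <- 0L
  tip_state <- character(0)
  lin_str <- function(ln) {
    if (endnode[ln] == 0L) {
      tipn <<- tipn + 1L
      lab <- sprintf("t%d", tipn)
      tip_state[lab] <<- c("N", "F")[state[ln]]
      sprintf("%s:%.10f", lab, T_end - start[ln])
    } else {
      nd <- endnode[ln]
      kids <- node_kids[[nd]]
      # daughters inherit the parent state at the split; record it
      sprintf("(%s,%s)H%s:%.10f", lin_str(kids[1]), lin_str(kids[2]),
              c("N", "F")[node_state[nd]], node_time[nd] - start[ln])
    }
  }
  # a lineage's habitat at its end node is its state when it speciated;
  # states only change by flip events, so track at speciation time
  nwk <- sprintf("(%s,%s)H%s;", lin_str(1L), lin_str(2L), root_state)
  phy <- ape::read.tree(text = nwk)
  attr(phy, "habitat") <- tip_state[phy$tip.label]
  hb <- sub("^H", "", phy$node.label)
  phy$node.label <- NULL
  attr(phy, "node_habitat") <- setNames(hb, length(phy$tip.label) +
                                          seq_len(phy$Nnode))
  phy
}

#' Simulate two binary traits jointly under a trait-pair model
#'
#' Runs [simulate_trait()] on the 4-state joint space and splits the result
#' into two binary tip-state columns.
#'
#' @param tree a `chronogram`.
#' @param model a [pair_model()].
#' @param seed integer seed.
#' @return list with `traitA`, `traitB` (named tip-state vectors),
#'   `joint_tips`, and latent `node_states`.
#' @export
simulate_correlated_traits <- function(tree, model, seed) {
  stopifnot(inherits(model, "pair_model"))
  sim <- simulate_trait(tree, model, seed)
  list(traitA = setNames(substr(sim$tip_states, 1, 1), names(sim$tip_states)),
       traitB = setNames(substr(sim$tip_states, 2, 2), names(sim$tip_states)),
       joint_tips = sim$tip_states, node_states = sim$node_states)
}

#' Simulate tip ranges under a DEC model
#'
#' Forward simulation: root range from the model's root prior, equiprobable
#' cladogenesis scenarios at nodes, anagenetic CTMC along branches. A
#' simulation in which any surviving lineage reaches the null range is
#' inconsistent with an extant tree and is retried.
#'
#' @param tree a `chronogram`.
#' @param model a [dec_model()].
#' @param seed integer seed.
#' @param max_retries retry cap before erroring.
#' @return list with `tip_ranges` (named) and latent `node_ranges`.
#' @export
simulate_ranges <- function(tree, model, seed, max_retries = 100) {
  set.seed(seed)
  Q <- dec_generator(model)
  phy <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(phy$tip.label)
  rp <- dec_root_prior(model)
  for (try in seq_len(max_retries)) {
    range <- character(ntip + phy$Nnode)
    # top-of-branch range below each node, set by the cladogenesis draw
    top <- character(ntip + phy$Nnode)
    range[ntip + 1L] <- sample(DEC_RANGES, 1, prob = rp)
    ok <- TRUE
    # cladewise edge order: parents before children
    kids_of <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
    draw_clado <- function(nd) {
      sc <- dec_scenarios(range[nd])
      s <- sc[[sample.int(length(sc), 1)]]
      es <- kids_of[[as.character(nd)]]
      top[phy$edge[es[1], 2]] <<- s$l
      top[phy$edge[es[2], 2]] <<- s$r
    }
    draw_clado(ntip + 1L)
    for (e in seq_len(nrow(phy$edge))) {
      ch <- phy$edge[e, 2]
      P <- transition_probs(Q, phy$edge.length[e])
      range[ch] <- sample(DEC_RANGES, 1, prob = P[top[ch], ])
      if (range[ch] == "0") { ok <- FALSE; break }
      if (ch > ntip) draw_clado(ch)
    }
    if (ok) {
      tips <- setNames(range[seq_len(ntip)], phy$tip.label)
      nodes <- setNames(range[(ntip + 1L):(ntip + phy$Nnode)],
                        ntip + seq_len(phy$Nnode))
      return(list(tip_ranges = tips, node_ranges = nodes))
    }
  }
  stop("simulate_ranges: lineage went extinct (null range) in every retry")
}

# Simulate a binary trait whose rates differ between branches inside and
# outside a focal clade (used by the fixture to tie seed traits to the
# planted fireprone clade).
sim_trait_clade_rates <- function(tree, clade_node, rates_in, rates_out, seed) {
  set.seed(seed)
  phy <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(phy$tip.label)
  inside_tips <- clade_tips(tree, clade_node)
  desc <- function(nd) {
    if (nd <= ntip) return(nd)
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    c(nd, unlist(lapply(kids, desc)))
  }
  inside_nodes <- desc(clade_node)
  state <- integer(ntip + phy$Nnode)
  state[ntip + 1L] <- 1L  # root in state 0
  for (e in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[e, 2]
    r <- if (ch %in% inside_nodes) rates_in else rates_out
    Q <- build_rate_matrix(mk_model(r[1], r[2]))
    P <- transition_probs(Q, phy$edge.length[e])
    state[ch] <- sample.int(2, 1, prob = P[state[phy$edge[e, 1]], ])
  }
  setNames(c("0", "1")[state[seq_len(ntip)]], phy$tip.label)
}

#' Build the synthetic "Proteaceae-like" fixture bundle
#'
#' Writes a fully synthetic dataset shaped like the real inputs: an 80-tip,
#' 113-My-crown chronogram (taxa `G001`..`G080`), habitat ranges with one
#' planted colonization of the fireprone habitat by a mid-depth clade, three
#' seed-trait columns (serotiny, soil storage, aril) simulated with elevated
#' gain rates inside the fireprone clade, species counts drawn larger for
#' fireprone tips, and a manifest recording every true parameter for
#' recovery tests. All outputs are deterministic given `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_tips,crown_age tree shape (defaults 80 tips, 113 My).
#' @return invisibly, the loaded bundle (see [load_fixture()]) with the
#'   truth parameters attached as `$truth`.
#' @export
make_fixture <- function(dir, seed = 4242, n_tips = 80, crown_age = 113) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(n_tips, crown_age, birth = 0.08, death = 0.02,
                        seed = seed)
  tree$tip.label <- sprintf("G%03d", seq_len(n_tips))
  # attach synthetic clade support: strong but not uniform
  set.seed(seed + 1L)
  pp <- round(pmin(1, 0.95 + runif(tree$Nnode, 0, 0.05)), 3)
  pp[1] <- 1
  tree$clade_pp <- pp

  # plant one N->F colonization: a mid-depth clade of roughly a third of
  # the genera becomes the fireprone radiation
  ntip <- n_tips
  sizes <- vapply(ntip + seq_len(tree$Nnode),
                  function(nd) length(clade_tips(tree, nd)), numeric(1))
  ages <- tree$node_age[ntip + seq_len(tree$Nnode)]
  cand <- which(ages > 0.25 * crown_age & ages < 0.6 * crown_age & sizes >= 8)
  if (!length(cand)) cand <- which(sizes >= 4 & sizes <= n_tips / 2)
  planted <- ntip + cand[which.min(abs(sizes[cand] - round(n_tips * 0.35)))]
  fire_tips <- clade_tips(tree, planted)
  ranges <- setNames(rep("N", ntip), tree$tip.label)
  ranges[fire_tips] <- "F"
  # two mixed-habitat genera outside the fireprone clade
  set.seed(seed + 2L)
  both <- sample(setdiff(tree$tip.label, fire_tips), 2)
  ranges[both] <- "FN"

  traits <- data.frame(taxon = tree$tip.label)
  # seed traits are labile inside the fireprone radiation (repeated gains
  # and losses, as for serotiny in fire-prone floras) and essentially
  # static outside it
  trait_rates <- list(in_clade = c(0.12, 0.08), out_clade = c(0.001, 0.05))
  for (i in seq_along(c("serotiny", "soil_storage", "aril"))) {
    tn <- c("serotiny", "soil_storage", "aril")[i]
    traits[[tn]] <- unname(sim_trait_clade_rates(
      tree, planted, trait_rates$in_clade, trait_rates$out_clade,
      seed = seed + 10L + i))
  }

  set.seed(seed + 3L)
  counts <- ifelse(ranges[tree$tip.label] == "F",
                   1L + stats::rnbinom(ntip, size = 2, mu = 19),
                   1L + stats::rnbinom(ntip, size = 2, mu = 4))
  counts <- setNames(as.integer(counts), tree$tip.label)

  write_newick(tree, file.path(dir, "tree.nwk"))
  tr_out <- traits
  tr_out[tr_out == "ambiguous"] <- "both"
  write.table(tr_out, file.path(dir, "traits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(taxon = names(ranges), range = unname(ranges)),
              file.path(dir, "ranges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(taxon = names(counts), n_species = unname(counts)),
              file.path(dir, "species_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(seed = seed, n_tips = n_tips, crown_age = crown_age,
                birth = 0.08, death = 0.02,
                # node ids are not stable across Newick round-trips; the
                # planted clade is identified by its tip set (MRCA)
                planted_tips = fire_tips,
                planted_clade_size = length(fire_tips),
                planted_stem_age = tree$node_age[
                  tree$edge[match(planted, tree$edge[, 2]), 1]],
                planted_node_age = tree$node_age[planted],
                trait_gain_in = trait_rates$in_clade[1],
                trait_loss_in = trait_rates$in_clade[2],
                trait_gain_out = trait_rates$out_clade[1],
                trait_loss_out = trait_rates$out_clade[2],
                mixed_taxa = both)
  writeLines(c("# synthetic fixture manifest (all data simulated; no real taxa)",
               paste0(names(truth), ": ",
                      vapply(truth, function(v) paste(v, collapse = ","),
                             character(1)))),
             file.path(dir, "manifest.txt"))
  invisible(c(load_fixture(dir), list(truth = truth)))
}

#' Load a fixture bundle from disk
#'
#' @param dir directory written by [make_fixture()].
#' @return list: `tree` (chronogram), `traits` (trait_table), `ranges`
#'   (named vector), `species_counts` (named vector), `manifest` (character).
#' @export
load_fixture <- function(dir) {
  rg <- read.delim(file.path(dir, "ranges.tsv"), sep = "\t")
  list(tree = read_chronogram(file.path(dir, "tree.nwk")),
       traits = read_trait_table(file.path(dir, "traits.tsv")),
       ranges = setNames(rg$range, rg$taxon),
       species_counts = read_species_counts(file.path(dir, "species_counts.tsv")),
       manifest = if (file.exists(file.path(dir, "manifest.txt")))
         readLines(file.path(dir, "manifest.txt")) else character())
}
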