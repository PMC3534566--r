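#' Corrected-posterior node assignments
#'
#' For every internal node, multiplies the node's trait-state posterior by the
#' clade posterior probability of that node existing in the phylogeny (the
#' "corrected" posterior), and calls the ancestral state unambiguously when
#' the larger corrected posterior exceeds the threshold. The root's clade
#' support is 1 by construction; nodes without a support label use
#' `default_pp`.
#'
#' @param trace an `mcmc_trace` with node posteriors (2-state models), or a
#'   matrix of per-node state posteriors (internal nodes x 2, rows named by
#'   ape node id).
#' @param tree the `chronogram` the trace was run on.
#' @param trait trait name recorded in the output.
#' @param threshold corrected-posterior decision threshold, in (0.5, 1\].
#' @param default_pp clade support assumed where the tree has none.
#' @return a `node_assignment` data frame: `node`, `age`, `trait`,
#'   `p_state0`, `p_state1`, `clade_pp`, `corrected0`, `corrected1`,
#'   `decision` in `{"state-0", "state-1", "ambiguous"}`.
#' @export
assign_nodes <- function(trace, tree, trait = "trait", threshold = 0.95,
                         default_pp = 1.0) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  post <- if (inherits(trace, "mcmc_trace")) trace$node_posterior else trace
  if (ncol(post) != 2) stop("assign_nodes expects a 2-state posterior")
  ntip <- length(tree$tip.label)
  if (nrow(post) != tree$Nnode) stop("posterior rows must match internal nodes")
  pp <- clade_support(tree, default = default_pp)
  cor0 <- post[, 1] * pp
  cor1 <- post[, 2] * pp
  decision <- ifelse(cor1 > threshold, "state-1",
              ifelse(cor0 > threshold, "state-0", "ambiguous"))
  out <- data.frame(node = ntip + seq_len(tree$Nnode),
                    age = tree$node_age[ntip + seq_len(tree$Nnode)],
                    trait = trait,
                    p_state0 = unname(post[, 1]), p_state1 = unname(post[, 2]),
                    clade_pp = pp, corrected0 = unname(cor0),
                    corrected1 = unname(cor1), decision = decision)
  class(out) <- c("node_assignment", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

# Per-stem table: one row per edge plus a virtual root row. A stem carries
# the state probabilities (and decision) of the node it subtends -- they are
# held constant from the node up to its parent. Age interval convention:
# [child age, parent age), so a query at a node's own age reads that node's
# assignment and tips are counted at age 0.
stem_table <- function(assignments, tree, tip_states = NULL) {
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  parent <- tree$edge[, 1]
  p0 <- p1 <- numeric(length(child))
  dec <- character(length(child))
  idx <- match(child, assignments$node)
  int <- !is.na(idx)
  p0[int] <- assignments$p_state0[idx[int]]
  p1[int] <- assignments$p_state1[idx[int]]
  dec[int] <- assignments$decision[idx[int]]
  tip_rows <- which(child <= ntip)
  if (length(tip_rows)) {
    if (is.null(tip_states)) stop("tip_states required to build tip stems")
    st <- states_for_tree(tip_states, tree$tip.label)[child[tip_rows]]
    p1[tip_rows] <- ifelse(st == "1", 1, ifelse(st == "0", 0, 0.5))
    p0[tip_rows] <- 1 - p1[tip_rows]
    dec[tip_rows] <- ifelse(st == "1", "state-1",
                     ifelse(st == "0", "state-0", "ambiguous"))
  }
  data.frame(node = child, parent = parent,
             age_lo = tree$node_age[child], age_hi = tree$node_age[parent],
             p_state0 = p0, p_state1 = p1, decision = dec)
}

#' Propagate node assignments along their supporting stems
#'
#' The probability assigned to a node is retained, unchanged, along the
#' branch (stem) below it until the next assignment decision at its parent.
#' Stems are half-open in age, `[child age, parent age)`, so a query at a
#' node's exact age reads that node's own assignment.
#'
#' @inheritParams date_origin
#' @param tip_states named tip states, used for terminal stems.
#' @return an object of class `stem_profile`; use it with
#'   [stem_probabilities()] or `$table` for the per-stem data frame.
#' @export
propagate_stems <- function(assignments, tree, tip_states = NULL) {
  structure(list(table = stem_table(assignments, tree, tip_states),
                 root_age = root_age(tree),
                 root_node = length(tree$tip.label) + 1L,
                 assignments = assignments),
            class = "stem_profile")
}

#' Query stem trait probabilities at an age
#'
#' @param stems a `stem_profile` from [propagate_stems()].
#' @param age query age in Ma, `0 <= age <= root age`. At exactly the root
#'   age the root node's own assignment is returned as a single lineage.
#' @return data frame of the stems crossing `age` with their constant state
#'   probabilities and decision.
#' @export
stem_probabilities <- function(stems, age) {
  if (age > stems$root_age || age < 0)
    stop("query age outside [0, root age]")
  tb <- stems$table
  if (age == stems$root_age) {
    a <- stems$assignments
    r <- a[a$node == stems$root_node, , drop = FALSE]
    return(data.frame(node = r$node, parent = NA_integer_, age_lo = age,
                      age_hi = age, p_state0 = r$p_state0,
                      p_state1 = r$p_state1, decision = r$decision))
  }
  tb[tb$age_lo <= age & age < tb$age_hi, , drop = FALSE]
}

#' Date the origin of a derived trait state
#'
#' Finds the oldest point on the tree where the derived state's corrected
#' posterior probability exceeds the assignment threshold. Under the stem
#' propagation rule that point is the top (parent end) of the oldest passing
#' stem; a passing root dates the origin at the root age. Tips in the derived
#' state extend the search onto terminal stems when `tip_states` is given.
#'
#' @param assignments a `node_assignment` from [assign_nodes()].
#' @param tree the `chronogram`.
#' @param trait trait name for the report.
#' @param derived_state `"1"` or `"0"`.
#' @param tip_states optional named tip states; include terminal stems.
#' @param age_interval optional length-2 vector of age uncertainty bounds
#'   (e.g. a 95\% HPD carried over from the dating analysis) echoed into the
#'   estimate; the package does not recompute node-age uncertainty.
#' @return an `origin_estimate` list: `trait`, `detected`, `age` (Ma, `NA`
#'   when undetected), `node` (the node whose stem dates the origin),
#'   `interval`.
#' @export
date_origin <- function(assignments, tree, trait = "trait",
                        derived_state = "1", tip_states = NULL,
                        age_interval = NULL) {
  want <- paste0("state-", derived_state)
  ntip <- length(tree$tip.label)
  pass <- assignments$node[assignments$decision == want]
  ages <- numeric(0); nodes <- integer(0)
  if (length(pass)) {
    # stem-top age: parent age, or root age for the root itself
    top <- vapply(pass, function(nd) {
      if (nd == ntip + 1L) return(root_age(tree))
      tree$node_age[tree$edge[match(nd, tree$edge[, 2]), 1]]
    }, numeric(1))
    ages <- top; nodes <- pass
  }
  if (!is.null(tip_states)) {
    st <- states_for_tree(tip_states, tree$tip.label)
    tip_pass <- which(st == derived_state)
    if (length(tip_pass)) {
      top <- tree$node_age[tree$edge[match(tip_pass, tree$edge[, 2]), 1]]
      ages <- c(ages, top); nodes <- c(nodes, tip_pass)
    }
  }
  if (!length(ages)) {
    return(structure(list(trait = trait, detected = FALSE, age = NA_real_,
                          node = NA_integer_, interval = age_interval),
                     class = "origin_estimate"))
  }
  i <- which.max(ages)
  structure(list(trait = trait, detected = TRUE, age = ages[i],
                 node = nodes[i], interval = age_interval),
            class = "origin_estimate")
}

#' @export
print.origin_estimate <- function(x, ...) {
  if (!x$detected) {
    cat(sprintf("origin of %s: undetected (no node passes the threshold)\n", x$trait))
  } else {
    iv <- if (!is.null(x$interval))
      sprintf(" (%g-%g)", x$interval[1], x$interval[2]) else ""
    cat(sprintf("origin of %s: %.4g Ma%s at stem of node %d\n",
                x$trait, x$age, iv, x$node))
  }
  invisible(x)
}

#' Lineages through time by assignment category
#'
#' Counts, at every age gridpoint from 0 back to the root at the given
#' spacing, the stems crossing that age whose decision is state-1 (e.g.
#' fireprone), state-0, or ambiguous. Stems are half-open `[child, parent)`
#' so the tips are counted at age 0 and category counts always sum to the
#' number of stems crossing the gridpoint.
#'
#' @inheritParams propagate_stems
#' @param interval grid spacing in My (> 0).
#' @param labels length-2 character vector naming states 1 and 0 in the
#'   output (defaults to `fireprone` / `non-fireprone`).
#' @return data frame: `age`, one count column per category, `ambiguous`,
#'   `total`.
#' @export
lineage_timeline <- function(assignments, tree, tip_states = NULL,
                             interval = 10, labels = c("fireprone", "non-fireprone")) {
  if (interval <= 0) stop("interval must be > 0")
  tb <- stem_table(assignments, tree, tip_states)
  grid <- seq(0, root_age(tree), by = interval)
  rows <- lapply(grid, function(a) {
    cross <- tb$age_lo <= a & a < tb$age_hi
    d <- tb$decision[cross]
    data.frame(age = a,
               n1 = sum(d == "state-1"), n0 = sum(d == "state-0"),
               ambiguous = sum(d == "ambiguous"), total = sum(cross))
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- labels
  out
}

#' Write node assignments as TSV
#' @param assignments a `node_assignment`.
#' @param file output path.
#' @export
write_assignments <- function(assignments, file) {
  write.table(format_assignments(assignments), file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(assignments)
}

format_assignments <- function(a) {
  d <- as.data.frame(a)
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) formatC(x, digits = 10, format = "g"))
  d
}
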