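#' Parse a Newick string into a validated chronogram
#'
#' A chronogram is a rooted, ultrametric, time-calibrated tree with branch
#' lengths in millions of years (My). Node ages are reported in Ma with the
#' tips at age 0. Internal-node labels that parse as numbers in \[0, 1\] are
#' interpreted as clade posterior probabilities (`clade_pp`); any other label
#' is kept as a node name.
#'
#' @param text a Newick string (one tree).
#' @param tol relative ultrametricity tolerance, as a fraction of root age.
#' @return an object of class `c("chronogram", "phylo")` with components
#'   `node_age` (ages in Ma for all nodes, tips first) and `clade_pp`
#'   (per internal node; `NA` where the input carried no support value).
#' @examples
#' tr <- parse_newick("((A:1,B:1)0.95:1,C:2);")
#' root_age(tr)
#' @export
parse_newick <- function(text, tol = 1e-6) {
  phy <- tryCatch(ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("Newick parse error: no tree found in input", call. = FALSE)
  as_chronogram(phy, tol = tol)
}

#' Validate a phylo object as a chronogram
#'
#' @param phy an [ape::read.tree()]-style `phylo` object.
#' @inheritParams parse_newick
#' @return a `chronogram` (see [parse_newick()]).
#' @export
as_chronogram <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' object")
  if (is.null(phy$edge.length)) stop("chronogram requires branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths are not allowed")
  ntip <- length(phy$tip.label)
  if (ntip < 2) stop("chronogram requires at least 2 tips")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels: ",
    paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (any(!nzchar(phy$tip.label))) stop("empty tip labels are not allowed")

  depth <- ape::node.depth.edgelength(phy)  # distance from root, all nodes
  root_age <- max(depth[seq_len(ntip)])
  tipd <- depth[seq_len(ntip)]
  spread <- max(tipd) - min(tipd)
  if (root_age > 0 && spread > tol * root_age) {
    hi <- which.max(tipd); lo <- which.min(tipd)
    stop(sprintf(
      "tree is not ultrametric: root-to-tip depth %.6g ('%s') vs %.6g ('%s')",
      tipd[hi], phy$tip.label[hi], tipd[lo], phy$tip.label[lo]), call. = FALSE)
  }

  clade_pp <- rep(NA_real_, phy$Nnode)
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label
    num <- suppressWarnings(as.numeric(lab))
    is_pp <- !is.na(num) & num >= 0 & num <= 1
    clade_pp[is_pp] <- num[is_pp]
    phy$node.label[is_pp] <- NA_character_
    if (all(is.na(phy$node.label) | !nzchar(phy$node.label))) phy$node.label <- NULL
  }

  phy$node_age <- root_age - depth
  # snap tiny ultrametricity slack so tips sit exactly at 0
  phy$node_age[seq_len(ntip)] <- 0
  phy$clade_pp <- clade_pp
  class(phy) <- c("chronogram", "phylo")
  phy
}

#' Read a chronogram from a Newick file
#' @param path path to a Newick file.
#' @inheritParams parse_newick
#' @return a `chronogram`.
#' @export
read_chronogram <- function(path, tol = 1e-6) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""), tol = tol)
}

#' Serialize a chronogram to Newick
#'
#' Round-trips topology, branch lengths (to at least 12 significant digits)
#' and clade posterior probabilities written as internal-node labels.
#'
#' @param tree a `chronogram`.
#' @param file optional path; when `NULL` the string is returned.
#' @return the Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  phy <- tree
  if (!is.null(phy$clade_pp) && any(!is.na(phy$clade_pp))) {
    lab <- if (is.null(phy$node.label)) rep("", phy$Nnode) else phy$node.label
    lab[is.na(lab)] <- ""
    has <- !is.na(phy$clade_pp)
    lab[has] <- format(phy$clade_pp[has], digits = 12, trim = TRUE)
    phy$node.label <- lab
  }
  phy$node_age <- NULL; phy$clade_pp <- NULL
  class(phy) <- "phylo"
  txt <- ape::write.tree(phy, digits = 14)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Root age of a chronogram in Ma
#' @param tree a `chronogram`.
#' @return scalar age of the root in Ma.
#' @export
root_age <- function(tree) {
  stopifnot(!is.null(tree$node_age))
  tree$node_age[length(tree$tip.label) + 1L]
}

#' Clade posterior probabilities with a default for missing values
#'
#' @param tree a `chronogram`.
#' @param default value used where the tree carries no support label
#'   (the root is always assigned 1).
#' @return numeric vector, one entry per internal node.
#' @export
clade_support <- function(tree, default = 1.0) {
  pp <- tree$clade_pp
  if (is.null(pp)) pp <- rep(NA_real_, tree$Nnode)
  pp[is.na(pp)] <- default
  pp[1L] <- 1.0  # root exists by construction
  pp
}

VALID_TOKENS <- c("0", "1", "both", "NA", "")

#' Read a taxon-by-trait table
#'
#' Tab-delimited, UTF-8, `#` comment lines ignored. First column is the taxon
#' name; remaining columns are binary traits coded `0`, `1` or `both`
#' (species of the taxon occur in both states). `both` maps to `ambiguous`;
#' `NA`/empty maps to `ambiguous` with a warning.
#'
#' @param path path to the TSV file.
#' @return a `trait_table`: data frame with column `taxon` plus one character
#'   column per trait with values in `{"0", "1", "ambiguous"}`.
#' @export
read_trait_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character", check.names = FALSE,
                   na.strings = NULL)
  if (ncol(df) < 2) stop("trait table needs a taxon column plus >= 1 trait column")
  names(df)[1] <- "taxon"
  if (anyDuplicated(df$taxon))
    stop("duplicate taxon rows: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  for (j in seq(2, ncol(df))) {
    col <- df[[j]]
    bad <- which(!(col %in% VALID_TOKENS))
    if (length(bad))
      stop(sprintf("unknown trait token '%s' at row %d, column '%s'",
                   col[bad[1]], bad[1], names(df)[j]))
    if (any(col %in% c("NA", "")))
      warning(sprintf("column '%s': NA cells treated as ambiguous", names(df)[j]))
    col[col %in% c("both", "NA", "")] <- "ambiguous"
    df[[j]] <- col
    obs <- col[col != "ambiguous"]
    if (!("0" %in% obs) || !("1" %in% obs))
      warning(sprintf("invariant trait '%s': column lacks both a 0 and a 1 observation",
                      names(df)[j]))
  }
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Extract one trait column matched to the tips of a chronogram
#'
#' Performs a strict join: every tree tip must appear in the table and vice
#' versa; nothing is dropped silently.
#'
#' @param traits a `trait_table` (or compatible data frame).
#' @param tree a `chronogram`.
#' @param trait trait column name.
#' @return named character vector over `tree$tip.label` with values in
#'   `{"0", "1", "ambiguous"}`.
#' @export
trait_states <- function(traits, tree, trait) {
  if (!trait %in% names(traits)) stop("no trait column '", trait, "'")
  miss <- setdiff(tree$tip.label, traits$taxon)
  if (length(miss)) stop("taxa missing from trait table: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(traits$taxon, tree$tip.label)
  if (length(extra)) stop("trait table taxa absent from tree: ",
                          paste(extra, collapse = ", "))
  setNames(traits[[trait]][match(tree$tip.label, traits$taxon)], tree$tip.label)
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf("chronogram: %d tips, root age %.4g Ma, %d/%d nodes with clade support\n",
              length(x$tip.label), root_age(x),
              sum(!is.na(x$clade_pp)), x$Nnode))
  invisible(x)
}
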