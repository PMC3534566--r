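#' Stem-group net speciation rate
#'
#' `R_st = log(N) / t` where `N` is the number of extant species in the
#' lineage and `t` its stem age in My. Natural log by default; base 10
#' available since the literature is split on the convention.
#'
#' @param N number of extant species (integer >= 1).
#' @param t stem age in My (> 0).
#' @param log_base `"natural"` or `"10"`.
#' @return rate per My.
#' @examples
#' stem_rate(10, 20)  # log(10)/20
#' @export
stem_rate <- function(N, t, log_base = "natural") {
  if (any(N < 1) || any(N != round(N))) stop("N must be an integer >= 1")
  if (any(t <= 0)) stop("t must be > 0")
  lg <- switch(log_base, natural = log, "10" = log10,
               stop("log_base must be 'natural' or '10'"))
  lg(N) / t
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_tips, tree = tree))
}

#' Find habitat-divergence events and their sister-lineage rates
#'
#' An event is an internal node where one daughter stem carries fireprone
#' probability above the threshold and the other daughter stem carries
#' non-fireprone probability above the threshold (stem probabilities follow
#' the propagation rule: a stem reads the node or tip it subtends). Each
#' event is populated with the two clades' summed species counts, the stem
#' age (the age of the divergence node), and the net speciation rates with
#' the fireprone side always in the numerator.
#'
#' @param assignments a `node_assignment` for the habitat trait (state 1 =
#'   fireprone), or any data frame with columns `node`, `p_state0`,
#'   `p_state1`.
#' @param tree the `chronogram`.
#' @param species_counts named integer vector of extant species per tip.
#' @param tip_states named habitat tip states used for terminal stems.
#' @param threshold stem-probability threshold (default 0.80).
#' @param log_base passed to [stem_rate()].
#' @return a `divergence_events` data frame: `event`, `node`, `age`,
#'   `N_fire`, `t_fire`, `R_fire`, `N_nonfire`, `t_nonfire`, `R_nonfire`,
#'   `ratio` (`NA` when the non-fireprone rate is 0, flagged in
#'   `ratio_defined`).
#' @export
find_divergence_events <- function(assignments, tree, species_counts,
                                   tip_states = NULL, threshold = 0.80,
                                   log_base = "natural") {
  ntip <- length(tree$tip.label)
  stems <- stem_table(assignments, tree, tip_states)
  p_fire <- setNames(stems$p_state1, stems$node)
  p_non <- setNames(stems$p_state0, stems$node)
  out <- list()
  for (nd in assignments$node) {
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    if (length(kids) != 2) next
    pf <- p_fire[as.character(kids)]
    pn <- p_non[as.character(kids)]
    fire_side <- if (pf[1] > threshold && pn[2] > threshold) 1L
                 else if (pf[2] > threshold && pn[1] > threshold) 2L
                 else next
    fk <- kids[fire_side]; nk <- kids[3L - fire_side]
    tips_f <- clade_tips(tree, fk)
    tips_n <- clade_tips(tree, nk)
    missing <- setdiff(c(tips_f, tips_n), names(species_counts))
    if (length(missing))
      stop("missing species count for tip(s): ", paste(missing, collapse = ", "))
    Nf <- sum(species_counts[tips_f]); Nn <- sum(species_counts[tips_n])
    t_stem <- tree$node_age[nd]
    Rf <- stem_rate(Nf, t_stem, log_base)
    Rn <- stem_rate(Nn, t_stem, log_base)
    out[[length(out) + 1]] <- data.frame(
      node = nd, age = t_stem, N_fire = Nf, t_fire = t_stem, R_fire = Rf,
      N_nonfire = Nn, t_nonfire = t_stem, R_nonfire = Rn,
      ratio = if (Rn > 0) Rf / Rn else NA_real_, ratio_defined = Rn > 0)
  }
  if (!length(out)) {
    ev <- data.frame(event = character(), node = integer(), age = numeric(),
                     N_fire = integer(), t_fire = numeric(), R_fire = numeric(),
                     N_nonfire = integer(), t_nonfire = numeric(),
                     R_nonfire = numeric(), ratio = numeric(),
                     ratio_defined = logical())
  } else {
    ev <- do.call(rbind, out)
    ev <- ev[order(-ev$age), , drop = FALSE]
    ev <- cbind(event = paste0("D", seq_len(nrow(ev))), ev)
    rownames(ev) <- NULL
  }
  class(ev) <- c("divergence_events", "data.frame")
  ev
}

#' Summarise fireprone/non-fireprone rate ratios across divergence events
#'
#' @param events a `divergence_events` data frame with >= 1 defined ratio.
#' @return list: `events` (per-event ratios), `mean_ratio` (arithmetic),
#'   `geometric_mean_ratio`, `n_undefined` (events excluded because the
#'   non-fireprone rate was 0).
#' @export
rate_ratio_summary <- function(events) {
  if (!nrow(events)) stop("no divergence events supplied")
  def <- events[!is.na(events$ratio), , drop = FALSE]
  if (!nrow(def)) stop("all rate ratios undefined (non-fireprone rate 0)")
  structure(list(events = def[, c("event", "node", "age", "ratio")],
                 mean_ratio = mean(def$ratio),
                 geometric_mean_ratio = exp(mean(log(def$ratio))),
                 n_undefined = sum(is.na(events$ratio))),
            class = "rate_ratio_summary")
}

#' @export
print.rate_ratio_summary <- function(x, ...) {
  cat(sprintf(
    "net speciation in fireprone lineages: mean ratio %.2f (geometric %.2f) over %d event(s)%s\n",
    x$mean_ratio, x$geometric_mean_ratio, nrow(x$events),
    if (x$n_undefined) sprintf(", %d undefined excluded", x$n_undefined) else ""))
  invisible(x)
}

#' Read a species-count table
#' @param path TSV with columns `taxon`, `n_species`.
#' @return named integer vector.
#' @export
read_species_counts <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#")
  if (!all(c("taxon", "n_species") %in% names(df)))
    stop("species-count table needs columns 'taxon' and 'n_species'")
  setNames(as.integer(df$n_species), df$taxon)
}
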