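#' MCMC configuration
#'
#' Presets: `"paper"` uses the full-scale settings of the original analyses
#' (1e7 iterations, burn-in 1e4, one sample every 2000 iterations; 5e6
#' iterations for correlation runs, see [test_correlation()]); `"test"` is a
#' desk-scale configuration (1e5 iterations, burn-in 1e3, thin 20) suitable
#' for simulation studies and CI.
#'
#' @param preset `"test"` or `"paper"`.
#' @param iterations,burn_in,thin chain length controls; any value given
#'   explicitly overrides the preset.
#' @param ratedev half-width of the reflected-uniform rate proposal, or
#'   `"auto"` to tune it to a 20--40\% acceptance rate with [tune_ratedev()].
#' @param hyperprior_upper upper bound of the uniform hyperprior on the mean
#'   of the exponential rate prior (the prior is Exp(mean m), m ~ U(0, upper)).
#' @param rj enable reversible-jump moves over rate-class partitions
#'   (including a zero-bin).
#' @param seed integer seed; chain `i` uses `seed + i - 1`.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(preset = "test", iterations = NULL, burn_in = NULL,
                        thin = NULL, ratedev = "auto", hyperprior_upper = 30,
                        rj = TRUE, seed = 1L) {
  base <- switch(preset,
    test  = list(iterations = 1e5, burn_in = 1e3, thin = 20),
    paper = list(iterations = 1e7, burn_in = 1e4, thin = 2000),
    stop("unknown preset '", preset, "'"))
  cfg <- list(preset = preset,
              iterations = if (is.null(iterations)) base$iterations else iterations,
              burn_in = if (is.null(burn_in)) base$burn_in else burn_in,
              thin = if (is.null(thin)) base$thin else thin,
              ratedev = ratedev, hyperprior_upper = hyperprior_upper,
              rj = rj, seed = as.integer(seed))
  if (cfg$iterations <= cfg$burn_in) stop("iterations must exceed burn_in")
  if (cfg$thin < 1) stop("thin must be >= 1")
  if (!identical(cfg$ratedev, "auto") && cfg$ratedev <= 0)
    stop("ratedev must be > 0")
  structure(cfg, class = "mcmc_config")
}

n_free_rates <- function(model) {
  if (inherits(model, "mk_model")) 2L
  else if (model$dependent) 8L else 4L
}

chain_inputs <- function(tree, states, model) {
  kd <- tree_kernel_data(tree)
  states <- states_for_tree(states, kd$tip_order)
  part <- tip_partials(states, model)
  list(kd = kd, part = part, cells = rate_cells(model),
       k = length(model$states), rootp = root_prior_vec(model),
       height = root_age(tree))
}

run_chain_raw <- function(ci, model, ratedev, cfg, seed, fix_rates = FALSE,
                          init_rates = NULL, sample_nodes = TRUE,
                          iterations = cfg$iterations, burn_in = cfg$burn_in,
                          thin = cfg$thin) {
  n <- n_free_rates(model)
  set.seed(seed)
  hyper0 <- runif(1, 0, cfg$hyperprior_upper)
  # start on the likelihood scale (about one expected event per root-to-tip
  # path) rather than at a diffuse hyperprior draw, so short burn-ins suffice
  if (is.null(init_rates)) init_rates <- rep(1 / max(ci$height, 1e-6), n)
  cells0 <- ci$cells
  cells0[, 1:2] <- cells0[, 1:2] - 1L
  cells0[, 3] <- cells0[, 3] - 1L
  chain_cpp(ci$kd$edge, ci$kd$elen, ci$kd$ntip, ci$kd$nnode_tot, ci$kd$root,
            ci$part, cells0, ci$k, ci$rootp, n, ratedev,
            cfg$hyperprior_upper, TRUE, cfg$rj, iterations, burn_in,
            as.integer(thin), init_rates, seq_len(n), hyper0,
            fix_rates, sample_nodes)
}

#' Tune the rate-proposal step to a 20--40\% acceptance rate
#'
#' Runs short pilot chains (default 3 chains of 1e4 iterations) and scales
#' `ratedev` geometrically (doubling or halving) until the pooled acceptance
#' rate of the rate proposals falls in \[0.20, 0.40\].
#'
#' @inheritParams run_chain
#' @param pilot_iterations,pilot_chains pilot-chain settings.
#' @param max_steps maximum number of geometric rescalings before giving up.
#' @return the tuned `ratedev` value, deterministic given `config$seed`.
#' @export
tune_ratedev <- function(tree, states, model, config = mcmc_config(),
                         pilot_iterations = 1e4, pilot_chains = 3,
                         max_steps = 20) {
  ci <- chain_inputs(tree, states, model)
  rd <- 1.0
  lo <- hi <- NA_real_  # bracketing values once the window is straddled
  for (step in seq_len(max_steps)) {
    acc <- att <- 0
    for (ch in seq_len(pilot_chains)) {
      res <- run_chain_raw(ci, model, rd, config,
                           seed = config$seed + ch - 1L,
                           sample_nodes = FALSE,
                           iterations = pilot_iterations,
                           burn_in = pilot_iterations / 10,
                           thin = max(1, pilot_iterations / 100))
      acc <- acc + res$acceptance[["rate_accepted"]]
      att <- att + res$acceptance[["rate_attempted"]]
    }
    rate <- if (att > 0) acc / att else 1
    if (rate >= 0.20 && rate <= 0.40) return(rd)
    # acceptance decreases with step size: too-high acceptance means the
    # step is a lower bracket, too-low an upper bracket
    if (rate > 0.40) lo <- rd else hi <- rd
    rd <- if (is.na(lo)) rd / 2
          else if (is.na(hi)) rd * 2
          else sqrt(lo * hi)  # log-bisection once bracketed
  }
  stop("tune_ratedev: no acceptable ratedev after ", max_steps,
       " rescalings; check that the model fits the data scale")
}

#' Run a Metropolis-Hastings / reversible-jump chain over trait-model rates
#'
#' The sampler updates one rate class per iteration with a reflected-uniform
#' proposal of half-width `ratedev`; each rate has an exponential prior whose
#' mean is itself sampled (uniform hyperprior, see [mcmc_config()]). With
#' `rj = TRUE` the chain additionally jumps between rate-class partitions
#' (tied rates and a zero-bin). At each recorded sample the internal-node
#' states are drawn once from their joint conditional distribution given the
#' tips and current rates, and tallied into per-node posteriors.
#'
#' @param tree a `chronogram`.
#' @param states named tip states (see [prune_log_likelihood()]).
#' @param model an [mk_model()] or [pair_model()].
#' @param config an [mcmc_config()].
#' @param chains number of chains; samples are pooled, acceptance is reported
#'   per chain. Chain `i` is seeded with `config$seed + i - 1`.
#' @param fix_rates freeze the rates at `init_rates` (no moves); used to
#'   check node-state sampling against exact conditional posteriors.
#' @param init_rates optional starting rates (required if `fix_rates`).
#' @return an object of class `mcmc_trace` with elements `samples` (data
#'   frame: iteration, model_id, rates, logL, hyper), `node_posterior`
#'   (internal nodes x states, normalized), `acceptance`, `config`.
#' @export
run_chain <- function(tree, states, model, config = mcmc_config(),
                      chains = 1, fix_rates = FALSE, init_rates = NULL) {
  ci <- chain_inputs(tree, states, model)
  if (fix_rates && is.null(init_rates))
    stop("fix_rates = TRUE requires init_rates")
  rd <- config$ratedev
  if (identical(rd, "auto"))
    rd <- if (fix_rates) 1.0 else tune_ratedev(tree, states, model, config)
  n <- n_free_rates(model)
  samp <- list(); tally <- NULL; accept <- list()
  for (ch in seq_len(chains)) {
    res <- run_chain_raw(ci, model, rd, config, seed = config$seed + ch - 1L,
                         fix_rates = fix_rates, init_rates = init_rates)
    rn <- paste0("r", seq_len(n))
    if (inherits(model, "mk_model")) rn <- c("q01", "q10")
    if (inherits(model, "pair_model")) rn <- names(model$rates)
    df <- data.frame(chain = ch,
                     sample = seq_len(length(res$logL)),
                     model_id = res$model_id,
                     logL = res$logL, hyper = res$hyper)
    rt <- res$rates; colnames(rt) <- rn
    samp[[ch]] <- cbind(df, rt)
    tally <- if (is.null(tally)) res$node_tally else tally + res$node_tally
    accept[[ch]] <- res$acceptance
  }
  samples <- do.call(rbind, samp)
  npost <- tally / pmax(rowSums(tally), 1)
  rownames(npost) <- ci$kd$ntip + seq_len(nrow(npost))
  colnames(npost) <- model$states
  structure(list(samples = samples, node_posterior = npost,
                 node_tally = tally, acceptance = accept,
                 ratedev = rd, model = model, config = config,
                 tree_ntip = ci$kd$ntip),
            class = "mcmc_trace")
}

#' Log marginal likelihood by the harmonic-mean estimator
#'
#' `log HM = log n - logsumexp(-logL_i)`, computed wholly in log space.
#' The harmonic mean is a high-variance estimator; a block-based Monte Carlo
#' standard error is attached as attribute `"mc_se"` when the trace is long
#' enough.
#'
#' @param trace an `mcmc_trace`, or a numeric vector of log-likelihood
#'   samples.
#' @return log marginal likelihood estimate (natural log).
#' @export
harmonic_mean_logL <- function(trace) {
  logL <- if (inherits(trace, "mcmc_trace")) trace$samples$logL else trace
  n <- length(logL)
  if (n < 2) stop("harmonic mean requires >= 2 recorded samples")
  hm <- log(n) - logsumexp(-logL)
  nb <- 10
  if (n >= 5 * nb) {
    blocks <- split(logL, cut(seq_len(n), nb, labels = FALSE))
    bh <- vapply(blocks, function(b) log(length(b)) - logsumexp(-b), numeric(1))
    attr(hm, "mc_se") <- stats::sd(bh) / sqrt(nb)
  }
  hm
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Export an MCMC trace and its node posteriors as TSV
#'
#' @param trace an `mcmc_trace`.
#' @param samples_file,nodes_file output paths (`NULL` to skip either).
#' @return invisibly, the trace.
#' @export
write_trace <- function(trace, samples_file = NULL, nodes_file = NULL) {
  if (!is.null(samples_file))
    write.table(trace$samples, samples_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(nodes_file)) {
    np <- data.frame(node = rownames(trace$node_posterior),
                     trace$node_posterior, check.names = FALSE)
    write.table(np, nodes_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(trace)
}

#' @export
print.mcmc_trace <- function(x, ...) {
  acc <- vapply(x$acceptance, function(a)
    a[["rate_accepted"]] / max(a[["rate_attempted"]], 1), numeric(1))
  cat(sprintf("mcmc_trace: %d samples (%d chain%s), ratedev %.4g, rate-move acceptance %s\n",
              nrow(x$samples), length(x$acceptance),
              if (length(x$acceptance) > 1) "s" else "", x$ratedev,
              paste(sprintf("%.2f", acc), collapse = "/")))
  invisible(x)
}
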