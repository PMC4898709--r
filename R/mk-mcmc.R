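## Bayesian MCMC over Mk gain/loss rates, integrating over a posterior
## sample of time trees: each iteration proposes a tree drawn uniformly
## from the sample together with a multiplier update of one rate, and
## accepts by Metropolis-Hastings on pruning likelihood x prior. Marginal
## ancestral states are computed at every retained iteration on the tree
## drawn at that iteration and averaged per tree.

#' Prior on an Mk rate
#'
#' @param type `"exponential"` (parameter: `mean`) or `"uniform"` on
#'   `(0, max)`.
#' @param mean,max hyperparameters (events/Ma). If `NULL`, `mk_mcmc()`
#'   fills in a tree-height-based default: exponential mean `1/h` or
#'   uniform max `100/h`, `h` the mean root age of the sample, so that a
#'   priori about one event is expected per root-to-tip path.
#' @return a `rate_prior` object.
#' @export
rate_prior <- function(type = c("exponential", "uniform"), mean = NULL,
                       max = NULL) {
  type <- match.arg(type)
  structure(list(type = type, mean = mean, max = max), class = "rate_prior")
}

.prior_logdens <- function(prior, q) {
  if (prior$type == "exponential")
    dexp(q, rate = 1 / prior$mean, log = TRUE)
  else
    ifelse(q > 0 & q < prior$max, -log(prior$max), -Inf)
}

.prior_draw <- function(prior, n = 1) {
  if (prior$type == "exponential") rexp(n, rate = 1 / prior$mean)
  else runif(n, 0, prior$max)
}

.prior_quantile <- function(prior, p) {
  if (prior$type == "exponential") qexp(p, rate = 1 / prior$mean)
  else p * prior$max
}

## effective sample size from the initial positive sequence of the ACF
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.01)
  k <- if (length(pos)) pos[1] - 1 else length(rho)
  tau <- 1 + 2 * sum(rho[seq_len(k)])
  max(1, n / max(tau, 1))
}

#' Bayesian Mk rates and ancestral states over a tree sample
#'
#' Fits the two-state Mk model by MCMC while integrating over topology and
#' branch-length uncertainty: one tree is drawn uniformly from `sample` at
#' each iteration (jointly with a log-scale multiplier proposal on one of
#' the two rates) and the move is accepted by Metropolis-Hastings on the
#' pruning likelihood times the rate priors. At every retained iteration
#' the marginal ancestral-state probabilities are computed on the drawn
#' tree; per tree, these reconstructions are averaged over the retained
#' iterations at which that tree was drawn.
#'
#' @param sample a [tree_sample] (or single phylo).
#' @param traits a [trait_table].
#' @param priors a list `list(q01 = rate_prior(...), q10 = rate_prior(...))`
#'   or a single [rate_prior] used for both.
#' @param iterations,burnin,thin chain length, burn-in fraction (of
#'   iterations) and thinning interval.
#' @param root root prior mode: `"uniform"`, `"stationary"` (recomputed at
#'   the current rates each evaluation) or a fixed numeric length-2 prior.
#' @param proposal_width width of the uniform window of the log-multiplier
#'   proposal.
#' @param seed RNG seed; the chain is bit-reproducible given
#'   (inputs, seed).
#' @param asr logical; compute and average marginal reconstructions at
#'   retained iterations (switch off for rate-only runs).
#' @return an object of class `mk_mcmc` with components `chain`
#'   (data.frame: iteration, q01, q10, loglik, tree), `asr` (per tree:
#'   averaged `P(state 1)` by internal node, `NULL` for trees never drawn
#'   after burn-in), `tree_draws`, `acceptance`, `priors`, `seed`.
#' @export
mk_mcmc <- function(sample, traits, priors = rate_prior("exponential"),
                    iterations = 1010000, burnin = 0.1, thin = 1000,
                    root = c("uniform", "stationary"),
                    proposal_width = 3, seed = 1, asr = TRUE) {
  if (inherits(sample, "phylo")) sample <- tree_sample(list(sample))
  ntree <- length(sample)
  if (inherits(priors, "rate_prior")) priors <- list(q01 = priors, q10 = priors)
  stopifnot(iterations > iterations * burnin, thin >= 1)
  hbar <- mean(vapply(sample, function(t)
    max(ape::node.depth.edgelength(t)), 0))
  for (nm in c("q01", "q10")) {
    if (priors[[nm]]$type == "exponential" && is.null(priors[[nm]]$mean))
      priors[[nm]]$mean <- 1 / hbar
    if (priors[[nm]]$type == "uniform" && is.null(priors[[nm]]$max))
      priors[[nm]]$max <- 100 / hbar
  }
  fixed_root <- NULL
  if (is.numeric(root)) {
    fixed_root <- root / sum(root)
    root <- "fixed"
  } else root <- match.arg(root)

  prep <- lapply(sample, .prep_tree)
  tipL <- lapply(sample, .tip_partials, traits = traits)

  rootp <- function(q01, q10) {
    switch(root,
      uniform = c(0.5, 0.5),
      fixed = fixed_root,
      stationary = if (q01 + q10 <= 0) c(0.5, 0.5) else
        c(q10, q01) / (q01 + q10))
  }
  ll_fun <- function(ti, q01, q10) {
    .mk_loglik_cpp(prep[[ti]]$edge, prep[[ti]]$elen, prep[[ti]]$ntip,
                   tipL[[ti]], q01, q10, rootp(q01, q10))
  }

  set.seed(seed)
  q <- c(priors$q01$mean %||% priors$q01$max / 100,
         priors$q10$mean %||% priors$q10$max / 100)
  ti <- sample.int(ntree, 1)
  ll <- ll_fun(ti, q[1], q[2])
  lp <- .prior_logdens(priors$q01, q[1]) + .prior_logdens(priors$q10, q[2])

  nburn <- floor(iterations * burnin)
  keep_at <- seq(nburn + thin, iterations, by = thin)
  nkeep <- length(keep_at)
  if (nkeep == 0) stop("no retained iterations: shorten burn-in or thinning")
  chain <- matrix(NA_real_, nkeep, 5,
                  dimnames = list(NULL, c("iteration", "q01", "q10",
                                          "loglik", "tree")))
  asr_sum <- vector("list", ntree)
  asr_n <- integer(ntree)
  accepted <- 0L
  accepted_post <- 0L
  k <- 1L
  for (it in seq_len(iterations)) {
    tj <- sample.int(ntree, 1)
    which_q <- sample.int(2L, 1)
    u <- proposal_width * (runif(1) - 0.5)
    qn <- q
    qn[which_q] <- q[which_q] * exp(u)
    lln <- ll_fun(tj, qn[1], qn[2])
    lpn <- .prior_logdens(priors$q01, qn[1]) +
      .prior_logdens(priors$q10, qn[2])
    ## Hastings ratio of the multiplier proposal is q'/q, i.e. +u in logs
    if (is.finite(lln + lpn) &&
          log(runif(1)) < (lln + lpn) - (ll + lp) + u) {
      q <- qn; ll <- lln; lp <- lpn; ti <- tj
      accepted <- accepted + 1L
      if (it > nburn) accepted_post <- accepted_post + 1L
    }
    if (k <= nkeep && it == keep_at[k]) {
      chain[k, ] <- c(it, q[1], q[2], ll, ti)
      if (asr) {
        p1 <- .mk_marginal_cpp(prep[[ti]]$edge, prep[[ti]]$elen,
                               prep[[ti]]$ntip, tipL[[ti]], q[1], q[2],
                               rootp(q[1], q[2]))
        if (is.null(asr_sum[[ti]])) asr_sum[[ti]] <- p1
        else asr_sum[[ti]] <- asr_sum[[ti]] + p1
        asr_n[ti] <- asr_n[ti] + 1L
      }
      k <- k + 1L
    }
  }
  if (accepted_post == 0L)
    warning("no accepted moves after burn-in: ",
            "rate prior or proposal scale likely mismatched to the data")
  asr_avg <- vector("list", ntree)
  for (i in seq_len(ntree)) {
    if (asr_n[i] > 0) {
      p1 <- asr_sum[[i]] / asr_n[i]
      names(p1) <- as.character(prep[[i]]$ntip + seq_along(p1))
      asr_avg[[i]] <- p1
    }
  }
  structure(list(
    chain = as.data.frame(chain),
    asr = if (asr) asr_avg else NULL,
    tree_draws = asr_n,
    n_trees = ntree,
    acceptance = accepted / iterations,
    priors = priors,
    root = root,
    proposal_width = proposal_width,
    iterations = iterations, burnin = burnin, thin = thin,
    seed = seed,
    trees = sample,
    call = match.call()
  ), class = "mk_mcmc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mk_mcmc <- function(x, ...) {
  cm <- coef(x)
  cat(sprintf(
    "Mk MCMC over %d tree(s): %d retained samples, acceptance %.2f\n",
    x$n_trees, nrow(x$chain), x$acceptance))
  cat(sprintf("  posterior mean gain q01 = %.5g, loss q10 = %.5g events/Ma\n",
              cm["q01"], cm["q10"]))
  invisible(x)
}

#' @export
coef.mk_mcmc <- function(object, ...) {
  c(q01 = mean(object$chain$q01), q10 = mean(object$chain$q10))
}

#' @export
summary.mk_mcmc <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  f <- function(v) c(mean = mean(v),
                     lower = unname(quantile(v, a)),
                     upper = unname(quantile(v, 1 - a)),
                     ess = .ess(v))
  out <- rbind(q01 = f(object$chain$q01), q10 = f(object$chain$q10))
  structure(list(rates = out, acceptance = object$acceptance,
                 retained = nrow(object$chain),
                 trees_drawn = sum(object$tree_draws > 0),
                 n_trees = object$n_trees, prob = prob),
            class = "summary.mk_mcmc")
}

#' @export
print.summary.mk_mcmc <- function(x, ...) {
  cat(sprintf("Posterior rate summary (%d retained samples, %.0f%% interval):\n",
              x$retained, 100 * x$prob))
  print(round(x$rates, 6))
  cat(sprintf("acceptance %.2f; %d of %d trees drawn after burn-in\n",
              x$acceptance, x$trees_drawn, x$n_trees))
  invisible(x)
}

#' @export
plot.mk_mcmc <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$chain$iteration, x$chain$q01, type = "l",
                 xlab = "iteration", ylab = "q01 (gain)", ...)
  graphics::plot(x$chain$iteration, x$chain$q10, type = "l",
                 xlab = "iteration", ylab = "q10 (loss)", ...)
  invisible(x)
}

## internal node -> "tipA|tipB": the two smallest tips drawn from distinct
## child subtrees, so the node is the MRCA of the pair
.node_id_pairs <- function(tree) {
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  minlab <- character(ntip + tree$Nnode)
  minlab[seq_len(ntip)] <- tree$tip.label
  kids <- split(po$edge[, 2], po$edge[, 1])
  out <- character(tree$Nnode)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    minlab[p] <- if (minlab[p] == "") minlab[ch] else
      min(minlab[p], minlab[ch])
  }
  for (v in ntip + seq_len(tree$Nnode)) {
    labs <- sort(minlab[kids[[as.character(v)]]])
    out[v - ntip] <- paste(labs[1], labs[min(2, length(labs))], sep = "|")
  }
  out
}

#' Write MCMC trace and averaged reconstructions
#'
#' `write_chain()` writes the retained samples as tab-separated
#' (iteration, q01, q10, loglik, tree index). `write_asr()` writes one row
#' per (tree, internal node) with the node identified by its
#' smallest-descendant-tip pair.
#'
#' @param fit an [mk_mcmc] object.
#' @param path output file.
#' @export
write_chain <- function(fit, path) {
  write.table(fit$chain, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain
#' @export
write_asr <- function(fit, path) {
  rows <- list()
  for (i in seq_along(fit$asr)) {
    if (is.null(fit$asr[[i]])) next
    ids <- .node_id_pairs(fit$trees[[i]])
    rows[[length(rows) + 1L]] <- data.frame(
      tree = i, node = ids, p_state1 = unname(fit$asr[[i]]))
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
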