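## From probabilistic reconstructions to discrete origin counts: binarize
## node marginals, scan edges for state changes, classify each gain's
## light-production mechanism from its descendant tips, and summarise the
## cross-tree distribution of gain counts.

## descendant tip indices per node (tips first, ape numbering)
.desc_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Binarize averaged marginal reconstructions
#'
#' Converts each tree's averaged marginal probabilities into discrete node
#' states: state 1 iff `P(1) > threshold`; ties (`P == threshold`) resolve
#' to state 0, so reconstruction is absence-conservative. Tip states come
#' from the trait table; a missing tip inherits its parent node's state
#' (contributing no event on its pendant edge).
#'
#' @param fit an [mk_mcmc] object (with reconstructions).
#' @param traits the [trait_table] used in the fit.
#' @param threshold binarization cutoff in (0, 1).
#' @return a list, one element per tree that was drawn after burn-in
#'   (others `NULL`): an integer vector of 0/1 states indexed by ape node
#'   number (tips then internal nodes).
#' @export
binarize_asr <- function(fit, traits, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  out <- vector("list", fit$n_trees)
  for (i in seq_along(fit$asr)) {
    p1 <- fit$asr[[i]]
    if (is.null(p1)) next
    tree <- fit$trees[[i]]
    ntip <- ape::Ntip(tree)
    st <- integer(ntip + tree$Nnode)
    st[ntip + seq_len(tree$Nnode)] <- as.integer(p1 > threshold)
    tipst <- as.integer(traits$state[match(tree$tip.label, traits$tip)])
    st[seq_len(ntip)] <- tipst
    if (anyNA(tipst)) {
      miss <- which(is.na(tipst))
      parent <- tree$edge[match(miss, tree$edge[, 2]), 1]
      st[miss] <- st[parent]
    }
    out[[i]] <- st
  }
  out
}

#' Count state transitions on a painted tree
#'
#' One event per edge whose parent and child states differ: gains (0 to 1)
#' are independent origins, losses (1 to 0) are reported separately and
#' never folded into origin counts.
#'
#' @param tree an [ape::phylo].
#' @param states integer 0/1 vector indexed by ape node number (tips
#'   `1..Ntip`, then internal nodes), covering every node.
#' @param traits optional [trait_table]; when given, each gain is
#'   classified by [classify_mechanism()].
#' @return data.frame with one row per event: `parent`, `child`,
#'   `direction` (`"gain"`/`"loss"`) and, when `traits` is given,
#'   `mechanism`.
#' @export
count_transitions <- function(tree, states, traits = NULL) {
  nall <- ape::Ntip(tree) + tree$Nnode
  if (length(states) < nall || anyNA(states[seq_len(nall)]))
    stop("every node and tip needs a binary state")
  ps <- states[tree$edge[, 1]]
  cs <- states[tree$edge[, 2]]
  hit <- which(ps != cs)
  ev <- data.frame(parent = tree$edge[hit, 1], child = tree$edge[hit, 2],
                   direction = ifelse(cs[hit] == 1, "gain", "loss"),
                   stringsAsFactors = FALSE)
  if (!is.null(traits) && nrow(ev)) {
    desc <- .desc_tips(tree)
    ev$mechanism <- NA_character_
    g <- ev$direction == "gain"
    ev$mechanism[g] <- vapply(ev$child[g], function(v)
      classify_mechanism(tree, v, traits, desc = desc), "")
  }
  ev
}

#' Classify the mechanism behind a gain
#'
#' A gain is labelled by the unique mechanism annotation among the
#' luminous (state-1) tips descending from the gained node: `"mixed"` if
#' more than one annotation occurs, `"unknown"` if only unknowns, and
#' `"unknown"` (with a warning) when reconstruction noise leaves a gain
#' with no luminous descendant tips at all.
#'
#' @param tree an [ape::phylo].
#' @param node the child node (or tip) of the gain edge.
#' @param traits a [trait_table].
#' @param desc precomputed descendant-tip list (internal use).
#' @return one of `"intrinsic"`, `"bacterial"`, `"unknown"`, `"mixed"`.
#' @export
classify_mechanism <- function(tree, node, traits, desc = NULL) {
  if (is.null(desc)) desc <- .desc_tips(tree)
  tips <- tree$tip.label[desc[[node]]]
  sub <- traits[match(tips, traits$tip), ]
  mech <- sub$mechanism[!is.na(sub$state) & sub$state == 1]
  mech <- mech[!is.na(mech)]
  if (!length(mech)) {
    warning("gain at node ", node, " has no luminous descendant tips; ",
            "mechanism set to 'unknown'")
    return("unknown")
  }
  known <- unique(mech[mech != "unknown"])
  if (length(known) > 1) "mixed"
  else if (length(known) == 1) known
  else "unknown"
}

## smallest richness-table clade (fewest sampled tips, then fewest species)
## whose MRCA subtree contains `node`
.containing_clade <- function(tree, node, richness, desc) {
  if (is.null(richness) || !nrow(richness)) return(NA_character_)
  best <- NA_character_; bestn <- Inf; bests <- Inf
  for (r in seq_len(nrow(richness))) {
    tips <- strsplit(richness$tips[r], ";", fixed = TRUE)[[1]]
    idx <- match(tips, tree$tip.label)
    if (anyNA(idx)) next
    m <- ape::getMRCA(tree, idx)
    if (is.null(m)) next
    members <- desc[[m]]
    inside <- if (node <= ape::Ntip(tree)) node %in% members
    else all(desc[[node]] %in% members)
    if (inside) {
      nn <- length(members); ss <- richness$species[r]
      if (nn < bestn || (nn == bestn && ss < bests)) {
        best <- richness$clade[r]; bestn <- nn; bests <- ss
      }
    }
  }
  best
}

#' Summarise origins across a tree sample
#'
#' Aggregates per-tree transition events into the cross-tree distribution
#' of gain counts (minimum, mode, median, central 95% interval), the
#' mechanism tally of a representative reconstruction, and described
#' species totals per mechanism from a richness table. The headline count
#' is the modal per-tree gain count; the minimum is always reported
#' alongside, matching the lower-bound reading of "evolved at least N
#' times". The representative tree is the lowest-index tree attaining the
#' modal count; its gains are labelled by the smallest named clade
#' containing them.
#'
#' @param events list of per-tree event data.frames from
#'   [count_transitions()] (`NULL` entries for trees without a
#'   reconstruction are skipped).
#' @param trees the [tree_sample] the events refer to.
#' @param richness optional [richness_table] for species totals.
#' @return an `origin_summary` object.
#' @export
summarize_origins <- function(events, trees, richness = NULL) {
  have <- which(!vapply(events, is.null, TRUE))
  if (!length(have)) stop("no reconstructed trees to summarise")
  gains <- vapply(have, function(i) sum(events[[i]]$direction == "gain"), 0L)
  losses <- vapply(have, function(i) sum(events[[i]]$direction == "loss"), 0L)
  tab <- table(gains)
  mode_count <- as.integer(names(tab)[which.max(tab)])
  qs <- unname(quantile(gains, c(0.025, 0.975), type = 1))
  rep_tree <- have[which(gains == mode_count)[1]]
  rep_ev <- events[[rep_tree]]
  rep_gain <- rep_ev[rep_ev$direction == "gain", , drop = FALSE]
  mech_tally <- integer(0)
  if (nrow(rep_gain) && !is.null(rep_gain$mechanism))
    mech_tally <- table(rep_gain$mechanism)
  species_totals <- NULL
  incomplete <- FALSE
  if (nrow(rep_gain)) {
    desc <- .desc_tips(trees[[rep_tree]])
    rep_gain$clade <- vapply(rep_gain$child, function(v)
      .containing_clade(trees[[rep_tree]], v, richness, desc), "")
    if (!is.null(richness)) {
      incomplete <- anyNA(rep_gain$clade)
      mechs <- unique(rep_gain$mechanism)
      species_totals <- vapply(mechs, function(m) {
        cl <- unique(rep_gain$clade[rep_gain$mechanism == m])
        cl <- cl[!is.na(cl)]
        sum(richness$species[match(cl, richness$clade)])
      }, 0)
    }
  }
  structure(list(
    per_tree = data.frame(tree = have, gains = gains, losses = losses),
    gains_min = min(gains), gains_mode = mode_count,
    gains_median = median(gains), gains_ci95 = qs,
    losses_median = median(losses),
    representative_tree = rep_tree,
    events = rep_gain,
    mechanism_tally = mech_tally,
    species_totals = species_totals,
    species_incomplete = incomplete
  ), class = "origin_summary")
}

#' @export
print.origin_summary <- function(x, ...) {
  cat("Independent origins (absence -> presence gains) across trees:\n")
  cat(sprintf("  modal %d, minimum %d, median %.1f, 95%% interval [%d, %d]\n",
              x$gains_mode, x$gains_min, x$gains_median,
              as.integer(x$gains_ci95[1]), as.integer(x$gains_ci95[2])))
  cat(sprintf("  losses (median per tree): %.1f\n", x$losses_median))
  if (length(x$mechanism_tally)) {
    cat("  mechanism tally (representative reconstruction): ",
        paste(sprintf("%s %d", names(x$mechanism_tally), x$mechanism_tally),
              collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$species_totals)) {
    tot <- sum(x$species_totals)
    cat("  described species by mechanism:\n")
    for (m in names(x$species_totals))
      cat(sprintf("    %s: %.0f (%.0f%%)\n", m, x$species_totals[m],
                  100 * x$species_totals[m] / tot))
    if (x$species_incomplete)
      cat("    (incomplete: some gains lack a covering richness clade)\n")
  }
  invisible(x)
}

#' Threshold sensitivity of the origin count
#'
#' Re-binarizes the same reconstructions over a grid of thresholds and
#' reports modal and minimum gain counts at each, a built-in check that
#' the headline number is not an artefact of the (undocumented in common
#' practice) binarization cutoff.
#'
#' @param fit an [mk_mcmc] object.
#' @param traits the [trait_table] used in the fit.
#' @param thresholds probability grid.
#' @return data.frame: threshold, gains_mode, gains_min, gains_median.
#' @export
origin_sensitivity <- function(fit, traits,
                               thresholds = seq(0.5, 0.95, by = 0.05)) {
  out <- lapply(thresholds, function(th) {
    st <- binarize_asr(fit, traits, threshold = th)
    ev <- lapply(seq_along(st), function(i)
      if (is.null(st[[i]])) NULL else
        count_transitions(fit$trees[[i]], st[[i]]))
    s <- summarize_origins(ev, fit$trees)
    data.frame(threshold = th, gains_mode = s$gains_mode,
               gains_min = s$gains_min, gains_median = s$gains_median)
  })
  do.call(rbind, out)
}

#' Expected gain count by stochastic character mapping
#'
#' Cross-check estimator for the number of origins: samples full character
#' histories (joint node states from their conditional distributions, then
#' endpoint-conditioned paths along each branch by rejection sampling) and
#' returns the mean number of 0-to-1 transitions per history. Unlike edge
#' counting on binarized marginals, this accounts for multiple changes on
#' a branch.
#'
#' @inheritParams tree_loglik
#' @param nsim number of sampled histories.
#' @param seed RNG seed.
#' @param max_tries rejection cap per branch before falling back to the
#'   minimal (0 or 1 change) path.
#' @return numeric: mean gains per history, with attribute `"gains"` (the
#'   per-history counts).
#' @export
expected_gains_simmap <- function(tree, traits, params,
                                  root = root_prior("uniform"),
                                  nsim = 100, seed = 1, max_tries = 1000) {
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(1, ntip + tree$Nnode, 2)
  L[seq_len(ntip), ] <- .tip_partials(tree, traits)
  ## downward pass storing per-node partials (normalized)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    P <- .mk_pmat_cpp(params$q01, params$q10, po$edge.length[e])
    contrib <- P %*% L[ch, ]
    L[p, ] <- L[p, ] * as.numeric(contrib)
    L[p, ] <- L[p, ] / max(L[p, ])
  }
  rootnode <- po$edge[nrow(po$edge), 1]
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  prelen <- rev(po$edge.length)
  s <- params$q01 + params$q10
  gains <- integer(nsim)
  for (k in seq_len(nsim)) {
    st <- integer(ntip + tree$Nnode)
    w <- as.numeric(root) * L[rootnode, ]
    st[rootnode] <- rbinom(1, 1, w[2] / sum(w))
    g <- 0L
    for (e in seq_len(nrow(pre))) {
      p <- pre[e, 1]; ch <- pre[e, 2]; t <- prelen[e]
      P <- .mk_pmat_cpp(params$q01, params$q10, t)
      w <- P[st[p] + 1, ] * L[ch, ]
      st[ch] <- rbinom(1, 1, w[2] / sum(w))
      ## endpoint-conditioned path by rejection from the forward process
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cur <- st[p]; tau <- 0; ng <- 0L
        repeat {
          rate <- if (cur == 0) params$q01 else params$q10
          if (rate <= 0) break
          tau <- tau + rexp(1, rate)
          if (tau > t) break
          if (cur == 0) ng <- ng + 1L
          cur <- 1L - cur
        }
        if (cur == st[ch]) { g <- g + ng; ok <- TRUE; break }
      }
      if (!ok && st[p] == 0 && st[ch] == 1) g <- g + 1L
    }
    gains[k] <- g
  }
  structure(mean(gains), gains = gains)
}
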