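## Piecewise birth-death likelihood on a time tree with terminal richness,
## and the stepwise AICc rate-shift search. The likelihood of a piece
## combines (a) the reconstructed-process density of its internal
## branching times and (b), for each terminal of stem age t_s carrying m
## described species, the survival-conditioned geometric "taxonomic"
## probability (1 - beta_s) beta_s^(m-1).
##
## The density is assembled per edge so that pieces are additive: an edge
## running from age a down to age b contributes p1(a)/p1(b) when its child
## is an internal node (p1(t) the probability that a lineage of age t
## leaves exactly one reconstructed descendant), the taxonomic term when
## its child is a terminal, and each branching event (non-root internal
## node) contributes lambda. The basal piece starts from the two crown
## lineages, so the root's own branching is not counted.

.log_expm1 <- function(x) ifelse(x > 30, x, log(expm1(x)))

## log p1(t), log beta(t), log(1-beta), log(1-alpha) for net rate r,
## relative extinction eps; alpha = eps * beta is the extinction
## probability of a lineage of age t, p1 = (1-alpha)(1-beta)
.bd_terms <- function(r, eps, t) {
  rt <- r * t
  logS <- rt + log1p(-eps * exp(-rt))        # log(e^{rt} - eps)
  list(logp1 = -rt + 2 * log1p(-eps) - 2 * log1p(-eps * exp(-rt)),
       logbeta = .log_expm1(rt) - logS,
       log1mbeta = log1p(-eps) - logS,
       log1malpha = rt + log1p(-eps) - logS)
}

## per-edge data table used by every piece likelihood
.bd_edge_data <- function(tree, m) {
  age <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  data.frame(parent = parent, child = child,
             start = age[parent], end = age[child],
             pendant = child <= ntip,
             m = ifelse(child <= ntip, m[child], NA_real_))
}

## piece log-likelihood given edge-data rows
.bd_piece_loglik <- function(r, eps, ed) {
  if (r <= 0 || eps < 0 || eps >= 1) return(-Inf)
  ll <- 0
  int <- !ed$pendant
  nevents <- sum(int)
  if (nevents) ll <- ll + nevents * log(r / (1 - eps))
  if (any(int)) {
    a <- .bd_terms(r, eps, ed$start[int])
    b <- .bd_terms(r, eps, ed$end[int])
    ll <- ll + sum(a$logp1 - b$logp1)
  }
  if (any(ed$pendant)) {
    ## terminal of stem age t_s with m described species: unconditioned
    ## geometric p1(t_s) beta^(m-1) = (1-alpha)(1-beta)beta^(m-1), which
    ## reduces to p1 for m = 1 (a resolved tip) and to (1-beta)beta^(m-1)
    ## when eps = 0
    ts <- ed$start[ed$pendant]
    m <- ed$m[ed$pendant]
    tm <- .bd_terms(r, eps, pmax(ts, 1e-10))
    ll <- ll + sum(tm$logp1 + (m - 1) * tm$logbeta)
  }
  ## condition on survival of the piece's basal lineage(s): both crown
  ## lineages for the root piece, the stem lineage for a shift piece
  tbase <- max(ed$start)
  nbase <- sum(ed$start >= tbase - 1e-12)
  ll <- ll - nbase * .bd_terms(r, eps, tbase)$log1malpha
  if (!is.finite(ll)) -Inf else ll
}

## ML fit of (r, eps) on one piece, multiple eps starts
.bd_fit_piece <- function(ed, eps_starts = c(0, 0.5, 0.9),
                          eps_max = 0.99, r_start = NULL) {
  span <- max(ed$start)
  rich <- sum(ed$m, na.rm = TRUE) + sum(!ed$pendant)
  r0 <- r_start %||% max(log(max(rich, 3) / 2) / max(span, 1e-6), 1e-4)
  best <- NULL
  for (e0 in eps_starts) {
    fit <- tryCatch(
      nlminb(c(log(r0), e0),
             function(p) -.bd_piece_loglik(exp(p[1]), p[2], ed),
             lower = c(log(1e-8), 0), upper = c(log(20), eps_max)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) return(NULL)
  list(r = exp(best$par[1]), eps = best$par[2], loglik = -best$objective)
}

#' Birth-death log-likelihood of a time tree with terminal richness
#'
#' Single-piece (homogeneous rates) version of the likelihood used by the
#' shift search: reconstructed-process density of the internal branching
#' times plus a taxonomic term `(1 - beta_s) beta_s^(m - 1)` per terminal
#' of stem age `t_s` and richness `m`. With `eps = 0` and all richness 1
#' this is the Yule log-likelihood of the branching times.
#'
#' @param tree ultrametric [ape::phylo] with `>= 2` tips.
#' @param bd a [bd_params].
#' @param richness per-tip described species counts: a named numeric
#'   vector, a [richness_table] (distributed over sampled tips by
#'   [tip_richness()]), or `NULL` for all 1.
#' @return log-likelihood.
#' @export
bd_loglik <- function(tree, bd, richness = NULL) {
  m <- tip_richness(tree, richness)
  ed <- .bd_edge_data(tree, m)
  .bd_piece_loglik(bd$r, bd$eps, ed)
}

#' Per-tip richness vector
#'
#' Expands clade-level described species counts to the sampled terminals:
#' each clade's count is split over its sampled tips in integer shares
#' (remainder to the first tips) so the total is conserved; tips not
#' covered by any clade get richness 1. Nested clades are not supported;
#' overlapping clade rows raise an error.
#'
#' @param tree an [ape::phylo].
#' @param richness `NULL`, a named numeric vector (partial cover allowed),
#'   or a [richness_table].
#' @return numeric vector of length `Ntip(tree)` in tip order, all `>= 1`.
#' @export
tip_richness <- function(tree, richness = NULL) {
  ntip <- ape::Ntip(tree)
  m <- rep(1, ntip)
  if (is.null(richness)) return(m)
  if (is.numeric(richness)) {
    idx <- match(names(richness), tree$tip.label)
    if (anyNA(idx)) stop("richness names not in tree: ",
                         paste(names(richness)[is.na(idx)], collapse = ", "))
    m[idx] <- richness
    if (any(m < 1)) stop("tip richness must be >= 1")
    return(m)
  }
  assigned <- logical(ntip)
  for (i in seq_len(nrow(richness))) {
    tips <- strsplit(richness$tips[i], ";", fixed = TRUE)[[1]]
    idx <- match(tips, tree$tip.label)
    if (anyNA(idx)) stop("richness clade '", richness$clade[i],
                         "' lists tips absent from the tree")
    if (any(assigned[idx]))
      stop("overlapping richness clades at tip ",
           tree$tip.label[idx[assigned[idx]][1]])
    assigned[idx] <- TRUE
    k <- length(idx); S <- richness$species[i]
    share <- rep(S %/% k, k)
    share[seq_len(S %% k)] <- share[seq_len(S %% k)] + 1
    m[idx] <- share
  }
  m
}

#' Stepwise diversification-rate-shift search
#'
#' Fits a homogeneous birth-death model to the tree (with terminal
#' richness) by maximum likelihood, then iteratively proposes a rate shift
#' on every eligible stem edge, refits the affected pieces, and accepts
#' the best candidate whenever it improves AICc by at least `threshold`;
#' stops when no candidate does. A shift placed on an edge moves that edge
#' and the edges of its subtree that belong to the donor piece into a new
#' piece (nested earlier shifts keep theirs). Deterministic given the tree
#' and threshold.
#'
#' @param tree ultrametric [ape::phylo] with `>= 3` tips.
#' @param richness as in [tip_richness()].
#' @param threshold required AICc improvement to accept a shift
#'   (default 4).
#' @param eps_max upper bound on relative extinction during optimisation.
#' @param max_shifts cap on accepted shifts.
#' @return an object of class `medusa_fit`: `pieces` (per-piece shift
#'   edge, r, eps, lambda, mu, log-likelihood, AICc improvement when
#'   accepted), `edge_piece` (piece id per edge row), `loglik`, `aicc`,
#'   `n_param`.
#' @details AICc is `-2 lnL + 2k + 2k(k+1)/(n - k - 1)` with `k` counted
#'   as 2 parameters per piece plus 1 per shift location and `n` the
#'   number of nodes of the tree (branching times plus terminal richness
#'   observations).
#' @export
medusa_fit <- function(tree, richness = NULL, threshold = 4,
                       eps_max = 0.99, max_shifts = Inf) {
  if (ape::Ntip(tree) < 3) stop("need >= 3 tips")
  m <- tip_richness(tree, richness)
  ed <- .bd_edge_data(tree, m)
  nedge <- nrow(ed)
  nobs <- ape::Ntip(tree) + tree$Nnode
  ## edges of the subtree rooted at each edge's child (incl. the edge)
  below <- vector("list", nedge)
  pot <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(pot$edge[, 1], pot$edge[, 2]),
               paste(ed$parent, ed$child))
  kids_edges <- split(seq_len(nedge), ed$parent)
  for (e in ord) {
    ch <- ed$child[e]
    sub <- kids_edges[[as.character(ch)]]
    below[[e]] <- c(e, unlist(below[sub], use.names = FALSE))
  }
  aicc <- function(ll, npiece) {
    k <- 2 * npiece + (npiece - 1)
    -2 * ll + 2 * k + 2 * k * (k + 1) / (nobs - k - 1)
  }
  piece_of <- rep(1L, nedge)
  base <- .bd_fit_piece(ed, eps_max = eps_max)
  if (is.null(base)) stop("single-rate birth-death fit failed to converge")
  pieces <- list(list(shift_edge = NA_integer_, r = base$r, eps = base$eps,
                      loglik = base$loglik, daicc = NA_real_))
  cur_aicc <- aicc(base$loglik, 1)
  trace <- data.frame(step = 0L, shift_edge = NA_integer_,
                      loglik = base$loglik, aicc = cur_aicc)
  ## Stepwise search, two stages per round: (1) scan every eligible edge,
  ## fitting only the candidate piece and holding the donor remainder at
  ## its current ML parameters (a lower bound on the candidate's gain);
  ## (2) fully refit both affected pieces for the best-scoring handful
  ## before deciding acceptance.
  repeat {
    if (length(pieces) - 1L >= max_shifts) break
    stems <- vapply(pieces, function(p) p$shift_edge, 0L)
    scan_ll <- rep(-Inf, nedge)
    scan_new <- vector("list", nedge)
    for (e in seq_len(nedge)) {
      if (e %in% stems) next
      donor <- piece_of[e]
      new_idx <- intersect(below[[e]], which(piece_of == donor))
      rem_idx <- setdiff(which(piece_of == donor), new_idx)
      if (!length(rem_idx)) next
      fit_new <- .bd_fit_piece(ed[new_idx, , drop = FALSE],
                               eps_starts = unique(c(pieces[[donor]]$eps, 0)),
                               eps_max = eps_max,
                               r_start = pieces[[donor]]$r)
      if (is.null(fit_new)) next
      ll_rem0 <- .bd_piece_loglik(pieces[[donor]]$r, pieces[[donor]]$eps,
                                  ed[rem_idx, , drop = FALSE])
      scan_ll[e] <- sum(vapply(seq_along(pieces), function(j)
        if (j == donor) ll_rem0 else pieces[[j]]$loglik, 0)) +
        fit_new$loglik
      scan_new[[e]] <- fit_new
    }
    top <- order(scan_ll, decreasing = TRUE)
    top <- top[is.finite(scan_ll[top])][seq_len(min(3, sum(is.finite(scan_ll))))]
    best <- NULL
    for (e in top) {
      donor <- piece_of[e]
      new_idx <- intersect(below[[e]], which(piece_of == donor))
      rem_idx <- setdiff(which(piece_of == donor), new_idx)
      fit_new <- .bd_fit_piece(ed[new_idx, , drop = FALSE],
                               eps_max = eps_max,
                               r_start = pieces[[donor]]$r)
      fit_rem <- .bd_fit_piece(ed[rem_idx, , drop = FALSE],
                               eps_max = eps_max,
                               r_start = pieces[[donor]]$r)
      if (is.null(fit_new) || is.null(fit_rem)) {
        warning("optimizer failed on candidate shift at edge ", e,
                "; skipped")
        next
      }
      ll_tot <- sum(vapply(seq_along(pieces), function(j)
        if (j == donor) fit_rem$loglik else pieces[[j]]$loglik, 0)) +
        fit_new$loglik
      cand_aicc <- aicc(ll_tot, length(pieces) + 1L)
      if (is.null(best) || cand_aicc < best$aicc)
        best <- list(edge = e, donor = donor, new = fit_new,
                     rem = fit_rem, aicc = cand_aicc, loglik = ll_tot)
    }
    if (is.null(best) || cur_aicc - best$aicc < threshold) break
    donor <- best$donor
    new_idx <- intersect(below[[best$edge]], which(piece_of == donor))
    piece_of[new_idx] <- length(pieces) + 1L
    pieces[[donor]]$r <- best$rem$r
    pieces[[donor]]$eps <- best$rem$eps
    pieces[[donor]]$loglik <- best$rem$loglik
    pieces[[length(pieces) + 1L]] <- list(
      shift_edge = best$edge, r = best$new$r, eps = best$new$eps,
      loglik = best$new$loglik, daicc = cur_aicc - best$aicc)
    trace <- rbind(trace, data.frame(
      step = nrow(trace), shift_edge = best$edge,
      loglik = best$loglik, aicc = best$aicc))
    cur_aicc <- best$aicc
  }
  ptab <- do.call(rbind, lapply(seq_along(pieces), function(j) {
    p <- pieces[[j]]
    lam <- p$r / (1 - p$eps)
    data.frame(piece = j, shift_edge = p$shift_edge,
               shift_node = if (is.na(p$shift_edge)) NA_integer_
               else ed$child[p$shift_edge],
               r = p$r, eps = p$eps, lambda = lam, mu = lam * p$eps,
               loglik = p$loglik, daicc = p$daicc)
  }))
  ll <- sum(ptab$loglik)
  structure(list(pieces = ptab, edge_piece = piece_of,
                 loglik = ll, aicc = aicc(ll, nrow(ptab)),
                 n_param = 2 * nrow(ptab) + (nrow(ptab) - 1),
                 threshold = threshold, nobs = nobs,
                 trace = trace, tree = tree, tip_richness = m,
                 call = match.call()),
            class = "medusa_fit")
}

#' @export
print.medusa_fit <- function(x, ...) {
  cat(sprintf(
    "Stepwise rate-shift fit: %d piece(s), logLik %.3f, AICc %.3f\n",
    nrow(x$pieces), x$loglik, x$aicc))
  print(x$pieces, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.medusa_fit <- function(object, ...) {
  p <- object$pieces
  out <- as.matrix(p[, c("r", "eps", "lambda", "mu")])
  rownames(out) <- ifelse(is.na(p$shift_edge), "background",
                          paste0("shift@edge", p$shift_edge))
  out
}

#' @export
summary.medusa_fit <- function(object, ...) {
  cat(sprintf("Pieces: %d (threshold AICc improvement %.2f)\n",
              nrow(object$pieces), object$threshold))
  print(object$pieces, digits = 4, row.names = FALSE)
  cat("\nStep trace:\n")
  print(object$trace, digits = 6, row.names = FALSE)
  invisible(object)
}

#' @export
logLik.medusa_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_param, class = "logLik")
}

#' Background birth-death rates of a shift fit
#'
#' The basal (root) piece of a [medusa_fit()], used as the default
#' envelope rates so that the richness envelopes are coupled to the same
#' diversification analysis.
#'
#' @param fit a `medusa_fit`.
#' @return a [bd_params].
#' @export
background_bd <- function(fit) {
  p <- fit$pieces[is.na(fit$pieces$shift_edge), ]
  bd_params(p$r[1], p$eps[1])
}
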