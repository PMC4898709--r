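## Two-state continuous-time Markov (Mk) model of trait gain and loss.
## q01 is the gain rate (absent -> present), q10 the loss rate, both in
## events per lineage per Ma. The pruning likelihood and marginal ASR run
## in compiled code; these wrappers do the bookkeeping between ape's tree
## representation and the trait table.

#' Mk rate parameters
#'
#' @param q01 gain rate (0 to 1), events/Ma, `>= 0`.
#' @param q10 loss rate (1 to 0), events/Ma, `>= 0`.
#' @return an `mk_params` object.
#' @export
mk_params <- function(q01, q10) {
  if (!is.finite(q01) || !is.finite(q10) || q01 < 0 || q10 < 0)
    stop("rates must be finite and >= 0")
  structure(list(q01 = q01, q10 = q10), class = "mk_params")
}

#' @export
print.mk_params <- function(x, ...) {
  cat(sprintf("Mk rates: gain q01 = %.6g, loss q10 = %.6g events/Ma\n",
              x$q01, x$q10))
  invisible(x)
}

#' Transition probability matrix of the two-state chain
#'
#' Closed form: `P00 = (q10 + q01 exp(-(q01+q10) t)) / (q01 + q10)` and
#' analogously for the other entries; the identity matrix when both rates
#' are zero or `t = 0`.
#'
#' @param params [mk_params].
#' @param t elapsed time, Ma, `>= 0`.
#' @return 2x2 row-stochastic matrix with dimnames `0`/`1`.
#' @export
transition_matrix <- function(params, t) {
  if (!is.finite(t) || t < 0) stop("t must be finite and >= 0")
  P <- .mk_pmat_cpp(params$q01, params$q10, t)
  dimnames(P) <- list(c("0", "1"), c("0", "1"))
  P
}

#' Root state prior
#'
#' @param mode `"uniform"` (0.5, 0.5), `"stationary"`
#'   (`q10/(q01+q10)`, `q01/(q01+q10)`), or `"fixed"` (supply `p1`).
#' @param params [mk_params], needed for `"stationary"`.
#' @param p1 probability of state 1 at the root for `"fixed"`.
#' @return length-2 numeric prior `(P(0), P(1))`, summing to 1.
#' @export
root_prior <- function(mode = c("uniform", "stationary", "fixed"),
                       params = NULL, p1 = NULL) {
  mode <- match.arg(mode)
  p <- switch(mode,
    uniform = c(0.5, 0.5),
    stationary = {
      if (is.null(params)) stop("stationary root prior needs params")
      s <- params$q01 + params$q10
      if (s <= 0) c(0.5, 0.5) else c(params$q10, params$q01) / s
    },
    fixed = {
      if (is.null(p1) || p1 < 0 || p1 > 1) stop("fixed root prior needs p1 in [0,1]")
      c(1 - p1, p1)
    })
  structure(p, mode = mode)
}

## tip partial-likelihood matrix (ntip x 2) from a trait table; missing
## states contribute (1,1), i.e. full ambiguity
.tip_partials <- function(tree, traits) {
  st <- traits$state[match(tree$tip.label, traits$tip)]
  if (anyNA(match(tree$tip.label, traits$tip)))
    stop("tip without a trait row: ",
         tree$tip.label[is.na(match(tree$tip.label, traits$tip))][1])
  L <- matrix(1, ape::Ntip(tree), 2)
  L[!is.na(st) & st == 0, 2] <- 0
  L[!is.na(st) & st == 1, 1] <- 0
  L
}

## postorder edge/length arrays reused across likelihood calls
.prep_tree <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, elen = po$edge.length, ntip = ape::Ntip(tree))
}

#' Pruning log-likelihood of a binary trait on a time tree
#'
#' Felsenstein pruning with per-node rescaling; missing tip states enter as
#' ambiguous partials (1, 1). Polytomies are handled natively.
#'
#' @param tree an [ape::phylo].
#' @param traits a [trait_table] covering every tip (missing states allowed).
#' @param params [mk_params].
#' @param root a [root_prior] (or any length-2 nonnegative vector summing
#'   to 1).
#' @return log-likelihood (finite unless the data have probability 0).
#' @export
tree_loglik <- function(tree, traits, params, root = root_prior("uniform")) {
  if (any(!is.finite(tree$edge.length))) stop("non-finite branch length")
  pr <- .prep_tree(tree)
  L <- .tip_partials(tree, traits)
  .mk_loglik_cpp(pr$edge, pr$elen, pr$ntip, L, params$q01, params$q10,
                 as.numeric(root))
}

#' Marginal ancestral-state reconstruction
#'
#' For each internal node, the marginal posterior probability of state 1
#' (presence), integrating over all other nodes' states, by combining
#' downward (subtree) and upward (rest-of-tree) partial likelihoods.
#'
#' @inheritParams tree_loglik
#' @return numeric vector of `P(state = 1)` named by internal node number
#'   (ape numbering: `Ntip+1` is the root).
#' @export
marginal_asr <- function(tree, traits, params, root = root_prior("uniform")) {
  pr <- .prep_tree(tree)
  L <- .tip_partials(tree, traits)
  p1 <- .mk_marginal_cpp(pr$edge, pr$elen, pr$ntip, L, params$q01,
                         params$q10, as.numeric(root))
  names(p1) <- as.character(pr$ntip + seq_along(p1))
  p1
}
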