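# Independent oracles used across the suite. Each is deliberately written
# in the most naive correct way (exhaustive enumeration, flat loops,
# generic matrix exponentials) so it shares no code path with the package.

# 2x2 transition probabilities via a generic matrix exponential
pmat_oracle <- function(q01, q10, t) {
  Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
  as.matrix(Matrix::expm(Q * t))
}

# Exhaustive joint-assignment likelihood and node marginals for a binary
# trait: sums over all 2^Nnode internal state assignments.
enum_mk <- function(tree, tip_states, q01, q10, rootp = c(0.5, 0.5)) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  P <- lapply(tree$edge.length, function(t) pmat_oracle(q01, q10, t))
  tipL <- rbind(`0` = c(1, 0), `1` = c(0, 1), miss = c(1, 1))
  tl <- tipL[ifelse(is.na(tip_states), 3, tip_states + 1), , drop = FALSE]
  root <- ntip + 1
  grid <- as.matrix(expand.grid(rep(list(0:1), nn)))
  tot <- 0
  marg <- numeric(nn)
  for (row in seq_len(nrow(grid))) {
    s <- grid[row, ]
    lik <- rootp[s[1] + 1]   # root is the first internal node (ntip+1)
    for (e in seq_len(nrow(tree$edge))) {
      a <- s[tree$edge[e, 1] - ntip]
      ch <- tree$edge[e, 2]
      lik <- lik * if (ch <= ntip)
        sum(P[[e]][a + 1, ] * tl[ch, ])
      else P[[e]][a + 1, s[ch - ntip] + 1]
    }
    tot <- tot + lik
    marg <- marg + lik * s
  }
  list(loglik = log(tot), marginal_p1 = marg / tot)
}

# flat edge-scan transition counter
edge_scan_events <- function(tree, states) {
  gains <- 0L; losses <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    a <- states[tree$edge[e, 1]]
    b <- states[tree$edge[e, 2]]
    if (a == 0 && b == 1) gains <- gains + 1L
    if (a == 1 && b == 0) losses <- losses + 1L
  }
  c(gains = gains, losses = losses)
}

# gains minus losses along the path from the root to a tip
path_net_change <- function(tree, states, tip) {
  ntip <- ape::Ntip(tree)
  par <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2])
  v <- tip; net <- 0L
  while (!is.na(par[v])) {
    p <- tree$edge[par[v], 1]
    net <- net + (states[v] - states[p])
    v <- p
  }
  net
}

# log clade-credibility score of each tree via ape::prop.part
mcc_scores_oracle <- function(sample) {
  pp <- ape::prop.part(sample)
  freq <- attr(pp, "number") / length(sample)
  labs <- attr(pp, "labels")
  key <- vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "|"), "")
  lookup <- setNames(freq, key)
  vapply(sample, function(tr) {
    pt <- ape::prop.part(tr)
    k <- vapply(pt, function(idx)
      paste(sort(attr(pt, "labels")[idx]), collapse = "|"), "")
    sum(log(lookup[k]))
  }, 0)
}

# vectorized birth-death crown-size simulator: two stem lineages of age t,
# both conditioned on survival; returns n surviving crown sizes
sim_crown_sizes <- function(r, eps, t, n) {
  lambda <- r / (1 - eps); mu <- lambda * eps
  sim_stems <- function(m) {
    N <- rep(1L, m); tm <- numeric(m); active <- N > 0
    while (any(active)) {
      k <- which(active)
      dt <- rexp(length(k), N[k] * (lambda + mu))
      tm[k] <- tm[k] + dt
      done <- tm[k] > t
      if (any(done)) active[k[done]] <- FALSE
      k <- k[!done]
      if (!length(k)) next
      birth <- runif(length(k)) < lambda / (lambda + mu)
      N[k] <- N[k] + ifelse(birth, 1L, -1L)
      dead <- N[k] == 0L
      if (any(dead)) active[k[dead]] <- FALSE
    }
    N
  }
  out <- integer(0)
  while (length(out) < 2 * n) {
    batch <- sim_stems(2 * n)
    out <- c(out, batch[batch > 0])
  }
  out <- out[seq_len(2 * n)]
  out[seq_len(n)] + out[n + seq_len(n)]
}
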