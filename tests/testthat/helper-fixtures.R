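# Shared fixtures, generated in code at test time.

# random ultrametric tree (coalescent shape is fine for likelihood tests)
rand_tree <- function(n, seed) {
  set.seed(seed)
  ape::rcoal(n)
}

make_traits <- function(tree, states, mech = "unknown") {
  trait_table(data.frame(
    tip = tree$tip.label, state = states,
    mechanism = ifelse(!is.na(states) & states == 1, mech, NA_character_),
    stringsAsFactors = FALSE))
}

# background Yule tree with a planted fast clade grafted onto a pendant
# edge; returns the tree and the planted clade's tip labels
plant_shift_tree <- function(seed, n_bg = 90, n_sub = 30, lambda = 0.1,
                             mult = 10) {
  bg <- simulate_bd_tree(lambda, 0, n_tips = n_bg, seed = seed)
  sub <- simulate_bd_tree(lambda * mult, 0, n_tips = n_sub,
                          seed = seed + 5000)
  sub$tip.label <- paste0("s", seq_len(ape::Ntip(sub)))
  ca <- max(node_ages(sub))
  pend <- which(bg$edge[, 2] <= ape::Ntip(bg))
  cand <- which(bg$edge.length[pend] > ca * 1.5)
  tip <- bg$edge[pend[cand[1]], 2]
  pos <- ca * 1.2
  sub$root.edge <- pos - ca
  tr <- ape::bind.tree(bg, sub, where = tip, position = pos)
  list(tree = tr, subtips = sub$tip.label)
}

# the default fish fixture is expensive; build it once per test session
fish_fixture_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fish_fixture(seed = 1)
    cache
  }
})

# topology equality ignoring branch lengths (quiet on rooted trees)
same_topology <- function(a, b)
  isTRUE(ape::all.equal.phylo(a, b, use.edge.length = FALSE))
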