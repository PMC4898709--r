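test_that("birth-death simulation honours stops, pruning and seeds", {
  tr <- simulate_bd_tree(0.1, 0, n_tips = 50, seed = 1)
  expect_equal(ape::Ntip(tr), 50)
  expect_true(ape::is.ultrametric(tr))
  # with extinction the reconstructed tree still has exactly n tips
  tr2 <- simulate_bd_tree(0.15, 0.08, n_tips = 40, seed = 2)
  expect_equal(ape::Ntip(tr2), 40)
  expect_true(ape::is.ultrametric(tr2))
  # determinism at the Newick level
  expect_identical(ape::write.tree(simulate_bd_tree(0.1, 0.05, n_tips = 30,
                                                    seed = 7)),
                   ape::write.tree(simulate_bd_tree(0.1, 0.05, n_tips = 30,
                                                    seed = 7)))
  expect_error(simulate_bd_tree(0.1, 0, n_tips = 10, age = 5), "exactly one")
  expect_error(simulate_bd_tree(-1, 0, n_tips = 10), "lambda")
})

test_that("age-stopped Yule clades hit the 2 e^{lambda t} expectation", {
  set.seed(5)
  lam <- 0.3; t <- 5
  n <- 1500
  tips <- vapply(seq_len(n), function(i)
    ape::Ntip(simulate_bd_tree(lam, 0, age = t, seed = 10000 + i)), 0L)
  # both crown lineages conditioned to survive = always true for mu = 0
  expected <- 2 * exp(lam * t)
  se <- sd(tips) / sqrt(n)
  expect_lt(abs(mean(tips) - expected), 3 * se + 1e-9)
})

test_that("trait simulation is exact at the endpoints", {
  tr <- rand_tree(40, 2)
  # zero rates: everything inherits the root state
  s0 <- simulate_traits(tr, mk_params(0, 0), root_state = 1, seed = 3)
  expect_true(all(s0$node_states == 1))
  expect_equal(sum(count_transitions(tr, s0$node_states)$direction ==
                     "gain"), 0)
  # determinism
  s1 <- simulate_traits(tr, mk_params(0.4, 0.2), seed = 9)
  s2 <- simulate_traits(tr, mk_params(0.4, 0.2), seed = 9)
  expect_identical(s1$node_states, s2$node_states)

  # per-branch change frequencies match the analytic transition
  # probabilities: aggregate a z-score over many replicate simulations
  tr3 <- rand_tree(60, 4)
  p <- mk_params(0.3 / max(node_ages(tr3)) * 10, 0.2 / max(node_ages(tr3)) * 10)
  po <- ape::reorder.phylo(tr3, "postorder")
  obs <- 0; expn <- 0; varn <- 0
  for (k in 1:30) {
    s <- simulate_traits(tr3, p, seed = 100 + k)
    for (e in seq_len(nrow(po$edge))) {
      a <- s$node_states[po$edge[e, 1]]
      b <- s$node_states[po$edge[e, 2]]
      pr <- transition_matrix(p, po$edge.length[e])[a + 1, 2 - a]
      obs <- obs + (a != b)
      expn <- expn + pr
      varn <- varn + pr * (1 - pr)
    }
  }
  z <- (obs - expn) / sqrt(varn)
  expect_lt(abs(z), 4)
})

test_that("jittered samples stay ultrametric on a fixed topology", {
  tr <- rand_tree(25, 6)
  tr$edge.length <- tr$edge.length * 100 / max(node_ages(tr))
  js <- jitter_tree_sample(tr, 30, sigma = 0.1, seed = 8)
  expect_length(js, 30)
  roots <- vapply(js, function(x) max(node_ages(x)), 0)
  expect_gt(sd(roots), 0)
  for (i in c(1, 15, 30)) {
    expect_true(ape::is.ultrametric(js[[i]], tol = 1e-6))
    expect_true(same_topology(js[[i]], tr))
  }
})

test_that("the fish fixture pins its ground truth", {
  fx <- fish_fixture_cached()
  expect_equal(fx$truth$gain_count, 27)
  expect_equal(unname(fx$truth$mechanism_tally),
               c(8, 17, 2)[match(names(fx$truth$mechanism_tally),
                                 c("intrinsic", "bacterial", "unknown"))])
  expect_equal(sum(fx$truth$mechanism_tally), 27)
  # truth block consistency: recounting the true painting gives the truth
  ev <- count_transitions(fx$tree, fx$truth$node_states)
  expect_equal(sum(ev$direction == "gain"), fx$truth$gain_count)
  expect_equal(sum(ev$direction == "loss"), fx$truth$loss_count)
  expect_setequal(ev$child[ev$direction == "gain"], fx$truth$gain_nodes)
  # shape of the emulated study
  expect_equal(ape::Ntip(fx$tree), 301)
  expect_length(fx$trees, 500)
  expect_gte(max(fx$richness$species), 500)  # richness spans orders of magnitude
  expect_true(all(fx$richness$species >=
                    lengths(strsplit(fx$richness$tips, ";"))))
  # trait table mechanisms agree with the planted labels
  tally <- table(fx$truth$mechanism_of_gain)
  expect_equal(sum(tally), 27)
})

test_that("fixtures survive a disk round trip with truth intact", {
  fx <- fish_fixture_cached()
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  tr <- read_trees(file.path(dir, "tree.nwk"))
  expect_true(same_topology(tr[[1]], fx$tree))
  tt <- read_trait_table(file.path(dir, "traits.tsv"), tree = tr)
  expect_equal(sum(tt$state, na.rm = TRUE),
               sum(fx$traits$state, na.rm = TRUE))
  rt <- read_richness_table(file.path(dir, "richness.tsv"), tree = tr)
  expect_equal(rt$species, fx$richness$species)
  truth <- read_truth(file.path(dir, "truth.txt"))
  expect_equal(truth$gain_count, 27)
  expect_equal(truth$node_states, fx$truth$node_states)
  # re-reading the fixture leaves the truth gain count recomputable
  ev <- count_transitions(tr[[1]], truth$node_states)
  expect_equal(sum(ev$direction == "gain"), truth$gain_count)
  # the NEXUS tree sample round-trips with matching taxa
  ts <- read_trees(file.path(dir, "trees.nex"))
  expect_length(ts, 500)
  expect_setequal(ts[[1]]$tip.label, fx$tree$tip.label)
})
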