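test_that("binarization thresholds conservatively at ties", {
  tr <- rand_tree(4, 8)
  tt <- make_traits(tr, c(0, 1, 1, 0))
  fake <- structure(list(
    asr = list(setNames(c(0.93, 0.5, 0.51), as.character(5:7))),
    trees = tree_sample(tr), n_trees = 1L), class = "mk_mcmc")
  st <- binarize_asr(fake, tt, threshold = 0.5)[[1]]
  expect_identical(st[5:7], c(1L, 0L, 1L))  # tie at 0.5 resolves to absence
  st9 <- binarize_asr(fake, tt, threshold = 0.93)[[1]]
  expect_identical(st9[5:7], c(0L, 0L, 0L))
  expect_error(binarize_asr(fake, tt, threshold = 1), "threshold")
})

test_that("transition counting matches constructed cases", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,(e:2,f:2):1);")
  # all absent: no events
  st0 <- rep(0L, 6 + tr$Nnode)
  expect_equal(nrow(count_transitions(tr, st0)), 0)
  # two separate luminous clades under an absent root: exactly 2 gains
  ntip <- 6
  st <- rep(0L, 6 + tr$Nnode)
  cl1 <- ape::getMRCA(tr, c("a", "b")); cl2 <- ape::getMRCA(tr, c("e", "f"))
  st[c(match(c("a", "b"), tr$tip.label), cl1)] <- 1L
  st[c(match(c("e", "f"), tr$tip.label), cl2)] <- 1L
  ev <- count_transitions(tr, st)
  expect_equal(sum(ev$direction == "gain"), 2)
  expect_equal(sum(ev$direction == "loss"), 0)
  expect_error(count_transitions(tr, rep(NA, 11)), "binary state")
})

test_that("counts equal the flat edge-scan oracle on random paintings", {
  set.seed(31)
  for (i in 1:20) {
    tr <- rand_tree(50, 300 + i)
    st <- rbinom(50 + tr$Nnode, 1, 0.3)
    ev <- count_transitions(tr, st)
    or <- edge_scan_events(tr, st)
    expect_equal(sum(ev$direction == "gain"), unname(or["gains"]))
    expect_equal(sum(ev$direction == "loss"), unname(or["losses"]))
  }
})

test_that("gains minus losses telescope along every root-to-tip path", {
  set.seed(32)
  checked <- 0
  for (i in 1:20) {
    tr <- rand_tree(25, 500 + i)
    for (j in 1:2) {
      st <- rbinom(25 + tr$Nnode, 1, runif(1, 0.2, 0.8))
      ev <- count_transitions(tr, st)
      root <- ape::Ntip(tr) + 1
      for (tip in seq_len(25)) {
        expect_equal(path_net_change(tr, st, tip), st[tip] - st[root])
        checked <- checked + 1
      }
    }
  }
  expect_gte(checked, 1000)
})

test_that("counting is invariant to child order and monotone in added clades", {
  tr <- rand_tree(20, 77)
  st <- rbinom(20 + tr$Nnode, 1, 0.3)
  ev1 <- count_transitions(tr, st)
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  # remap states onto the rotated tree's node numbering via clade identity
  key <- function(tr) c(tr$tip.label,
                        vapply(ape::prop.part(tr), function(i)
                          paste(sort(attr(ape::prop.part(tr), "labels")[i]),
                                collapse = "|"), ""))
  st2 <- st[match(key(tr2), key(tr))]
  ev2 <- count_transitions(tr2, st2)
  expect_equal(table(ev1$direction), table(ev2$direction))

  # painting a fresh all-absent clade (absent parent) adds exactly 1 gain
  desc <- lumfish:::.desc_tips(tr)
  nodes_under <- function(v) which(vapply(seq_along(desc), function(u)
    all(desc[[u]] %in% desc[[v]]), TRUE))
  found <- FALSE
  for (v in (21:(20 + tr$Nnode))[-1]) {
    sub <- nodes_under(v)
    par <- tr$edge[match(v, tr$edge[, 2]), 1]
    if (all(st[sub] == 0) && st[par] == 0) {
      st3 <- st
      st3[sub] <- 1L
      before <- sum(count_transitions(tr, st)$direction == "gain")
      after <- sum(count_transitions(tr, st3)$direction == "gain")
      expect_equal(after, before + 1)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("mechanism classification follows the descendant-tip rule", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:3);")
  tt <- trait_table(data.frame(
    tip = c("a", "b", "c", "d"), state = c(1, 1, 1, 0),
    mechanism = c("bacterial", "bacterial", "intrinsic", NA)))
  m_ab <- ape::getMRCA(tr, c("a", "b"))
  expect_equal(classify_mechanism(tr, m_ab, tt), "bacterial")
  m_abc <- ape::getMRCA(tr, c("a", "c"))
  expect_equal(classify_mechanism(tr, m_abc, tt), "mixed")
  tt2 <- trait_table(data.frame(
    tip = c("a", "b", "c", "d"), state = c(1, 1, 0, 0),
    mechanism = c("unknown", "unknown", NA, NA)))
  expect_equal(classify_mechanism(tr, m_ab, tt2), "unknown")
  # reconstruction noise: gain with no luminous descendants
  expect_warning(out <- classify_mechanism(tr, match("d", tr$tip.label), tt2),
                 "no luminous")
  expect_equal(out, "unknown")
})

test_that("origin summaries aggregate the cross-tree distribution", {
  tr <- rand_tree(6, 12)
  trees <- tree_sample(list(tr, tr))
  ev27 <- data.frame(parent = rep(8L, 27), child = rep(9L, 27),
                     direction = "gain", mechanism = "bacterial")
  ev29 <- data.frame(parent = rep(8L, 29), child = rep(9L, 29),
                     direction = "gain", mechanism = "bacterial")
  s <- summarize_origins(list(ev27, ev29), trees)
  expect_equal(s$gains_min, 27)
  expect_equal(s$gains_median, 28)
  s2 <- summarize_origins(list(ev27, ev27), trees)
  expect_equal(s2$gains_min, s2$gains_mode)
  expect_equal(s2$gains_mode, s2$gains_median)
})

test_that("species totals sum described richness of smallest covering clades", {
  fx <- fish_fixture_cached()
  tr <- fx$tree
  st <- fx$truth$node_states
  ev <- count_transitions(tr, st, traits = fx$traits)
  s <- summarize_origins(list(ev), tree_sample(tr), richness = fx$richness)
  expect_equal(s$gains_mode, fx$truth$gain_count)
  # totals count each covering clade once and match a direct tabulation
  g <- s$events
  by_mech <- vapply(unique(g$mechanism), function(m) {
    cl <- unique(g$clade[g$mechanism == m]); cl <- cl[!is.na(cl)]
    sum(fx$richness$species[match(cl, fx$richness$clade)])
  }, 0)
  expect_equal(s$species_totals[names(by_mech)], by_mech)
  expect_equal(sum(table(g$mechanism)), s$gains_mode)
})

test_that("threshold sweep reports gains per cutoff on a real fit", {
  tr <- rand_tree(30, 44)
  sim <- simulate_traits(tr, mk_params(0.5 / max(node_ages(tr)), 0.01),
                         seed = 3)
  fit <- mk_mcmc(tr, sim$traits, iterations = 4000, burnin = 0.25,
                 thin = 5, seed = 11)
  sw <- origin_sensitivity(fit, sim$traits, thresholds = c(0.5, 0.7, 0.9))
  expect_equal(nrow(sw), 3)
  expect_true(all(sw$gains_mode >= 0))
  # losses are rare in this regime, so stricter cutoffs cannot inflate
  # the modal gain count below the loosest cutoff by much; check the
  # documented direction on the median
  expect_true(sw$gains_median[3] >= sw$gains_median[1] - 1)
})

test_that("stochastic mapping agrees with edge counting when unambiguous", {
  tr <- rand_tree(12, 90)
  tt <- make_traits(tr, c(rep(1, 3), rep(0, 9)))
  p <- mk_params(0.1 / max(node_ages(tr)), 0.001)
  eg <- expected_gains_simmap(tr, tt, p, nsim = 200, seed = 2)
  # the three luminous tips form whatever clusters they form; the
  # expected history count must stay near the marginal-ASR edge count
  asr <- marginal_asr(tr, tt, p)
  st <- c(c(rep(1L, 3), rep(0L, 9)), as.integer(asr > 0.5))
  hard <- sum(count_transitions(tr, st)$direction == "gain")
  expect_lt(abs(as.numeric(eg) - hard), 1)
  expect_length(attr(eg, "gains"), 200)
})
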