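test_that("minimal Newick reads into a validated time tree", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  s <- read_trees(f)
  expect_length(s, 1)
  expect_setequal(s[[1]]$tip.label, c("A", "B", "C"))
  expect_equal(max(ape::node.depth.edgelength(s[[1]])), 2)
})

test_that("ultrametricity is enforced unless disabled", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:1);", f)   # C sits at depth 1, others at 2
  expect_error(read_trees(f), "not ultrametric.*C")
  s <- read_trees(f, ultrametric = FALSE)
  expect_length(s, 1)
})

test_that("defective trees raise parse/validation errors naming the problem", {
  dup <- ape::read.tree(text = "((A:1,A:1):1,C:2);")
  expect_error(validate_time_tree(dup, index = 3), "tree 3.*duplicate.*A")
  nolen <- ape::read.tree(text = "((A,B),C);")
  expect_error(validate_time_tree(nolen), "missing branch lengths")
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("this is not a tree", f)
  expect_error(read_trees(f), "unreadable")
})

test_that("read -> write -> read round-trips trees in both dialects", {
  set.seed(42)
  trees <- tree_sample(lapply(1:5, function(i) ape::rcoal(8)))
  for (fmt in c("newick", "nexus")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_trees(trees, f, format = fmt)
    back <- read_trees(f, format = fmt)
    expect_length(back, 5)
    for (i in 1:5) {
      expect_true(same_topology(trees[[i]], back[[i]]))
      o1 <- sort(ape::branching.times(trees[[i]]))
      o2 <- sort(ape::branching.times(back[[i]]))
      expect_equal(unname(o1), unname(o2), tolerance = 1e-9)
      expect_setequal(back[[i]]$tip.label, trees[[i]]$tip.label)
    }
  }
})

test_that("trait and richness tables are validated on read", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_error(trait_table(data.frame(tip = "A", state = 2)), "0, 1 or NA")
  expect_error(
    trait_table(data.frame(tip = c("A", "B"), state = c(1, 0),
                           mechanism = c(NA, NA))),
    "mechanism")
  expect_error(
    trait_table(data.frame(tip = "A", state = 0, mechanism = "bacterial")),
    "non-luminous")
  expect_error(
    trait_table(data.frame(tip = c("A", "B"), state = c(0, 0)), tree = tr),
    "without a trait row.*C")
  ok <- trait_table(data.frame(tip = c("A", "B", "C"), state = c(1, NA, 0),
                               mechanism = c("intrinsic", NA, NA)),
                    tree = tr)
  expect_s3_class(ok, "trait_table")

  expect_error(richness_table(data.frame(clade = "x", tips = "A",
                                         species = 5)), ">= 2")
  expect_error(richness_table(data.frame(clade = "x", tips = "A;B",
                                         species = 1)), "below")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("clade\ttips\tspecies\tcrown_age_ma\nx\tA;B\t10\tNA", f)
  rt <- read_richness_table(f, tree = tr)
  expect_equal(rt$species, 10)
})

test_that("subsampling is deterministic and index-exact", {
  trees <- tree_sample(lapply(1:50, function(i) rand_tree(6, i)))
  ev <- subsample_trees(trees, 5, mode = "even")
  expect_identical(unclass(ev), unclass(trees)[c(1, 11, 21, 31, 41)])
  expect_identical(unclass(subsample_trees(trees, 50, mode = "even")),
                   unclass(trees))
  r1 <- subsample_trees(trees, 10, mode = "random", seed = 9)
  r2 <- subsample_trees(trees, 10, mode = "random", seed = 9)
  expect_identical(r1, r2)
  expect_error(subsample_trees(trees, 51), "cannot subsample")
})

test_that("the MCC tree maximizes the clade-frequency product", {
  # trivial case: identical trees
  base <- rand_tree(8, 5)
  same <- tree_sample(lapply(1:4, function(i) base))
  m <- mcc_tree(same)
  expect_true(same_topology(m, base))
  expect_equal(sort(unname(ape::branching.times(m))),
               sort(unname(ape::branching.times(base))), tolerance = 1e-12)

  # majority topology wins
  a <- rand_tree(6, 1); b <- rand_tree(6, 2)
  maj <- tree_sample(list(a, b, a))
  expect_true(same_topology(mcc_tree(maj), a))

  # 50-tree sample: selection agrees with an independent clade-frequency
  # tabulation (ape::prop.part) and with phangorn's MCC search
  trees <- tree_sample(lapply(1:50, function(i) rand_tree(10, 100 + i %% 7)))
  m <- mcc_tree(trees)
  sc <- mcc_scores_oracle(trees)
  expect_equal(attr(m, "log_clade_credibility"), max(sc), tolerance = 1e-9)
  ph <- phangorn::maxCladeCred(structure(unclass(trees),
                                         class = "multiPhylo"))
  expect_true(same_topology(m, ph))
})

test_that("MCC clade set is a subset of sampled clades, heights summarized", {
  trees <- jitter_tree_sample(rand_tree(10, 3), 20, sigma = 0.15, seed = 4)
  m <- mcc_tree(trees)
  pp <- ape::prop.part(structure(unclass(trees), class = "multiPhylo"))
  labs <- attr(pp, "labels")
  sampled <- vapply(pp, function(i) paste(sort(labs[i]), collapse = "|"), "")
  pm <- ape::prop.part(m)
  mine <- vapply(pm, function(i)
    paste(sort(attr(pm, "labels")[i]), collapse = "|"), "")
  expect_true(all(mine %in% sampled))
  # topology is shared across the jittered sample, so every node height
  # must equal the cross-sample mean of that clade's height
  ages <- sapply(unclass(trees), function(tr) {
    a <- node_ages(tr)
    a[(ape::Ntip(tr) + 1):length(a)]
  })
  expect_equal(unname(node_ages(m)[(ape::Ntip(m) + 1):(2 * ape::Ntip(m) - 1)]),
               unname(rowMeans(ages)), tolerance = 1e-9)
})
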