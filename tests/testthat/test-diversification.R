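test_that("crown size pmf normalizes and hits the Yule mean", {
  for (par in list(c(0.1, 0, 10), c(0.1, 0.5, 10), c(0.08, 0.9, 50),
                   c(0.4, 0.2, 5))) {
    pmf <- crown_size_pmf(bd_params(par[1], par[2]), par[3])
    expect_lt(abs(sum(pmf$prob) - 1), 1e-9)
    expect_true(all(pmf$n >= 2))
  }
  # pure birth: closed-form mean 2 e^{rt}
  for (rt in list(c(0.1, 7), c(0.25, 12))) {
    pmf <- crown_size_pmf(bd_params(rt[1], 0), rt[2])
    expect_equal(sum(pmf$n * pmf$prob), 2 * exp(rt[1] * rt[2]),
                 tolerance = 1e-6)
    expect_equal(attr(pmf, "mean"), 2 * exp(rt[1] * rt[2]),
                 tolerance = 1e-12)
  }
  expect_error(crown_size_pmf(bd_params(0.1, 0.5), 0), "age")
  expect_error(bd_params(0.1, 1), "extinction")
  expect_error(crown_size_pmf(structure(list(r = -1, eps = 0),
                                        class = "bd_params"), 5), "r must")
})

test_that("the CDF is monotone and the upper bound grows with t and r", {
  bd <- bd_params(0.1, 0.5)
  pmf <- crown_size_pmf(bd, 12)
  expect_true(all(diff(cumsum(pmf$prob)) >= 0))
  ups_t <- vapply(c(5, 10, 20, 40),
                  function(t) richness_interval(bd, t)[["upper"]], 0L)
  expect_true(all(diff(ups_t) >= 0))
  ups_r <- vapply(c(0.05, 0.1, 0.2),
                  function(r) richness_interval(bd_params(r, 0.5),
                                                12)[["upper"]], 0L)
  expect_true(all(diff(ups_r) >= 0))
})

test_that("richness intervals are equal-tail quantiles of the pmf", {
  bd <- bd_params(0.12, 0.3); t <- 15
  pmf <- crown_size_pmf(bd, t)
  cdf <- cumsum(pmf$prob)
  for (cov in c(0.5, 0.9, 0.95)) {
    ci <- richness_interval(bd, t, cov)
    a <- (1 - cov) / 2
    expect_equal(ci[["lower"]], pmf$n[which(cdf >= a)[1]])
    expect_equal(ci[["upper"]], pmf$n[which(cdf >= 1 - a)[1]])
  }
  # degenerate coverage collapses to the distribution's median point
  ci0 <- richness_interval(bd, t, 1e-9)
  expect_equal(ci0[["lower"]], ci0[["upper"]])
  # small rt piles mass at the minimum clade size
  expect_equal(richness_interval(bd_params(0.01, 0), 1)[["lower"]], 2)
  expect_error(richness_interval(bd, t, 1.2), "coverage")
})

test_that("pmf and intervals match a birth-death simulation oracle", {
  set.seed(77)
  bd <- bd_params(0.1, 0.5); t <- 10
  sizes <- sim_crown_sizes(bd$r, bd$eps, t, 20000)
  pmf <- crown_size_pmf(bd, t)
  emp <- as.numeric(table(factor(sizes, levels = pmf$n))) / length(sizes)
  tv <- 0.5 * (sum(abs(emp - pmf$prob)) + mean(sizes > max(pmf$n)))
  expect_lt(tv, 0.03)
  ci <- richness_interval(bd, t, 0.95)
  qs <- quantile(sizes, c(0.025, 0.975), type = 1)
  expect_lte(abs(ci[["lower"]] - qs[[1]]), 1)
  expect_lte(abs(ci[["upper"]] - qs[[2]]), 1)
})

test_that("exceptional flags follow the strict upper-bound rule", {
  ci <- c(lower = 4L, upper = 120L)
  expect_equal(flag_exceptional(120, ci), "within")
  expect_equal(flag_exceptional(121, ci), "exceptional")
  expect_equal(flag_exceptional(3, ci), "depauperate")
  expect_equal(flag_exceptional(4, ci), "within")
})

test_that("envelope reports take crown ages from the tree when absent", {
  tr <- rand_tree(10, 5)
  tr$edge.length <- tr$edge.length * 30 / max(node_ages(tr))
  rt <- richness_table(data.frame(
    clade = c("one", "two"),
    tips = c(paste(tr$tip.label[1:3], collapse = ";"),
             paste(tr$tip.label[6:8], collapse = ";")),
    species = c(5000, 4), crown_age_ma = c(NA, 12)))
  env <- richness_envelope(rt, tree = tr, bd = bd_params(0.08, 0.2))
  expect_equal(env$age[2], 12)
  m <- ape::getMRCA(tr, match(tr$tip.label[1:3], tr$tip.label))
  expect_equal(env$age[1], node_ages(tr)[m])
  expect_true(all(env$lower <= env$upper))
  expect_equal(env$flag[1], "exceptional")   # 5000 species in <= 30 Ma
})

test_that("a planted fast clade is flagged against the background envelope", {
  # clades simulated at 10x the background rate should land above the
  # background 95% envelope nearly always
  set.seed(12)
  bd_bg <- bd_params(0.05, 0)
  hits <- 0; n <- 50
  for (i in 1:n) {
    tr <- simulate_bd_tree(0.5, 0, n_tips = 40, seed = 600 + i)
    age <- max(node_ages(tr))
    ci <- richness_interval(bd_bg, age, 0.95)
    if (flag_exceptional(40, ci) == "exceptional") hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("single-piece likelihood matches ape::birthdeath and Yule forms", {
  tr <- simulate_bd_tree(0.1, 0.03, n_tips = 60, seed = 8)
  fit <- ape::birthdeath(tr)
  eps <- fit$para[["d/b"]]; r <- fit$para[["b-d"]]
  expect_equal(bd_loglik(tr, bd_params(r, eps)) +
                 lfactorial(ape::Ntip(tr) - 1),
               -fit$dev / 2, tolerance = 1e-6)
  # Yule: product of exponential waiting contributions
  ty <- simulate_bd_tree(0.2, 0, n_tips = 25, seed = 21)
  for (r in c(0.1, 0.2, 0.35)) {
    direct <- (ape::Ntip(ty) - 2) * log(r) - r * sum(ty$edge.length)
    expect_equal(bd_loglik(ty, bd_params(r, 0)), direct, tolerance = 1e-10)
  }
})

test_that("the taxonomic richness term is monotone beyond its mode", {
  bd <- bd_params(0.1, 0.4); ts <- 20
  term <- function(m) {
    ed <- data.frame(parent = 2L, child = 1L, start = ts, end = 0,
                     pendant = TRUE, m = m)
    lumfish:::.bd_piece_loglik(bd$r, bd$eps, ed)
  }
  vals <- vapply(1:200, term, 0)
  mode <- which.max(vals)
  expect_true(all(diff(vals[mode:200]) < 0))
  # doubling richness beyond the mode strictly decreases the term
  expect_lt(term(2 * (mode + 10)), term(mode + 10))
})
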