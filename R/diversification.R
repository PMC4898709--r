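## Birth-death expected clade-richness machinery: the Magallon-Sanderson
## crown clade-size distribution conditional on survival of both crown
## lineages, its equal-tail quantile envelope, and the exceptional-richness
## flag (observed described diversity strictly above the upper bound).

#' Birth-death parameters
#'
#' @param r net diversification rate `lambda - mu`, lineages/lineage/Ma.
#' @param eps relative extinction `mu / lambda` in `[0, 1)`.
#' @return a `bd_params` object with derived `lambda = r/(1-eps)` and
#'   `mu = lambda * eps`.
#' @export
bd_params <- function(r, eps = 0) {
  if (!is.finite(r) || !is.finite(eps)) stop("rates must be finite")
  if (eps < 0 || eps >= 1) stop("relative extinction must be in [0, 1)")
  lambda <- r / (1 - eps)
  structure(list(r = r, eps = eps, lambda = lambda, mu = lambda * eps),
            class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf(
    "Birth-death: r = %.5g, eps = %.4g (lambda = %.5g, mu = %.5g) /Ma\n",
    x$r, x$eps, x$lambda, x$mu))
  invisible(x)
}

## beta(t) of the crown-size distribution; expm1 keeps small rt accurate
.bd_beta <- function(r, eps, t) {
  ert1 <- expm1(r * t)            # e^{rt} - 1
  ert1 / (ert1 + 1 - eps)
}

#' Crown clade-size distribution
#'
#' Probability mass function of the number of extant species `n >= 2` in a
#' crown clade of age `t`, conditional on both crown lineages surviving:
#' `P(N = n) = (n - 1) (1 - beta)^2 beta^(n - 2)` with
#' `beta = (e^{rt} - 1) / (e^{rt} - eps)`. The support is truncated
#' adaptively where the CDF exceeds `1 - 1e-9`.
#'
#' @param bd a [bd_params] with positive net diversification.
#' @param t crown age, Ma, `> 0`.
#' @return data.frame with columns `n` and `prob`; attributes `beta` and
#'   `mean` (`2 / (1 - beta)`, which is `2 e^{rt}` for `eps = 0`).
#' @export
crown_size_pmf <- function(bd, t) {
  if (bd$r <= 0) stop("net diversification r must be > 0")
  if (t <= 0) stop("crown age t must be > 0")
  beta <- .bd_beta(bd$r, bd$eps, t)
  ## CDF(n) = 1 - n beta^(n-1) + (n-1) beta^n  => invert for truncation
  nmax <- 2L
  if (beta > 0) {
    nmax <- 2L + qgeom(1 - 1e-10, prob = 1 - beta) * 2L  # generous start
    while (.crown_cdf(nmax, beta) < 1 - 1e-9) nmax <- nmax * 2L
    while (nmax > 2L && .crown_cdf(nmax - 1L, beta) >= 1 - 1e-9)
      nmax <- nmax - 1L
  }
  n <- 2:max(nmax, 2L)
  prob <- (n - 1) * (1 - beta)^2 * beta^(n - 2)
  structure(data.frame(n = n, prob = prob),
            beta = beta, mean = 2 / (1 - beta))
}

.crown_cdf <- function(n, beta) 1 - n * beta^(n - 1) + (n - 1) * beta^n

#' Expected-richness confidence interval
#'
#' Equal-tail interval of [crown_size_pmf()]: the smallest `n` with
#' `CDF >= (1 - coverage)/2` and the smallest `n` with
#' `CDF >= 1 - (1 - coverage)/2` (closed-form CDF, no truncation error).
#'
#' @inheritParams crown_size_pmf
#' @param coverage interval mass in (0, 1), default 0.95.
#' @return integer vector `c(lower, upper)`, both `>= 2`.
#' @export
richness_interval <- function(bd, t, coverage = 0.95) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  beta <- .bd_beta(bd$r, bd$eps, t)
  a <- (1 - coverage) / 2
  c(lower = .crown_quantile(a, beta),
    upper = .crown_quantile(1 - a, beta))
}

## smallest n >= 2 with CDF(n) >= p, by doubling + bisection
.crown_quantile <- function(p, beta) {
  if (beta <= 0 || .crown_cdf(2L, beta) >= p) return(2L)
  hi <- 4L
  while (.crown_cdf(hi, beta) < p) hi <- hi * 2L
  lo <- hi %/% 2L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (.crown_cdf(mid, beta) >= p) hi <- mid else lo <- mid
  }
  hi
}

#' Flag exceptional species richness
#'
#' A clade is exceptionally rich iff its described species count lies
#' strictly above the upper envelope bound (`observed == upper` is not
#' exceptional); counts strictly below the lower bound are flagged
#' depauperate, reported separately, never as exceptional.
#'
#' @param observed described species count, `>= 2`.
#' @param interval `c(lower, upper)` from [richness_interval()].
#' @return `"exceptional"`, `"depauperate"` or `"within"`.
#' @export
flag_exceptional <- function(observed, interval) {
  if (observed > interval[["upper"]]) "exceptional"
  else if (observed < interval[["lower"]]) "depauperate"
  else "within"
}

#' Richness envelope report for a clade table
#'
#' The tabular form of a clade-age vs expected-richness plot: for each
#' clade, the expected size and equal-tail bounds under background
#' birth-death rates at its crown age, and the exceptional/depauperate
#' flag for its described species count. Crown ages come from the tree's
#' node heights (MRCA of the clade's sampled tips) unless the richness
#' table supplies `crown_age_ma`.
#'
#' @param richness a [richness_table].
#' @param tree an ultrametric [ape::phylo] (needed when any `crown_age_ma`
#'   is `NA`).
#' @param bd background [bd_params]; by default take the background piece
#'   of a [medusa_fit()] on the same tree.
#' @param coverage envelope mass, default 0.95.
#' @return a `richness_envelope` data.frame: clade, age, r, eps, expected,
#'   lower, upper, observed, flag.
#' @export
richness_envelope <- function(richness, tree = NULL, bd, coverage = 0.95) {
  ages <- richness$crown_age_ma
  if (anyNA(ages)) {
    if (is.null(tree)) stop("tree needed to derive crown ages")
    age <- node_ages(tree)
    for (i in which(is.na(ages))) {
      tips <- strsplit(richness$tips[i], ";", fixed = TRUE)[[1]]
      m <- ape::getMRCA(tree, match(tips, tree$tip.label))
      ages[i] <- age[m]
    }
  }
  rows <- lapply(seq_len(nrow(richness)), function(i) {
    ci <- richness_interval(bd, ages[i], coverage)
    beta <- .bd_beta(bd$r, bd$eps, ages[i])
    data.frame(clade = richness$clade[i], age = ages[i],
               r = bd$r, eps = bd$eps,
               expected = 2 / (1 - beta),
               lower = ci[["lower"]], upper = ci[["upper"]],
               observed = richness$species[i],
               flag = flag_exceptional(richness$species[i], ci),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("richness_envelope", "data.frame"),
            coverage = coverage)
}

#' @export
print.richness_envelope <- function(x, ...) {
  cat(sprintf("Expected-richness envelope (coverage %.0f%%):\n",
              100 * attr(x, "coverage")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  nexc <- sum(x$flag == "exceptional")
  cat(sprintf("%d of %d clades exceptionally species-rich\n",
              nexc, nrow(x)))
  invisible(x)
}
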