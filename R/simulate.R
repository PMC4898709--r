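## Synthetic data with known ground truth: forward birth-death tree
## simulation, exact Mk trait simulation, branch-length jitter emulating
## posterior height uncertainty, and the fish-like end-to-end fixture
## (301 tips, 27 clustered gains split 8 intrinsic / 17 bacterial /
## 2 unknown, clade richness spanning orders of magnitude).

#' Simulate a reconstructed birth-death time tree
#'
#' Gillespie forward simulation from the two crown lineages; extinct
#' lineages are pruned so the returned tree is the reconstructed
#' (ultrametric) tree. Stop either at a fixed number of surviving tips or
#' at a fixed crown age.
#'
#' @param lambda speciation rate, /Ma, `> 0`.
#' @param mu extinction rate, /Ma, `>= 0`.
#' @param n_tips stop when this many lineages survive (mutually exclusive
#'   with `age`).
#' @param age stop at this crown age (Ma).
#' @param condition_on_survival for `age` stops: require both crown
#'   lineages to leave survivors, resampling up to `max_retries` times.
#' @param seed RNG seed (identical seeds give identical Newick strings).
#' @param max_retries retry cap before giving up.
#' @return an ultrametric [ape::phylo] with tips `t1, t2, ...`.
#' @export
simulate_bd_tree <- function(lambda, mu = 0, n_tips = NULL, age = NULL,
                             condition_on_survival = TRUE, seed = NULL,
                             max_retries = 1000) {
  if (lambda <= 0 || mu < 0) stop("need lambda > 0 and mu >= 0")
  if (is.null(n_tips) == is.null(age))
    stop("give exactly one of n_tips or age")
  if (!is.null(n_tips) && n_tips < 2) stop("n_tips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_retries)) {
    sim <- .bd_forward(lambda, mu, n_tips, age)
    if (!is.null(sim)) {
      if (!is.null(age) && condition_on_survival) {
        ## both crown lineages must have extant descendants
        surv <- .extant_desc(sim)
        if (!(surv[1] && surv[2])) next
      }
      tree <- .bd_to_phylo(sim)
      if (!is.null(tree)) return(tree)
    }
    if (!is.null(age) && !condition_on_survival)
      stop("whole clade went extinct before the stopping age")
  }
  stop("retry cap reached without a surviving clade")
}

## one forward pass; returns lineage table or NULL on total extinction
## (n-stop) / clade death before age (age-stop handled by caller)
.bd_forward <- function(lambda, mu, n_tips, age) {
  cap <- 16L
  parent <- integer(cap); birth <- numeric(cap); death <- numeric(cap)
  parent[1:2] <- 0L; birth[1:2] <- 0
  death[1:2] <- NA_real_
  nlin <- 2L
  alive <- c(1L, 2L)
  t <- 0
  repeat {
    na <- length(alive)
    if (na == 0L) return(NULL)
    if (!is.null(n_tips) && na == n_tips) {
      stop_age <- t
      break
    }
    dt <- rexp(1, na * (lambda + mu))
    if (!is.null(age) && t + dt > age) {
      stop_age <- age
      break
    }
    t <- t + dt
    who <- alive[sample.int(na, 1)]
    if (runif(1) < lambda / (lambda + mu)) {
      nlin <- nlin + 1L
      if (nlin > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(birth) <- cap; length(death) <- cap
      }
      parent[nlin] <- who; birth[nlin] <- t; death[nlin] <- NA_real_
      alive <- c(alive, nlin)
    } else {
      death[who] <- t
      alive <- alive[alive != who]
    }
  }
  list(parent = parent[seq_len(nlin)], birth = birth[seq_len(nlin)],
       death = death[seq_len(nlin)], stop_age = stop_age)
}

## does each lineage have >= 1 extant descendant (incl. itself)?
.extant_desc <- function(sim) {
  n <- length(sim$parent)
  ok <- is.na(sim$death)
  for (i in rev(seq_len(n))) {   # children have larger ids than parents
    if (ok[i] && sim$parent[i] > 0) ok[sim$parent[i]] <- TRUE
  }
  ok
}

## lineage table -> reconstructed ultrametric phylo via Newick assembly
.bd_to_phylo <- function(sim) {
  ok <- .extant_desc(sim)
  if (!(ok[1] && ok[2])) return(NULL)
  present <- sim$stop_age
  kids <- split(seq_along(sim$parent), sim$parent)
  tipn <- 0L
  render <- function(lin, t0) {
    ch <- kids[[as.character(lin)]]
    if (is.null(ch)) ch <- integer(0)
    ch <- ch[sim$birth[ch] > t0 & ok[ch]]
    alive <- is.na(sim$death[lin])
    if (!length(ch)) {
      ## caller guarantees ok[lin], so a childless lineage here is extant
      tipn <<- tipn + 1L
      return(sprintf("t%d:%.10f", tipn, present - t0))
    }
    ## a dead lineage with a single surviving child is a pass-through in
    ## the reconstructed tree, not a bifurcation
    if (!alive && length(ch) == 1L) return(render(ch[1], t0))
    tb <- sim$birth[ch[1]]     # earliest surviving split after t0
    sprintf("(%s,%s):%.10f", render(lin, tb), render(ch[1], tb), tb - t0)
  }
  ## assemble from the two crown lineages at age 0
  nwk <- sprintf("(%s,%s);", render(1L, 0), render(2L, 0))
  ape::read.tree(text = nwk)
}

#' Simulate a binary trait down a tree
#'
#' Exact endpoint sampling: the state at each child node is drawn from the
#' closed-form transition probabilities over its branch, so no event-time
#' discretisation is involved. True states at every node are returned.
#'
#' @param tree an [ape::phylo].
#' @param params [mk_params].
#' @param root_state state at the root (0 or 1).
#' @param seed RNG seed.
#' @return list with `node_states` (0/1 vector over all nodes, ape
#'   numbering), `tip_states` (named), and `traits` (a [trait_table] with
#'   mechanism `"unknown"` for luminous tips; relabel as needed).
#' @export
simulate_traits <- function(tree, params, root_state = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  nall <- ntip + tree$Nnode
  root <- ntip + 1L
  ## edges grouped by child depth so each level samples as one vector
  depth <- integer(nall)
  po <- ape::reorder.phylo(tree, "postorder")
  pre_edges <- rev(seq_len(nrow(po$edge)))
  for (e in pre_edges)
    depth[po$edge[e, 2]] <- depth[po$edge[e, 1]] + 1L
  st <- integer(nall)
  st[root] <- as.integer(root_state)
  s <- params$q01 + params$q10
  decay <- if (s > 0) exp(-s * po$edge.length) else rep(1, nrow(po$edge))
  p01 <- if (s > 0) params$q01 * (1 - decay) / s else numeric(nrow(po$edge))
  p11 <- if (s > 0) (params$q01 + params$q10 * decay) / s else
    rep(1, nrow(po$edge))
  lev <- split(seq_len(nrow(po$edge)), depth[po$edge[, 2]])
  for (d in sort(as.integer(names(lev)))) {
    es <- lev[[as.character(d)]]
    par_st <- st[po$edge[es, 1]]
    pr <- ifelse(par_st == 1L, p11[es], p01[es])
    st[po$edge[es, 2]] <- as.integer(runif(length(es)) < pr)
  }
  tips <- setNames(st[seq_len(ntip)], tree$tip.label)
  traits <- trait_table(data.frame(
    tip = tree$tip.label, state = unname(tips),
    mechanism = ifelse(tips == 1, "unknown", NA_character_),
    stringsAsFactors = FALSE))
  list(node_states = st, tip_states = tips, traits = traits)
}

#' Jittered tree sample
#'
#' Emulates posterior divergence-time uncertainty on a fixed topology:
#' node ages are perturbed by multiplicative lognormal noise applied to
#' each node's relative placement along its parent path (so trees remain
#' ultrametric with positive branch lengths), the root age itself
#' included.
#'
#' @param tree an ultrametric [ape::phylo].
#' @param n number of jittered trees.
#' @param sigma lognormal sigma on the log scale (default 0.1).
#' @param seed RNG seed.
#' @return a [tree_sample] of `n` trees over the same taxa.
#' @export
jitter_tree_sample <- function(tree, n, sigma = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  age <- node_ages(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge)))
  root <- po$edge[nrow(po$edge), 1]
  out <- vector("list", n)
  for (k in seq_len(n)) {
    newage <- numeric(ntip + tree$Nnode)
    newage[root] <- age[root] * rlnorm(1, 0, sigma)
    for (e in pre) {
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      if (ch <= ntip) next
      ratio <- age[ch] / age[p]
      newage[ch] <- newage[p] * min(ratio * rlnorm(1, 0, sigma), 0.999)
    }
    tr <- tree
    tr$edge.length <- newage[tr$edge[, 1]] - newage[tr$edge[, 2]]
    out[[k]] <- tr
  }
  tree_sample(out)
}

## Are planted gains mutually separated? For every pair of gain nodes the
## absent tips under their MRCA must outnumber present tips by `factor`.
.gains_separated <- function(tree, gains, tip_states, desc, factor) {
  par <- match(seq_len(ape::Ntip(tree) + tree$Nnode), tree$edge[, 2])
  anc_path <- function(v) {
    path <- v
    while (!is.na(par[v])) { v <- tree$edge[par[v], 1]; path <- c(path, v) }
    path
  }
  paths <- lapply(gains, anc_path)
  st <- tip_states[tree$tip.label]
  for (i in seq_along(gains)) for (j in seq_len(i - 1)) {
    m <- paths[[i]][match(TRUE, paths[[i]] %in% paths[[j]])]
    ts <- st[desc[[m]]]
    if (sum(ts == 0) < factor * sum(ts == 1)) return(FALSE)
  }
  TRUE
}

#' Fish-like synthetic dataset with known truth
#'
#' Builds the full study-shaped fixture: a birth-death time tree rescaled
#' to the target crown depth, a clustered binary trait whose true gain
#' count is pinned by rejection sampling over trait seeds, mechanism
#' labels painted on the (disjoint) gain clades, a jittered tree sample
#' emulating the posterior, and a clade richness table drawn from planted
#' per-clade diversification rates (a subset of clades planted at an
#' elevated rate so that exceptional richness exists by construction).
#'
#' @param seed master RNG seed; all stages derive from it.
#' @param n_tips number of terminals (default 301).
#' @param target_gains exact number of true gains (default 27;
#'   must be `< n_tips / 4`).
#' @param tree_sample_size jittered posterior sample size (default 500).
#' @param depth crown age of the tree, Ma (default 150, so origins span
#'   an Early Cretaceous-to-Cenozoic window).
#' @param mechanisms named integer vector splitting the gains among
#'   mechanism labels; must sum to `target_gains`.
#' @param lambda,mu birth-death rates of the containing tree before depth
#'   rescaling.
#' @param jitter_sigma lognormal sigma of the tree-sample jitter.
#' @param n_exceptional number of gain clades planted at an elevated
#'   diversification rate.
#' @param separation minimum ratio of absent to present tips under the
#'   most recent common ancestor of every pair of gains. Keeps planted
#'   origins individually identifiable: absence stays the majority signal
#'   at any node where a reconstruction could otherwise merge two
#'   neighbouring origins into one.
#' @param max_retries cap on trait-seed rejection sampling.
#' @return a `fish_fixture`: `tree`, `trees` ([tree_sample]), `traits`,
#'   `richness`, and `truth` (true rates, node states, gain/loss counts,
#'   gain edges with mechanisms, per-clade planted rates).
#' @export
make_fish_fixture <- function(seed = 1, n_tips = 301, target_gains = 27,
                              tree_sample_size = 500, depth = 150,
                              mechanisms = c(intrinsic = 8, bacterial = 17,
                                             unknown = 2),
                              lambda = 0.04, mu = 0.012,
                              jitter_sigma = 0.1, n_exceptional = 3,
                              separation = 1, max_retries = 20000) {
  if (target_gains >= n_tips / 4)
    stop("target_gains must be < n_tips / 4")
  if (sum(mechanisms) != target_gains)
    stop("mechanism counts must sum to target_gains")
  sim <- NULL
  tries_per_tree <- max(1000L, max_retries %/% 4L)
  for (tree_try in 0:7) {
    ## some tree shapes cannot host the requested number of separated
    ## gains; redraw the containing tree when trait rejection exhausts
    tree <- simulate_bd_tree(lambda, mu, n_tips = n_tips,
                             seed = seed + 7000L * tree_try)
    tree$edge.length <- tree$edge.length * depth /
      max(ape::node.depth.edgelength(tree))
    TL <- sum(tree$edge.length)
    q01 <- target_gains / TL
    q10 <- q01 / 10
    params <- mk_params(q01, q10)
    ntip <- ape::Ntip(tree)
    desc <- .desc_tips(tree)
    ## precomputed level-wise simulation state, reused across trials
    po <- ape::reorder.phylo(tree, "postorder")
    lvl <- integer(ntip + tree$Nnode)
    for (e in rev(seq_len(nrow(po$edge))))
      lvl[po$edge[e, 2]] <- lvl[po$edge[e, 1]] + 1L
    s2 <- q01 + q10
    decay <- exp(-s2 * po$edge.length)
    p01 <- q01 * (1 - decay) / s2
    p11 <- (q01 + q10 * decay) / s2
    lev <- split(seq_len(nrow(po$edge)), lvl[po$edge[, 2]])
    lev <- lev[order(as.integer(names(lev)))]
    sim_once <- function() {
      st <- integer(ntip + tree$Nnode)
      for (es in lev) {
        par_st <- st[po$edge[es, 1]]
        pr <- ifelse(par_st == 1L, p11[es], p01[es])
        st[po$edge[es, 2]] <- as.integer(runif(length(es)) < pr)
      }
      st
    }
    for (try in seq_len(tries_per_tree)) {
    set.seed((seed * 1000L + tree_try * 555L + try) %%
               .Machine$integer.max)
    st_try <- sim_once()
    cand <- list(node_states = st_try,
                 tip_states = setNames(st_try[seq_len(ntip)],
                                       tree$tip.label))
    gain_edge <- cand$node_states[tree$edge[, 1]] == 0L &
      cand$node_states[tree$edge[, 2]] == 1L
    if (sum(gain_edge) != target_gains) next
    g <- tree$edge[gain_edge, 2]
    ## gains must be unambiguous: no gain edge nested in another, no two
    ## gains on sibling edges (a shared parent makes one-gain-plus-
    ## persistence the better reconstruction), every tip below a gain
    ## still luminous (a loss inside a gain clade makes two-smaller-gains
    ## the better reconstruction), and gain pairs mutually separated
    nested <- FALSE
    for (a in g) for (b in g) if (a != b &&
        all(desc[[a]] %in% desc[[b]])) nested <- TRUE
    if (nested) next
    if (anyDuplicated(tree$edge[match(g, tree$edge[, 2]), 1])) next
    clean <- vapply(g, function(v)
      all(cand$tip_states[tree$tip.label[desc[[v]]]] == 1), TRUE)
    if (!all(clean)) next
    if (separation > 0 && !.gains_separated(tree, g, cand$tip_states,
                                            desc, separation)) next
    sim <- cand
    gains <- g
    losses <- tree$edge[cand$node_states[tree$edge[, 1]] == 1L &
                          cand$node_states[tree$edge[, 2]] == 0L, 2]
    break
    }
    if (!is.null(sim)) break
  }
  if (is.null(sim))
    stop("retry cap exhausted before hitting the target gain count; ",
         "adjust rates or raise max_retries")
  ## paint mechanisms on the gain clades (larger clades first, labels
  ## shuffled deterministically)
  sz <- vapply(gains, function(v) length(desc[[v]]), 0L)
  ord <- order(-sz, gains)
  labels <- sample(rep(names(mechanisms), mechanisms))
  mech_of_gain <- setNames(labels, gains[ord])
  traits <- data.frame(
    tip = tree$tip.label, state = unname(sim$tip_states),
    mechanism = ifelse(sim$tip_states == 1, "unknown", NA_character_),
    stringsAsFactors = FALSE)
  for (i in seq_along(gains)) {
    v <- gains[ord[i]]
    tips <- tree$tip.label[desc[[v]]]
    lum <- tips[sim$tip_states[tips] == 1]
    traits$mechanism[match(lum, traits$tip)] <- labels[i]
  }
  traits <- trait_table(traits, tree = tree)
  trees <- jitter_tree_sample(tree, tree_sample_size, sigma = jitter_sigma,
                              seed = seed + 1L)
  ## richness: one clade per multi-tip gain, species drawn from planted
  ## birth-death rates at the clade's crown age
  r_bg <- lambda - mu
  age <- node_ages(tree)
  multi <- gains[vapply(gains, function(v) length(desc[[v]]) >= 2, TRUE)]
  exc <- if (length(multi))
    multi[order(-age[multi])][seq_len(min(n_exceptional, length(multi)))]
  else integer(0)
  rows <- list(); planted <- list()
  for (i in seq_along(multi)) {
    v <- multi[i]
    tips <- tree$tip.label[desc[[v]]]
    tcrown <- age[v]
    r_i <- if (v %in% exc) max(log(1500) / tcrown, 2 * r_bg) else r_bg
    beta <- .bd_beta(r_i, 0, tcrown)
    S <- 2 + rnbinom(1, size = 2, prob = 1 - beta)
    S <- max(S, length(tips))
    rows[[i]] <- data.frame(
      clade = sprintf("biolum_%02d", i), tips = paste(tips, collapse = ";"),
      species = S, crown_age_ma = NA_real_, stringsAsFactors = FALSE)
    planted[[i]] <- data.frame(clade = sprintf("biolum_%02d", i),
                               node = v, r = r_i, eps = 0,
                               exceptional = v %in% exc,
                               crown_age = tcrown)
  }
  richness <- richness_table(do.call(rbind, rows), tree = tree)
  truth <- list(
    params = params, bd = bd_params(r_bg, mu / lambda),
    node_states = sim$node_states,
    gain_count = length(gains), loss_count = length(losses),
    gain_nodes = gains, loss_nodes = losses,
    mechanism_of_gain = mech_of_gain,
    mechanism_tally = mechanisms,
    planted_clades = do.call(rbind, planted),
    seed = seed)
  structure(list(tree = tree, trees = trees, traits = traits,
                 richness = richness, truth = truth),
            class = "fish_fixture")
}

#' @export
print.fish_fixture <- function(x, ...) {
  cat(sprintf(
    "Synthetic fish-like dataset: %d tips, %d trees, %d true gains (%s), %d loss(es)\n",
    ape::Ntip(x$tree), length(x$trees), x$truth$gain_count,
    paste(sprintf("%s %d", names(x$truth$mechanism_tally),
                  x$truth$mechanism_tally), collapse = ", "),
    x$truth$loss_count))
  cat(sprintf("  true rates: q01 = %.5g, q10 = %.5g; richness table: %d clades\n",
              x$truth$params$q01, x$truth$params$q10, nrow(x$richness)))
  invisible(x)
}

#' Write a fixture to disk
#'
#' Writes the formats the readers consume -- Newick base tree, NEXUS tree
#' sample, tab-separated trait and richness tables -- plus the truth block
#' as a key-value sidecar.
#'
#' @param fixture a `fish_fixture`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trees(fixture$tree, file.path(dir, "tree.nwk"))
  write_trees(fixture$trees, file.path(dir, "trees.nex"), format = "nexus")
  write.table(fixture$traits, file.path(dir, "traits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fixture$richness, file.path(dir, "richness.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- fixture$truth
  lines <- c(
    sprintf("q01=%.12g", tr$params$q01),
    sprintf("q10=%.12g", tr$params$q10),
    sprintf("gain_count=%d", tr$gain_count),
    sprintf("loss_count=%d", tr$loss_count),
    sprintf("gain_nodes=%s", paste(tr$gain_nodes, collapse = ",")),
    sprintf("mechanism_tally=%s",
            paste(sprintf("%s:%d", names(tr$mechanism_tally),
                          tr$mechanism_tally), collapse = ",")),
    sprintf("node_states=%s", paste(tr$node_states, collapse = "")),
    sprintf("seed=%d", tr$seed))
  writeLines(lines, file.path(dir, "truth.txt"))
  invisible(dir)
}

#' @rdname write_fixture
#' @param path path to a `truth.txt` sidecar.
#' @return `read_truth()`: named list of truth values.
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- setNames(lapply(kv, function(x)
    paste(x[-1], collapse = "=")), vapply(kv, `[[`, "", 1))
  out$q01 <- as.numeric(out$q01); out$q10 <- as.numeric(out$q10)
  out$gain_count <- as.integer(out$gain_count)
  out$loss_count <- as.integer(out$loss_count)
  out$gain_nodes <- as.integer(strsplit(out$gain_nodes, ",")[[1]])
  out$node_states <- as.integer(strsplit(out$node_states, "")[[1]])
  out$seed <- as.integer(out$seed)
  out
}
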