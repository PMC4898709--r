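## Reading, validation and summarising of time-calibrated trees and their
## companion trait / clade-richness tables.  Parsing itself is delegated to
## ape; the validation layer (uniqueness, branch lengths, ultrametricity)
## is enforced here so every downstream stage can assume a clean TimeTree.

#' Validate a time-calibrated tree
#'
#' Checks the invariants every downstream computation relies on: unique tip
#' labels, finite non-negative branch lengths, and (optionally) ultrametricity
#' within a relative tolerance. Branch lengths are in millions of years (Ma).
#'
#' @param tree an [ape::phylo] object (rooted; polytomies allowed).
#' @param ultrametric logical; reject non-ultrametric trees. Posterior samples
#'   from clock dating are ultrametric by construction, so this defaults to
#'   `TRUE`; set `FALSE` to accept e.g. trees with sampled ancestors removed.
#' @param tol relative tolerance on root-to-tip depth spread,
#'   `max |depth - mean| / mean`.
#' @param index tree index used in error messages when validating a sample.
#' @return the tree, invisibly, with a `"root_age"` attribute.
#' @export
validate_time_tree <- function(tree, ultrametric = TRUE, tol = 1e-6,
                               index = NA_integer_) {
  where <- if (is.na(index)) "tree" else sprintf("tree %d", index)
  if (!inherits(tree, "phylo")) stop(where, ": not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop(where, ": duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop(where, ": missing branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop(where, ": branch lengths must be finite and >= 0 (offending edge ",
         which(!is.finite(tree$edge.length) | tree$edge.length < 0)[1], ")")
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  mu <- mean(depths)
  if (ultrametric && mu > 0) {
    rel <- max(abs(depths - mu)) / mu
    if (rel > tol)
      stop(where, sprintf(
        ": not ultrametric (relative depth spread %.3g > %.3g); tip '%s'",
        rel, tol, tree$tip.label[which.max(abs(depths - mu))]))
  }
  attr(tree, "root_age") <- mu
  invisible(tree)
}

#' Node ages of an ultrametric tree
#'
#' Age (time before present, Ma) of every node, tips first then internal
#' nodes, in ape node numbering. Tips of an ultrametric tree get age 0.
#'
#' @param tree an ultrametric [ape::phylo].
#' @return numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  age <- max(d[seq_len(ape::Ntip(tree))]) - d
  age[seq_len(ape::Ntip(tree))] <- pmax(age[seq_len(ape::Ntip(tree))], 0)
  age
}

#' Construct a tree sample
#'
#' Bundles one or more time trees over an identical taxon set into a
#' `tree_sample` (a `multiPhylo` subclass), validating each member.
#'
#' @param trees a phylo, multiPhylo, or list of phylo objects.
#' @inheritParams validate_time_tree
#' @return an object of class `c("tree_sample", "multiPhylo")`.
#' @export
tree_sample <- function(trees, ultrametric = TRUE, tol = 1e-6) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ## materialize through `[[` so multiPhylo objects with compressed tip
  ## labels (ape's TipLabel attribute, e.g. from read.nexus) expand
  trees <- lapply(seq_along(trees), function(i) trees[[i]])
  if (length(trees) == 0L) stop("empty tree sample")
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    validate_time_tree(trees[[i]], ultrametric = ultrametric, tol = tol,
                       index = i)
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop(sprintf("tree %d: taxon set differs from tree 1", i))
  }
  structure(trees, class = c("tree_sample", "multiPhylo"))
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("Tree sample: %d tree(s), %d tips, root age %.4g Ma\n",
              length(x), ape::Ntip(x[[1]]),
              mean(vapply(x, function(t)
                max(ape::node.depth.edgelength(t)), 0))))
  invisible(x)
}

#' Read time trees from Newick or NEXUS
#'
#' @param path file path.
#' @param format `"newick"` or `"nexus"` (TREES + TRANSLATE blocks supported
#'   via ape). Defaults to guessing from the file extension.
#' @inheritParams validate_time_tree
#' @return a [tree_sample].
#' @export
read_trees <- function(path, format = c("guess", "newick", "nexus"),
                       ultrametric = TRUE, tol = 1e-6) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.(nex|nexus|trees)$", path, ignore.case = TRUE))
      "nexus" else "newick"
  }
  trees <- tryCatch(
    suppressWarnings(switch(format,
                            newick = ape::read.tree(path),
                            nexus  = ape::read.nexus(path))),
    error = function(e) stop("unreadable ", format, " file '", path, "': ",
                             conditionMessage(e)))
  if (is.null(trees)) stop("unreadable ", format, " file '", path, "'")
  tree_sample(trees, ultrametric = ultrametric, tol = tol)
}

#' Write a tree sample
#'
#' @param sample a [tree_sample] or phylo.
#' @param path output path.
#' @param format `"newick"` or `"nexus"`.
#' @export
write_trees <- function(sample, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  obj <- if (inherits(sample, "phylo")) sample else
    structure(unclass(sample), class = "multiPhylo")
  if (format == "newick") ape::write.tree(obj, file = path)
  else ape::write.nexus(obj, file = path)
  invisible(path)
}

#' Read a tip trait table
#'
#' Tab-separated with columns `tip`, `state` (0 absent, 1 present, NA
#' missing) and `mechanism` (`intrinsic`, `bacterial` or `unknown`;
#' required exactly for state-1 tips).
#'
#' @param path file path.
#' @param tree optional tree or [tree_sample]; when given, every tip must
#'   have a row (missing states are allowed, absent rows are not).
#' @return a `trait_table` data.frame.
#' @export
read_trait_table <- function(path, tree = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  trait_table(df, tree = tree)
}

#' @rdname read_trait_table
#' @param df data.frame with columns `tip`, `state`, `mechanism`.
#' @export
trait_table <- function(df, tree = NULL) {
  need <- c("tip", "state")
  if (!all(need %in% names(df)))
    stop("trait table needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$mechanism)) df$mechanism <- NA_character_
  df$mechanism[!is.na(df$mechanism) & df$mechanism == ""] <- NA_character_
  if (anyDuplicated(df$tip))
    stop("duplicate tips in trait table: ",
         paste(unique(df$tip[duplicated(df$tip)]), collapse = ", "))
  ok <- is.na(df$state) | df$state %in% c(0L, 1L)
  if (!all(ok)) stop("states must be 0, 1 or NA (tip ", df$tip[!ok][1], ")")
  bad <- !is.na(df$state) & df$state == 1 &
    (is.na(df$mechanism) |
       !df$mechanism %in% c("intrinsic", "bacterial", "unknown"))
  if (any(bad))
    stop("state-1 tips need mechanism in {intrinsic, bacterial, unknown}: ",
         paste(df$tip[bad], collapse = ", "))
  bad2 <- (is.na(df$state) | df$state == 0) & !is.na(df$mechanism)
  if (any(bad2))
    stop("mechanism given for non-luminous tip: ",
         paste(df$tip[bad2], collapse = ", "))
  if (!is.null(tree)) {
    tips <- if (inherits(tree, "phylo")) tree$tip.label else
      tree[[1]]$tip.label
    miss <- setdiff(tips, df$tip)
    if (length(miss))
      stop("tree tips without a trait row: ",
           paste(head(miss, 5), collapse = ", "),
           if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5))
  }
  structure(df[c("tip", "state", "mechanism")],
            class = c("trait_table", "data.frame"))
}

#' Read a clade richness table
#'
#' Tab-separated with columns `clade`, `tips` (semicolon-joined sampled tip
#' labels, at least 2), `species` (described species count) and
#' `crown_age_ma` (NA = take the crown age from the tree).
#'
#' @param path file path.
#' @param tree optional tree used to check that listed tips exist and that
#'   `species >=` number of sampled tips.
#' @return a `richness_table` data.frame.
#' @export
read_richness_table <- function(path, tree = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  richness_table(df, tree = tree)
}

#' @rdname read_richness_table
#' @param df data.frame with the columns above.
#' @export
richness_table <- function(df, tree = NULL) {
  need <- c("clade", "tips", "species")
  if (!all(need %in% names(df)))
    stop("richness table needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$crown_age_ma)) df$crown_age_ma <- NA_real_
  if (anyDuplicated(df$clade))
    stop("duplicate clade names in richness table")
  tiplists <- strsplit(df$tips, ";", fixed = TRUE)
  n <- lengths(tiplists)
  if (any(n < 2))
    stop("clades need >= 2 defining tips: ",
         paste(df$clade[n < 2], collapse = ", "))
  if (any(!is.finite(df$species) | df$species < 1 |
            df$species != round(df$species)))
    stop("species counts must be positive integers")
  if (any(df$species < n))
    stop("species count below number of sampled tips for clade ",
         df$clade[df$species < n][1])
  if (!is.null(tree)) {
    tips <- if (inherits(tree, "phylo")) tree$tip.label else
      tree[[1]]$tip.label
    miss <- setdiff(unlist(tiplists), tips)
    if (length(miss))
      stop("richness table lists tips absent from the tree: ",
           paste(head(miss, 5), collapse = ", "))
  }
  structure(df[c("clade", "tips", "species", "crown_age_ma")],
            class = c("richness_table", "data.frame"))
}

#' Subsample a tree sample
#'
#' @param sample a [tree_sample].
#' @param n number of trees to keep (`n <= length(sample)`).
#' @param mode `"even"` takes every `floor(length/n)`-th tree starting at the
#'   first (deterministic); `"random"` samples without replacement.
#' @param seed RNG seed for `mode = "random"`.
#' @return a [tree_sample] of `n` trees.
#' @export
subsample_trees <- function(sample, n, mode = c("even", "random"),
                            seed = NULL) {
  mode <- match.arg(mode)
  len <- length(sample)
  if (n > len) stop("cannot subsample ", n, " from ", len, " trees")
  if (n < 1) stop("n must be >= 1")
  idx <- if (mode == "even") {
    step <- len %/% n
    seq(1L, by = step, length.out = n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    sort(sample.int(len, n))
  }
  structure(unclass(sample)[idx], class = class(sample))
}

## clade key: sorted tip indices (vs a reference taxon order), as a string
.clade_keys <- function(tree, taxa) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  idx <- match(tree$tip.label, taxa)
  desc <- vector("list", ntip + nn)
  for (i in seq_len(ntip)) desc[[i]] <- idx[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  vapply(seq_len(nn), function(j)
    paste(sort(desc[[ntip + j]]), collapse = ","), "")
}

#' Maximum clade credibility tree
#'
#' Selects the sampled tree maximising the product of its clades' posterior
#' frequencies across the sample (ties broken by lowest tree index) and
#' replaces its node heights by the mean (or median) height of the matching
#' clade across the trees that contain it.
#'
#' @param sample a [tree_sample].
#' @param height_summary `"mean"` or `"median"` clade heights.
#' @return a phylo with attribute `"log_clade_credibility"`.
#' @export
mcc_tree <- function(sample, height_summary = c("mean", "median")) {
  height_summary <- match.arg(height_summary)
  if (length(sample) == 0L) stop("empty tree sample")
  taxa <- sort(sample[[1]]$tip.label)
  keys <- lapply(sample, .clade_keys, taxa = taxa)
  freq <- table(unlist(keys))
  ntree <- length(sample)
  score <- vapply(keys, function(k) sum(log(as.numeric(freq[k]) / ntree)), 0)
  best <- which.max(score)  # which.max returns first (lowest index) on ties
  tree <- sample[[best]]
  ## clade -> heights across trees
  hts <- new.env(parent = emptyenv())
  for (i in seq_along(sample)) {
    age <- node_ages(sample[[i]])
    k <- keys[[i]]
    ntip <- ape::Ntip(sample[[i]])
    for (j in seq_along(k)) {
      hts[[k[j]]] <- c(hts[[k[j]]], age[ntip + j])
    }
  }
  ntip <- ape::Ntip(tree)
  newage <- node_ages(tree)
  fun <- if (height_summary == "mean") mean else median
  for (j in seq_len(tree$Nnode))
    newage[ntip + j] <- fun(hts[[keys[[best]][j]]])
  ## rebuild branch lengths from summarized ages; clamp tiny negatives that
  ## can arise when summarized parent/child heights cross
  el <- newage[tree$edge[, 1]] - newage[tree$edge[, 2]]
  if (any(el < 0)) {
    if (any(el < -1e-8 * max(newage)))
      warning("summarized clade heights non-monotone; clamping ",
              sum(el < 0), " branch(es) to 0")
    el[el < 0] <- 0
  }
  tree$edge.length <- el
  attr(tree, "log_clade_credibility") <- score[best]
  tree
}
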