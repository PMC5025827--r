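# Heuristic maximum-parsimony tree inference, consensus, bootstrap and
# Robinson-Foulds distance.
#
# Tree length (sum of per-character minimum changes) is this package's
# own dynamic programme; the heuristic search scores candidate trees
# through phangorn's C-level Fitch engine (random stepwise addition +
# SPR hill climbing), which the test suite validates against exhaustive
# enumeration scored by the package DP at small taxon numbers.

#' Convert a character matrix to a phangorn phyDat object
#'
#' Column alphabets are merged into one global level set; missing
#' entries become `"?"` (all states) and polymorphic entries get ad-hoc
#' ambiguity tokens via a contrast matrix. Minimum change counts are
#' unaffected by the merge because unobserved states never reduce
#' unordered parsimony cost.
#'
#' @param m a `char_matrix`.
#' @return a `phyDat` object of type USER.
#' @export
as_phydat <- function(m) {
  syms <- sort(unique(unlist(m$alphabet)))
  nt <- length(m$taxa); nc <- length(m$id)
  tok <- matrix("?", nt, nc, dimnames = list(m$taxa, NULL))
  for (j in seq_len(nc)) {
    a <- m$alphabet[[j]]
    s <- m$state[, j]
    tok[!is.na(s), j] <- a[s[!is.na(s)]]
    amb <- m$ambig[[j]]
    if (!is.null(amb))
      for (tx in names(amb))
        tok[tx, j] <- paste0("{", paste(a[amb[[tx]]], collapse = ""), "}")
  }
  extra <- setdiff(unique(as.vector(tok)), c(syms, "?"))
  contrast <- rbind(diag(length(syms)),
                    matrix(1, 1, length(syms)))
  rownames(contrast) <- c(syms, "?")
  for (tk in extra) {
    inner <- strsplit(substr(tk, 2L, nchar(tk) - 1L), "")[[1]]
    row <- as.numeric(syms %in% inner)
    contrast <- rbind(contrast, row)
    rownames(contrast)[nrow(contrast)] <- tk
  }
  colnames(contrast) <- syms
  phangorn::phyDat(tok, type = "USER", contrast = contrast)
}

#' Parsimony tree length
#'
#' The sum over all characters of the minimum number of changes on
#' `tree` — computed with the package's own reconstruction DP
#' (`method = "dp"`, the reference) or phangorn's Fitch engine
#' (`method = "fitch"`, fast, used by the heuristic search). The two
#' agree; the test suite asserts it.
#'
#' @param m a `char_matrix` whose taxa cover the tree leaves (leaves
#'   without data are treated as missing).
#' @param tree a `phylo` (rooted or unrooted).
#' @param method `"fitch"` or `"dp"`.
#' @return integer tree length.
#' @export
tree_length <- function(m, tree, method = c("fitch", "dp")) {
  method <- match.arg(method)
  if (method == "dp") {
    rt <- if (ape::is.rooted(tree)) tree else .root_any(tree)
    mm <- align_matrix_to_tree(m, rt)
    return(sum(min_changes(mm, rt)))
  }
  mm <- align_matrix_to_tree(m, tree)
  dat <- as_phydat(mm)
  as.integer(phangorn::parsimony(tree, dat, method = "fitch"))
}

.root_any <- function(tree) {
  if (ape::is.rooted(tree)) tree
  else ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
}

#' Heuristic maximum-parsimony search
#'
#' Each replicate builds a random-addition-sequence starting tree and
#' hill-climbs with SPR (via phangorn's Fitch engine) to a local
#' optimum; the globally best length and all distinct best topologies
#' found across replicates are pooled, and their strict consensus is
#' computed. Deterministic under a fixed seed.
#'
#' @param m a `char_matrix` with at least 4 taxa.
#' @param n_replicates number of independent search replicates.
#' @param seed integer seed (`NULL` = use current RNG state).
#' @param rearrangements `"SPR"` (default) or `"NNI"`.
#' @return an object of class `tree_search_result`: `best_length`,
#'   `trees` (a `multiPhylo` of distinct optimal topologies),
#'   `consensus` (strict), `n_replicates`.
#' @export
heuristic_search <- function(m, n_replicates = 10, seed = NULL,
                             rearrangements = "SPR") {
  if (n_taxa(m) < 4L) stop("need at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  dat <- as_phydat(m)
  best <- Inf
  pool <- list()
  for (i in seq_len(n_replicates)) {
    t0 <- phangorn::random.addition(dat)
    t1 <- suppressMessages(
      phangorn::optim.parsimony(t0, dat, method = "fitch",
                                rearrangements = rearrangements, trace = 0))
    sc <- phangorn::parsimony(t1, dat, method = "fitch")
    if (sc < best - 1e-9) {
      best <- sc
      pool <- list(t1)
    } else if (sc <= best + 1e-9) {
      pool <- c(pool, list(t1))
    }
  }
  # deduplicate topologies
  uniq <- list(pool[[1]])
  for (tr in pool[-1]) {
    dup <- any(vapply(uniq, function(u) robinson_foulds(u, tr) == 0, logical(1)))
    if (!dup) uniq <- c(uniq, list(tr))
  }
  trees <- uniq
  class(trees) <- "multiPhylo"
  cons <- if (length(trees) == 1L) trees[[1]] else
    ape::consensus(trees, p = 1, rooted = FALSE)
  structure(list(best_length = as.integer(best), trees = trees,
                 consensus = cons, n_replicates = n_replicates),
            class = "tree_search_result")
}

#' @export
print.tree_search_result <- function(x, ...) {
  cat("<tree_search_result> best length", x$best_length, "|",
      length(x$trees), "distinct optimal topologies from",
      x$n_replicates, "replicates\n")
  invisible(x)
}

#' Nonparametric bootstrap support
#'
#' Resamples characters with replacement, reruns a reduced heuristic
#' search per replicate, and credits each of the `k` equally
#' parsimonious trees of a replicate with `1/k` per bipartition it
#' contains. Support is the percentage over replicates.
#'
#' @param m a `char_matrix`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param search_reps search replicates per bootstrap sample.
#' @return named numeric vector: bipartition key (see details) ->
#'   percentage. Keys are `"|"`-joined sorted labels of the split side
#'   not containing the alphabetically first taxon.
#' @export
bootstrap_support <- function(m, n_boot = 100, seed = 1, search_reps = 1) {
  set.seed(seed)
  nc <- n_characters(m)
  acc <- new.env(parent = emptyenv())
  for (b in seq_len(n_boot)) {
    res <- heuristic_search(m[sample(nc, replace = TRUE)],
                            n_replicates = search_reps)
    k <- length(res$trees)
    for (tr in res$trees)
      for (key in .tree_splits(tr)) {
        cur <- if (is.null(acc[[key]])) 0 else acc[[key]]
        assign(key, cur + 1 / k, envir = acc)
      }
  }
  keys <- ls(acc)
  out <- vapply(keys, function(k) 100 * acc[[k]] / n_boot, numeric(1))
  sort(out, decreasing = TRUE)
}

# non-trivial bipartitions of an (unrooted sense) tree as canonical keys
.tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(character(0))
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  tr <- reorder(tr, "postorder")
  labs <- tr$tip.label
  ref <- sort(labs)[1]
  m <- ntip + tr$Nnode
  below <- matrix(FALSE, m, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(tr$edge)))
    below[tr$edge[e, 1], ] <- below[tr$edge[e, 1], ] | below[tr$edge[e, 2], ]
  root <- ntip + 1L
  keys <- character(0)
  for (v in setdiff(unique(tr$edge[, 2]), seq_len(ntip))) {
    side <- labs[below[v, ]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (ref %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance
#'
#' `d_RF = |P_a xor P_b| / ((|P_a| + |P_b|) / 2)` where `P_x` is the set
#' of non-trivial bipartitions of tree `x` in the unrooted sense: twice
#' the fraction of bipartitions that differ for equally resolved trees,
#' 0 iff the unrooted topologies agree, at most 2.
#'
#' @param tree_a,tree_b `phylo` objects with identical leaf sets.
#' @return a value in `[0, 2]`.
#' @export
robinson_foulds <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees must share an identical leaf set")
  pa <- .tree_splits(tree_a)
  pb <- .tree_splits(tree_b)
  if (length(pa) + length(pb) == 0L) return(0)
  sym <- length(setdiff(pa, pb)) + length(setdiff(pb, pa))
  sym / ((length(pa) + length(pb)) / 2)
}
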