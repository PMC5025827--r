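# Unordered (Fitch/Sankoff) parsimony with exact MPR accounting.
#
# A most-parsimonious reconstruction (MPR) is one full assignment of
# singleton states to every internal node AND every ambiguous leaf that
# achieves the minimum number of changes; all MPRs get equal weight.  The
# dynamic programme below computes, per node v and state s,
#   cost[v,s] = min changes in the subtree of v given state(v) = s
#   cnt[v,s]  = number of optimal assignments of the subtree given s
# so the minimum change count, the total MPR count, and the fraction of
# MPRs consistent with clamping a few nodes to given states are all exact
# (no Monte-Carlo).  Missing leaves are wildcards: they are resolved
# "simultaneously during the inference", never adding changes.

.INFCOST <- 1e12

# postorder bookkeeping for a rooted phylo
.tree_prep <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (!ape::is.rooted(tree)) stop("`tree` must be rooted")
  tree <- reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  m <- ntip + tree$Nnode
  children <- split(tree$edge[, 2], tree$edge[, 1])
  post_int <- unique(tree$edge[, 1])        # postorder: children first
  parent <- integer(m)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  list(tree = tree, n_tip = ntip, n_node = m, children = children,
       post_internal = post_int, parent = parent, root = root)
}

# core DP; sets = list over tips of integer state-index vectors,
# clamp = integer vector length n_node (NA = unconstrained)
.mpr_dp <- function(prep, sets, k, clamp = NULL) {
  m <- prep$n_node
  cost <- matrix(.INFCOST, m, k)
  cnt <- matrix(0, m, k)
  for (i in seq_len(prep$n_tip)) {
    s <- sets[[i]]
    if (!is.null(clamp) && !is.na(clamp[i])) s <- intersect(s, clamp[i])
    cost[i, s] <- 0
    cnt[i, s] <- 1
  }
  for (v in prep$post_internal) {
    cv <- numeric(k)
    wv <- rep(1, k)
    for (ch in prep$children[[as.character(v)]]) {
      cc <- cost[ch, ]
      nc <- cnt[ch, ]
      mc <- min(cc)
      if (mc >= .INFCOST) { cv[] <- .INFCOST; wv[] <- 0; break }
      s0 <- sum(nc[cc == mc])
      cv <- cv + pmin(cc, mc + 1)
      wv <- wv * ifelse(cc == mc, nc, ifelse(cc == mc + 1, nc + s0, s0))
    }
    if (!is.null(clamp) && !is.na(clamp[v])) cv[-clamp[v]] <- .INFCOST
    cost[v, ] <- pmin(cv, .INFCOST)
    cnt[v, ] <- wv
  }
  rc <- cost[prep$root, ]
  mn <- min(rc)
  if (mn >= .INFCOST) return(list(min = Inf, count = 0))
  list(min = mn, count = sum(cnt[prep$root, rc == mn]))
}

#' Summarise most-parsimonious reconstructions of one character
#'
#' Builds the reusable parsimony summary of a single character on a
#' rooted tree: the minimum change count, the exact number of MPRs, and
#' the tables needed by [assignment_fraction()] and
#' [pair_event_weights()].
#'
#' @param m a `char_matrix`.
#' @param tree a rooted `phylo`; every leaf lacking a matrix entry is
#'   treated as missing.
#' @param char character column (position or id).
#' @return an object of class `mpr_summary` with elements `min_changes`
#'   and `mpr_count`.
#' @export
mpr_summary <- function(m, tree, char) {
  j <- if (is.character(char)) match(char, m$id) else char
  if (is.na(j) || j < 1L || j > n_characters(m)) stop("unknown character: ", char)
  prep <- .tree_prep(tree)
  sets <- .col_state_sets(m, j, taxa = prep$tree$tip.label)
  k <- length(m$alphabet[[j]])
  base <- .mpr_dp(prep, sets, k)
  structure(list(char = m$id[j], alphabet = m$alphabet[[j]], k = k,
                 prep = prep, sets = sets,
                 min_changes = base$min, mpr_count = base$count),
            class = "mpr_summary")
}

#' @export
print.mpr_summary <- function(x, ...) {
  cat("<mpr_summary> character", x$char, "- min changes:", x$min_changes,
      "| MPRs:", format(x$mpr_count, big.mark = ","), "\n")
  invisible(x)
}

#' Minimum number of parsimony changes
#'
#' The minimum number of state changes over all assignments of singleton
#' states to internal nodes and ambiguous leaves (missing leaves are free
#' wildcards and never add changes).
#'
#' @inheritParams mpr_summary
#' @param chars columns to evaluate (default all).
#' @return named numeric vector of change counts.
#' @export
min_changes <- function(m, tree, chars = NULL) {
  .per_char_dp(m, tree, chars, function(dp) dp$min)
}

#' Number of most-parsimonious reconstructions
#'
#' Counts distinct full assignments of singleton states to all internal
#' nodes and ambiguous leaves achieving [min_changes()] — the "equally
#' parsimonious pathways" that share weight 1/n in event counting.
#'
#' @inheritParams min_changes
#' @return named numeric vector of MPR counts.
#' @export
count_mprs <- function(m, tree, chars = NULL) {
  .per_char_dp(m, tree, chars, function(dp) dp$count)
}

.per_char_dp <- function(m, tree, chars, extract) {
  if (is.null(chars)) chars <- seq_along(m$id)
  if (is.character(chars)) chars <- match(chars, m$id)
  if (anyNA(chars)) stop("unknown character id")
  prep <- .tree_prep(tree)
  out <- vapply(chars, function(j) {
    sets <- .col_state_sets(m, j, taxa = prep$tree$tip.label)
    extract(.mpr_dp(prep, sets, length(m$alphabet[[j]])))
  }, numeric(1))
  names(out) <- m$id[chars]
  out
}

# resolve node references (tip labels, internal-node labels, or integer
# ape node numbers) to node indices
.resolve_nodes <- function(tree, nodes) {
  ntip <- length(tree$tip.label)
  if (is.numeric(nodes)) {
    idx <- as.integer(nodes)
    if (any(idx < 1L | idx > ntip + tree$Nnode))
      stop("node id out of range")
    return(idx)
  }
  idx <- match(nodes, tree$tip.label)
  if (!is.null(tree$node.label)) {
    miss <- is.na(idx)
    idx[miss] <- ntip + match(nodes[miss], tree$node.label)
  }
  if (anyNA(idx)) stop("unknown node: ", paste(nodes[is.na(idx)], collapse = ", "))
  idx
}

#' Fraction of MPRs consistent with a joint state assignment
#'
#' Clamps up to a handful of nodes (internal nodes or leaves) to given
#' states, re-runs the counting dynamic programme, and returns the exact
#' fraction of MPRs in which all clamped nodes carry the requested
#' states. An empty assignment returns 1.
#'
#' @param summary an [mpr_summary()].
#' @param assignment named vector: names are node references (tip
#'   labels, internal node labels, or integer ape node ids), values are
#'   state symbols from the character's alphabet.
#' @return a fraction in `[0, 1]`.
#' @export
assignment_fraction <- function(summary, assignment) {
  stopifnot(inherits(summary, "mpr_summary"))
  if (length(assignment) == 0L) return(1)
  nodes <- .resolve_nodes(summary$prep$tree, names(assignment))
  states <- match(as.character(assignment), summary$alphabet)
  if (anyNA(states))
    stop("state not in alphabet: ",
         paste(assignment[is.na(states)], collapse = ", "))
  if (anyDuplicated(nodes)) stop("duplicate node in assignment")
  .clamped_fraction(summary, nodes, states)
}

.clamped_fraction <- function(summary, nodes, states) {
  clamp <- rep(NA_integer_, summary$prep$n_node)
  clamp[nodes] <- states
  dp <- .mpr_dp(summary$prep, summary$sets, summary$k, clamp = clamp)
  if (!is.finite(dp$min) || dp$min > summary$min_changes + 1e-9) return(0)
  dp$count / summary$mpr_count
}

#' Homoplasy indices (ci, ri, rc)
#'
#' For each character: `Min` = observed state count − 1 (the smallest
#' change count any tree could need); `Max` = number of unambiguous taxa
#' minus the largest single-state count (the change count on a star-like
#' worst tree); `Obs` = [min_changes()] on the supplied tree. Then
#' `ci = Min/Obs`, `ri = (Max − Obs)/(Max − Min)` and `rc = ci * ri`.
#' Characters with `Obs = 0` (ci undefined) or `Max = Min` (ri undefined)
#' are flagged by `ci_defined` / `ri_defined` and get `NA` indices.
#'
#' @inheritParams min_changes
#' @return a data.frame with one row per character: `id`, `type`,
#'   `states`, `Obs`, `Min`, `Max`, `ci`, `ri`, `rc`, `mpr_count`,
#'   `ci_defined`, `ri_defined`.
#' @export
homoplasy_indices <- function(m, tree, chars = NULL) {
  if (is.null(chars)) chars <- seq_along(m$id)
  if (is.character(chars)) chars <- match(chars, m$id)
  prep <- .tree_prep(tree)
  res <- lapply(chars, function(j) {
    sets <- .col_state_sets(m, j, taxa = prep$tree$tip.label)
    dp <- .mpr_dp(prep, sets, length(m$alphabet[[j]]))
    v <- m$state[, j]
    tab <- table(v[!is.na(v)])
    nstate <- length(tab)
    mn <- max(nstate - 1L, 0L)
    mx <- sum(tab) - if (length(tab)) max(tab) else 0L
    obs <- dp$min
    ci <- if (obs > 0) mn / obs else NA_real_
    ri <- if (mx > mn) (mx - obs) / (mx - mn) else NA_real_
    data.frame(id = m$id[j], type = m$type[j], states = nstate,
               Obs = obs, Min = mn, Max = mx, ci = ci, ri = ri,
               rc = ci * ri, mpr_count = dp$count,
               ci_defined = obs > 0, ri_defined = mx > mn)
  })
  do.call(rbind, res)
}
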