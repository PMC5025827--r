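# Whole-tree branch-pair convergence/divergence analysis.
#
# An independent branch pair is two parent->child edges (1->3, 2->4)
# whose four nodes are distinct and where neither child lies on the
# root-to-child path of the other.  With ancestral states X1..X4, a pair
# shows a convergence iff X1 != X3, X2 != X4 and X3 == X4 (parallel and
# convergent changes are not separated), and a divergence iff X1 != X3,
# X2 != X4 and X3 != X4.  Weights over MPRs make the per-character
# contribution of a pair the exact fraction of MPRs showing the event.

#' Enumerate independent branch pairs
#'
#' Returns every unordered pair of edges of a rooted tree such that the
#' four endpoint nodes are distinct and neither child node is on the path
#' from the root to the other child node.
#'
#' @param tree a rooted `phylo` with at least 3 leaves.
#' @return a data.frame with columns `parent1`, `child1`, `parent2`,
#'   `child2` (ape node ids), one row per independent pair, `child1 <
#'   child2`.
#' @export
enumerate_independent_pairs <- function(tree) {
  prep <- .tree_prep(tree)
  edge <- prep$tree$edge
  ne <- nrow(edge)
  # desc[v, ] = leaves-and-nodes in the subtree rooted at v (incl. v):
  # u is on the path root->w  iff  w is in the subtree of u
  m <- prep$n_node
  insub <- matrix(FALSE, m, m)
  diag(insub) <- TRUE
  for (v in seq_len(m)) insub[v, v] <- TRUE
  for (e in seq_len(ne)) {       # postorder: child rows already complete
    p <- edge[e, 1]; ch <- edge[e, 2]
    insub[p, ] <- insub[p, ] | insub[ch, ]
  }
  ord <- order(edge[, 2])
  edge <- edge[ord, , drop = FALSE]
  out <- list()
  for (a in seq_len(ne - 1L)) {
    p1 <- edge[a, 1]; c1 <- edge[a, 2]
    for (b in (a + 1L):ne) {
      p2 <- edge[b, 1]; c2 <- edge[b, 2]
      if (length(unique(c(p1, c1, p2, c2))) != 4L) next
      if (insub[c1, c2] || insub[c2, c1]) next
      out[[length(out) + 1L]] <- c(p1, c1, p2, c2)
    }
  }
  if (length(out) == 0L)
    return(data.frame(parent1 = integer(), child1 = integer(),
                      parent2 = integer(), child2 = integer()))
  mt <- do.call(rbind, out)
  data.frame(parent1 = mt[, 1], child1 = mt[, 2],
             parent2 = mt[, 3], child2 = mt[, 4])
}

#' MPR-weighted convergence and divergence weights for one branch pair
#'
#' Sums [assignment_fraction()] over all joint ancestral-state
#' assignments `(X1, X2, X3, X4)` at the pair's four nodes satisfying the
#' convergence condition (`X1 != X3`, `X2 != X4`, `X3 == X4`) and the
#' divergence condition (`X3 != X4` instead). Both weights lie in
#' `[0, 1]` per character and their sum never exceeds 1.
#'
#' @param summary an [mpr_summary()] built on the same tree.
#' @param pair one row of [enumerate_independent_pairs()] (or any list
#'   with `parent1`, `child1`, `parent2`, `child2`).
#' @return named numeric vector `c(cv = ..., dv = ...)`.
#' @export
pair_event_weights <- function(summary, pair) {
  stopifnot(inherits(summary, "mpr_summary"))
  n1 <- pair$parent1; n3 <- pair$child1
  n2 <- pair$parent2; n4 <- pair$child2
  k <- summary$k
  frac <- function(nodes, states) .clamped_fraction(summary, nodes, states)
  cv <- 0
  for (s in seq_len(k)) {
    # X3 = X4 = s, X1 != s, X2 != s  by inclusion-exclusion on the clamps
    f34 <- frac(c(n3, n4), c(s, s))
    if (f34 == 0) next
    cv <- cv + f34 -
      frac(c(n1, n3, n4), c(s, s, s)) -
      frac(c(n2, n3, n4), c(s, s, s)) +
      frac(c(n1, n2, n3, n4), c(s, s, s, s))
  }
  dv <- 0
  for (s in seq_len(k)) for (t in seq_len(k)) {
    if (s == t) next
    f34 <- frac(c(n3, n4), c(s, t))
    if (f34 == 0) next
    dv <- dv + f34 -
      frac(c(n1, n3, n4), c(s, s, t)) -
      frac(c(n2, n3, n4), c(t, s, t)) +
      frac(c(n1, n2, n3, n4), c(s, t, s, t))
  }
  c(cv = max(cv, 0), dv = max(dv, 0))
}

#' Whole-tree convergence/divergence tallies
#'
#' Computes MPR-weighted convergence (`Cv`) and divergence (`Dv`)
#' weights for every character over every independent branch pair, and
#' aggregates them per pair (split by character type) and per character
#' (summed over pairs). Exact but exhaustive: cost grows with
#' `pairs x characters x alphabet^2`, so reserve full runs for data of
#' modest size.
#'
#' @inheritParams min_changes
#' @param pairs optionally a subset of rows from
#'   [enumerate_independent_pairs()].
#' @return list with `per_pair` (one row per pair: `Cv_morph`,
#'   `Dv_morph`, `Cv_mol`, `Dv_mol`, `n_morph`, `n_mol`, `defined`) and
#'   `per_char` (one row per character: `id`, `type`, `Cv`, `Dv`).
#' @export
whole_tree_counts <- function(m, tree, pairs = NULL, chars = NULL) {
  if (is.null(pairs)) pairs <- enumerate_independent_pairs(tree)
  if (is.null(chars)) chars <- seq_along(m$id)
  if (is.character(chars)) chars <- match(chars, m$id)
  np <- nrow(pairs)
  is_morph <- m$type[chars] == "morphological"
  cvp <- matrix(0, np, length(chars))
  dvp <- matrix(0, np, length(chars))
  for (ci in seq_along(chars)) {
    sm <- mpr_summary(m, tree, chars[ci])
    for (p in seq_len(np)) {
      w <- pair_event_weights(sm, pairs[p, ])
      cvp[p, ci] <- w["cv"]
      dvp[p, ci] <- w["dv"]
    }
  }
  per_pair <- data.frame(
    pairs,
    Cv_morph = rowSums(cvp[, is_morph, drop = FALSE]),
    Dv_morph = rowSums(dvp[, is_morph, drop = FALSE]),
    Cv_mol = rowSums(cvp[, !is_morph, drop = FALSE]),
    Dv_mol = rowSums(dvp[, !is_morph, drop = FALSE]),
    n_morph = sum(is_morph), n_mol = sum(!is_morph))
  per_pair$defined <- per_pair$Cv_mol > 0 | per_pair$Dv_mol > 0
  per_char <- data.frame(id = m$id[chars], type = m$type[chars],
                         Cv = colSums(cvp), Dv = colSums(dvp))
  list(per_pair = per_pair, per_char = per_char)
}

# round half away from zero, the convention behind "24.67 -> 25"
.round_half_up <- function(x) floor(x + 0.5)

#' Fisher tests for one branch pair's tallies
#'
#' Rounds the weighted counts to the nearest integer (half-up) and runs
#' two two-tailed Fisher's exact tests: `p_conv` compares convergence
#' incidence between the character types using the table
#' `[Cv_morph, n_morph - Cv_morph; Cv_mol, n_mol - Cv_mol]`, and
#' `p_cvdv` compares the Cv/Dv ratio using
#' `[Cv_morph, Dv_morph; Cv_mol, Dv_mol]`. Pairs with
#' `Cv_mol = Dv_mol = 0` have undefined molecular ratios and get `NA`
#' with `defined = FALSE`; exclude them downstream.
#'
#' @param counts a row (or several rows) of `whole_tree_counts()$per_pair`.
#' @return `counts` with columns `p_conv`, `p_cvdv` appended.
#' @export
pair_fisher_tests <- function(counts) {
  cvm <- .round_half_up(counts$Cv_morph); cvs <- .round_half_up(counts$Cv_mol)
  dvm <- .round_half_up(counts$Dv_morph); dvs <- .round_half_up(counts$Dv_mol)
  undef <- counts$Cv_mol == 0 & counts$Dv_mol == 0
  counts$p_conv <- vapply(seq_len(nrow(counts)), function(i) {
    if (undef[i]) return(NA_real_)
    fisher_exact_2x2(cvm[i], counts$n_morph[i] - cvm[i],
                     cvs[i], counts$n_mol[i] - cvs[i])
  }, numeric(1))
  counts$p_cvdv <- vapply(seq_len(nrow(counts)), function(i) {
    if (undef[i]) return(NA_real_)
    fisher_exact_2x2(cvm[i], dvm[i], cvs[i], dvs[i])
  }, numeric(1))
  counts$defined <- !undef
  counts
}

#' State-binned morphological/molecular ratio
#'
#' Characters are binned by their number of states; within each bin the
#' mean morphological per-character ratio is divided by the mean
#' molecular one, and the bin-level quotients are averaged weighted by
#' the number of morphological characters contributing to the bin. This
#' expresses the morphological Cv/Dv (or Cv/Cs) relative to molecular
#' characters *with the same number of states*. Characters with an
#' undefined ratio (`NA`) are excluded from bin means; bins lacking one
#' character type are skipped and reported in attribute `"skipped"`.
#'
#' @param ratios numeric per-character ratios (e.g. summed Cv / summed
#'   Dv), `NA` when undefined.
#' @param state_counts integer number of states per character.
#' @param types character type per character.
#' @return the weighted-average ratio; bin details in attribute
#'   `"bins"`.
#' @export
state_binned_ratio <- function(ratios, state_counts, types) {
  stopifnot(length(ratios) == length(state_counts),
            length(ratios) == length(types))
  ok <- !is.na(ratios) & is.finite(ratios)
  d <- data.frame(r = ratios[ok], n = state_counts[ok],
                  morph = types[ok] == "morphological")
  bins <- sort(unique(d$n))
  rows <- lapply(bins, function(b) {
    db <- d[d$n == b, ]
    nm <- sum(db$morph); ns <- sum(!db$morph)
    data.frame(states = b, n_morph = nm, n_mol = ns,
               mean_morph = if (nm) mean(db$r[db$morph]) else NA_real_,
               mean_mol = if (ns) mean(db$r[!db$morph]) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  tab$quotient <- tab$mean_morph / tab$mean_mol
  usable <- tab$n_morph > 0 & tab$n_mol > 0 & is.finite(tab$quotient)
  if (!any(usable)) stop("no bin contains both character types")
  val <- sum(tab$quotient[usable] * tab$n_morph[usable]) /
    sum(tab$n_morph[usable])
  attr(val, "bins") <- tab
  attr(val, "skipped") <- tab$states[!usable]
  val
}
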