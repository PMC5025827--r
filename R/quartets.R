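# Quartet congruence and convergence/consistency scoring.
#
# A quartet is four taxa (Y1, Y2 | Y3, Y4) such that in BOTH input trees
# (i) Y1+Y2 form a clade excluding Y3 and Y4, (ii) Y3+Y4 form a clade
# excluding Y1 and Y2, and (iii) the root of the induced four-taxon tree
# sits on the internal branch.  For rooted trees, (i) + (ii) force the
# two cherry ancestors to be disjoint, which places the projection of
# the root on the internal branch, so (iii) is implied; it is still what
# the enumeration guarantees.

#' Find quartets congruent between two rooted trees
#'
#' Enumerates every 4-subset of the shared taxa that satisfies the
#' quartet conditions in both trees, each reported once in canonical
#' order (cherries sorted internally; the cherry containing the smallest
#' shared label first).
#'
#' @param tree_a,tree_b rooted `phylo` objects sharing at least 4 leaf
#'   labels.
#' @return a data.frame with character columns `Y1`, `Y2`, `Y3`, `Y4`
#'   (Y1, Y2 sister; Y3, Y4 sister); zero rows (with a warning) when
#'   fewer than 4 taxa are shared.
#' @export
find_congruent_quartets <- function(tree_a, tree_b) {
  shared <- sort(intersect(tree_a$tip.label, tree_b$tip.label))
  empty <- data.frame(Y1 = character(), Y2 = character(),
                      Y3 = character(), Y4 = character())
  if (length(shared) < 4L) {
    warning("fewer than 4 shared taxa; no quartets")
    return(empty)
  }
  n <- length(shared)
  prs <- t(combn(n, 2L))
  bad <- .pair_clade_mask(tree_a, shared, prs) |
    .pair_clade_mask(tree_b, shared, prs)
  i1 <- prs[, 1]; i2 <- prs[, 2]
  np <- nrow(prs)
  res <- list()
  for (p in seq_len(np - 1L)) {
    q <- (p + 1L):np
    ok <- !bad[p, i1[q]] & !bad[p, i2[q]] &
      !bad[q, i1[p]] & !bad[q, i2[p]] &
      i1[q] != i1[p] & i1[q] != i2[p] & i2[q] != i2[p]   # i2[q] > i1[p] always
    if (any(ok)) {
      qq <- q[ok]
      res[[length(res) + 1L]] <-
        cbind(i1[p], i2[p], i1[qq], i2[qq])
    }
  }
  if (length(res) == 0L) return(empty)
  mt <- do.call(rbind, res)
  data.frame(Y1 = shared[mt[, 1]], Y2 = shared[mt[, 2]],
             Y3 = shared[mt[, 3]], Y4 = shared[mt[, 4]])
}

# logical matrix [pair, taxon]: taxon is inside the smallest clade
# containing the pair (evaluated on the tree pruned to the shared taxa)
.pair_clade_mask <- function(tree, shared, prs) {
  tr <- if (length(tree$tip.label) > length(shared))
    ape::keep.tip(tree, shared) else tree
  prep <- .tree_prep(tr)
  m <- prep$n_node
  ntip <- prep$n_tip
  tipmap <- match(tr$tip.label, shared)       # tree tip -> shared index
  inclade <- matrix(FALSE, m, length(shared))
  for (i in seq_len(ntip)) inclade[i, tipmap[i]] <- TRUE
  edge <- prep$tree$edge
  for (e in seq_len(nrow(edge)))
    inclade[edge[e, 1], ] <- inclade[edge[e, 1], ] | inclade[edge[e, 2], ]
  mr <- ape::mrca(tr)
  ord <- match(shared, tr$tip.label)
  mr <- mr[ord, ord]
  inclade[mr[prs], , drop = FALSE]
}

#' Classify a character's pattern on one quartet
#'
#' With observed singleton states `(x1, x2, x3, x4)` at `(Y1, Y2, Y3,
#' Y4)`: convergent when the pattern is `(A, B, A, B)` or `(A, B, B,
#' A)`; consistent when it is `(A, A, B, B)` (one change on the internal
#' branch suffices); anything else — a missing or polymorphic entry, a
#' third state, or any other pattern — is `"other"`.
#'
#' @param states a length-4 vector of state symbols in quartet order;
#'   `NA` marks a missing or polymorphic entry.
#' @return `"convergent"`, `"consistent"` or `"other"`.
#' @export
classify_quartet_character <- function(states) {
  stopifnot(length(states) == 4L)
  if (anyNA(states)) return("other")
  x <- as.character(states)
  if (x[1] != x[2] && ((x[1] == x[3] && x[2] == x[4]) ||
                       (x[1] == x[4] && x[2] == x[3]))) return("convergent")
  if (x[1] == x[2] && x[3] == x[4] && x[1] != x[3]) return("consistent")
  "other"
}

#' Tally convergences and consistencies over quartets
#'
#' Applies the quartet pattern classification of every character to
#' every quartet and aggregates: per quartet, convergence (`Cv`) and
#' consistency (`Cs`) counts split by character type; per character,
#' `Cv` and `Cs` summed over all quartets (the quantity the filtering
#' pipeline consumes). Quartets with `Cv_mol = Cs_mol = 0` are flagged
#' `defined = FALSE`: their molecular Cv/Cs is undefined and they are
#' excluded from morphological-vs-molecular comparisons.
#'
#' @param m a `char_matrix` containing the quartet taxa.
#' @param quartets a data.frame from [find_congruent_quartets()].
#' @return list with data.frames `per_quartet` (`Cv_morph`, `Cs_morph`,
#'   `Cv_mol`, `Cs_mol`, `n_morph`, `n_mol`, `defined`) and `per_char`
#'   (`id`, `type`, `Cv`, `Cs`).
#' @export
quartet_tally <- function(m, quartets) {
  nq <- nrow(quartets)
  nc <- n_characters(m)
  is_morph <- m$type == "morphological"
  i1 <- match(quartets$Y1, m$taxa); i2 <- match(quartets$Y2, m$taxa)
  i3 <- match(quartets$Y3, m$taxa); i4 <- match(quartets$Y4, m$taxa)
  if (anyNA(c(i1, i2, i3, i4))) stop("quartet taxon absent from matrix")
  cv_char <- numeric(nc); cs_char <- numeric(nc)
  cvm <- numeric(nq); csm <- numeric(nq); cvs <- numeric(nq); css <- numeric(nq)
  X <- m$state
  for (q in seq_len(nq)) {
    x1 <- X[i1[q], ]; x2 <- X[i2[q], ]; x3 <- X[i3[q], ]; x4 <- X[i4[q], ]
    conv <- x1 != x2 & ((x1 == x3 & x2 == x4) | (x1 == x4 & x2 == x3))
    cons <- x1 == x2 & x3 == x4 & x1 != x3
    conv[is.na(conv)] <- FALSE
    cons[is.na(cons)] <- FALSE
    cv_char <- cv_char + conv
    cs_char <- cs_char + cons
    cvm[q] <- sum(conv & is_morph); csm[q] <- sum(cons & is_morph)
    cvs[q] <- sum(conv & !is_morph); css[q] <- sum(cons & !is_morph)
  }
  per_quartet <- data.frame(quartets,
                            Cv_morph = cvm, Cs_morph = csm,
                            Cv_mol = cvs, Cs_mol = css,
                            n_morph = sum(is_morph), n_mol = sum(!is_morph))
  per_quartet$defined <- per_quartet$Cv_mol > 0 | per_quartet$Cs_mol > 0
  list(per_quartet = per_quartet,
       per_char = data.frame(id = m$id, type = m$type,
                             Cv = cv_char, Cs = cs_char))
}
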