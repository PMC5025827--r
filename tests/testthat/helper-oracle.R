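# Brute-force parsimony oracle: enumerate every assignment of singleton
# states to internal nodes and ambiguous leaves, score changes directly
# on the edge list.  Independent of the package's dynamic programme.

# sets: list over tips (in tree tip order) of integer state vectors
oracle_enumerate <- function(tree, sets, k) {
  tree <- reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  free <- c(which(lengths(sets) > 1L), (ntip + 1L):nnode)
  fixed <- setdiff(seq_len(ntip), free)
  choices <- lapply(free, function(v) if (v <= ntip) sets[[v]] else seq_len(k))
  grid <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  assign_full <- matrix(0L, nrow(grid), nnode)
  for (v in fixed) assign_full[, v] <- sets[[v]]
  assign_full[, free] <- grid
  edge <- tree$edge
  changes <- integer(nrow(grid))
  for (e in seq_len(nrow(edge)))
    changes <- changes +
      (assign_full[, edge[e, 1]] != assign_full[, edge[e, 2]])
  mn <- min(changes)
  list(min = mn, count = sum(changes == mn),
       opt = assign_full[changes == mn, , drop = FALSE])
}

oracle_fraction <- function(oracle, nodes, states) {
  hit <- rep(TRUE, nrow(oracle$opt))
  for (i in seq_along(nodes))
    hit <- hit & oracle$opt[, nodes[i]] == states[i]
  mean(hit)
}

oracle_pair_weights <- function(oracle, pair) {
  x1 <- oracle$opt[, pair$parent1]; x3 <- oracle$opt[, pair$child1]
  x2 <- oracle$opt[, pair$parent2]; x4 <- oracle$opt[, pair$child2]
  c(cv = mean(x1 != x3 & x2 != x4 & x3 == x4),
    dv = mean(x1 != x3 & x2 != x4 & x3 != x4))
}

# random instance: rooted topology, k-state column with optional missing
# and polymorphic leaves; returns the char_matrix (fixed alphabet so the
# package and the oracle share k) plus the raw state sets
random_parsimony_instance <- function(ntaxa, k, p_missing = 0.15,
                                      p_poly = 0.1) {
  tree <- ape::rtree(ntaxa, br = NULL)
  tree$tip.label <- paste0("t", seq_len(ntaxa))
  alpha <- as.character(seq_len(k))
  sets <- vector("list", ntaxa)
  tok <- character(ntaxa)
  for (i in seq_len(ntaxa)) {
    u <- runif(1)
    if (u < p_missing) {
      sets[[i]] <- seq_len(k)
      tok[i] <- "?"
    } else if (u < p_missing + p_poly && k >= 2) {
      s <- sort(sample(k, 2))
      sets[[i]] <- s
      tok[i] <- paste0("{", paste(alpha[s], collapse = ""), "}")
    } else {
      s <- sample(k, 1)
      sets[[i]] <- s
      tok[i] <- alpha[s]
    }
  }
  m <- character_matrix(matrix(tok, ncol = 1,
                               dimnames = list(tree$tip.label, NULL)),
                        alphabet = alpha)
  list(tree = tree, sets = sets, k = k, matrix = m)
}

# token matrix helper: one string of tokens per taxon is clumsy for
# polymorphism, so take a list of per-taxon token vectors
tok_matrix <- function(..., taxa) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- taxa
  m
}

# clean-signal fixture: every internal branch of the given rooted binary
# tree is supported by `per_branch` compatible binary characters
clean_signal_matrix <- function(tree, per_branch = 5) {
  ntip <- length(tree$tip.label)
  prep <- convergia:::.tree_prep(tree)
  below <- matrix(FALSE, prep$n_node, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  edge <- prep$tree$edge
  for (e in seq_len(nrow(edge)))
    below[edge[e, 1], ] <- below[edge[e, 1], ] | below[edge[e, 2], ]
  cols <- list()
  for (v in setdiff(unique(edge[, 2]), seq_len(ntip))) {
    side <- below[v, ]
    if (sum(side) < 2 || sum(!side) < 2) next
    for (r in seq_len(per_branch))
      cols[[length(cols) + 1L]] <- ifelse(side, "1", "0")
  }
  tok <- do.call(cbind, cols)
  rownames(tok) <- prep$tree$tip.label
  character_matrix(tok)
}
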