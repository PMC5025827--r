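quartet_tree <- function() read_newick(text = "((Y1,Y2)A,(Y3,Y4)B)R;")
qmat <- function(states) {
  character_matrix(matrix(states, 4, 1,
                          dimnames = list(c("Y1", "Y2", "Y3", "Y4"), NULL)))
}

# brute-force pair enumeration straight from the three conditions
oracle_pairs <- function(tree) {
  prep <- convergia:::.tree_prep(tree)
  edge <- prep$tree$edge
  m <- prep$n_node
  insub <- diag(m) > 0
  for (e in seq_len(nrow(edge)))
    insub[edge[e, 1], ] <- insub[edge[e, 1], ] | insub[edge[e, 2], ]
  n <- 0L
  for (a in seq_len(nrow(edge) - 1L)) for (b in (a + 1L):nrow(edge)) {
    nd <- c(edge[a, ], edge[b, ])
    if (length(unique(nd)) != 4L) next
    if (insub[edge[a, 2], edge[b, 2]] || insub[edge[b, 2], edge[a, 2]]) next
    n <- n + 1L
  }
  n
}

test_that("independent pair enumeration matches the conditions", {
  tr <- quartet_tree()
  pr <- enumerate_independent_pairs(tr)
  expect_equal(nrow(pr), 8)
  # no pair shares a node; neither child ancestral to the other
  for (i in seq_len(nrow(pr))) {
    nd <- unlist(pr[i, ])
    expect_equal(length(unique(nd)), 4)
  }
  tr3 <- read_newick(text = "(A,(B,C));")
  expect_equal(nrow(enumerate_independent_pairs(tr3)), oracle_pairs(tr3))
  set.seed(3)
  for (i in 1:5) {
    rt <- ape::rtree(sample(4:8, 1), br = NULL)
    expect_equal(nrow(enumerate_independent_pairs(rt)), oracle_pairs(rt))
  }
})

test_that("pair event weights reproduce the worked quartet cases", {
  tr <- quartet_tree()
  pr <- enumerate_independent_pairs(tr)
  tip <- function(l) which(tr$tip.label == l)
  grab <- function(a, b) {
    pr[pr$child1 == min(tip(a), tip(b)) & pr$child2 == max(tip(a), tip(b)), ]
  }
  sm <- mpr_summary(qmat(c("A", "B", "A", "B")), tr, 1)
  expect_equal(pair_event_weights(sm, grab("Y2", "Y4")),
               c(cv = 0.5, dv = 0))
  expect_equal(pair_event_weights(sm, grab("Y1", "Y4")),
               c(cv = 0, dv = 0))
  sm2 <- mpr_summary(qmat(c("A", "B", "A", "C")), tr, 1)
  expect_equal(pair_event_weights(sm2, grab("Y2", "Y4")),
               c(cv = 0, dv = 1))
})

test_that("pair weights agree with explicit MPR enumeration", {
  set.seed(202)
  for (i in 1:12) {
    inst <- random_parsimony_instance(6, 3, p_missing = 0.15, p_poly = 0.05)
    orc <- oracle_enumerate(inst$tree, inst$sets, inst$k)
    sm <- mpr_summary(inst$matrix, inst$tree, 1)
    pr <- enumerate_independent_pairs(inst$tree)
    for (p in sample(nrow(pr), min(4, nrow(pr)))) {
      w <- pair_event_weights(sm, pr[p, ])
      ow <- oracle_pair_weights(orc, pr[p, ])
      expect_equal(w, ow, tolerance = 1e-12,
                   info = paste("instance", i, "pair", p))
      expect_lte(w[["cv"]] + w[["dv"]], 1 + 1e-12)
    }
  }
})

test_that("unique-MPR characters give 0/1 weights equal to inspection", {
  tr <- quartet_tree()
  sm <- mpr_summary(qmat(c("A", "B", "A", "C")), tr, 1)   # unique MPR: all A
  expect_equal(sm$mpr_count, 1)
  pr <- enumerate_independent_pairs(tr)
  for (p in seq_len(nrow(pr))) {
    w <- pair_event_weights(sm, pr[p, ])
    expect_true(all(w %in% c(0, 1)))
  }
})

test_that("per-pair Fisher tests round half-up and flag undefined pairs", {
  counts <- data.frame(Cv_morph = c(24.67, 0), Dv_morph = c(9.84, 2),
                       Cv_mol = c(21.88, 0), Dv_mol = c(88.57, 0),
                       n_morph = c(3414, 100), n_mol = c(5722, 200))
  out <- pair_fisher_tests(counts)
  expect_equal(out$p_conv[1], fisher_exact_2x2(25, 3414 - 25, 22, 5722 - 22))
  expect_equal(out$p_cvdv[1], fisher_exact_2x2(25, 10, 22, 89))
  expect_true(is.na(out$p_conv[2]) && is.na(out$p_cvdv[2]))
  expect_false(out$defined[2])
})

test_that("whole-tree tallies agree with per-pair sums on a small matrix", {
  tr <- quartet_tree()
  taxa <- c("Y1", "Y2", "Y3", "Y4")
  tok <- tok_matrix(c("A", "A", "0"), c("B", "A", "1"),
                    c("A", "B", "0"), c("B", "B", "1"), taxa = taxa)
  m <- character_matrix(tok, type = c("morphological", "morphological",
                                      "molecular"))
  res <- whole_tree_counts(m, tr)
  expect_equal(nrow(res$per_pair), 8)
  expect_equal(sum(res$per_char$Cv[res$per_char$type == "morphological"]),
               sum(res$per_pair$Cv_morph))
  expect_equal(sum(res$per_char$Dv[res$per_char$type == "molecular"]),
               sum(res$per_pair$Dv_mol))
})

test_that("state-binned ratio averages bins weighted by morphology counts", {
  # single bin: morph mean 0.2, mol mean 0.4 -> 0.5
  r1 <- state_binned_ratio(c(0.2, 0.2, 0.4, 0.4), c(2, 2, 2, 2),
                           c("morphological", "morphological",
                             "molecular", "molecular"))
  expect_equal(as.numeric(r1), 0.5)
  # two bins with quotients 1.0 and 0.5, morph counts 3 and 1 -> 0.875
  ratios <- c(rep(0.2, 3), 0.2, 0.3, 0.2, 0.6)
  states <- c(rep(2, 3), 2, 3, 2, 3)
  types <- c(rep("morphological", 3), "molecular", "morphological",
             "molecular", "molecular")
  r2 <- state_binned_ratio(ratios, states, types)
  expect_equal(as.numeric(r2), (3 * 1 + 1 * 0.5) / 4)
  # identity
  r3 <- state_binned_ratio(c(1, 1, 1, 1), c(2, 2, 3, 3),
                           rep(c("morphological", "molecular"), 2))
  expect_equal(as.numeric(r3), 1)
  # a bin lacking one type is skipped and reported
  r4 <- state_binned_ratio(c(0.2, 0.4, 0.7), c(2, 2, 5),
                           c("morphological", "molecular", "morphological"))
  expect_equal(as.numeric(r4), 0.5)
  expect_equal(attr(r4, "skipped"), 5)
})
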