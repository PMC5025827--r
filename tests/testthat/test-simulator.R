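test_that("transition matrix has the prescribed structure", {
  M2 <- build_transition_matrix(2)
  expect_equal(M2[1, 2], 0.005)
  expect_equal(M2[1, 1], 0.995)
  for (N in c(2, 5, 20)) {
    M <- build_transition_matrix(N)
    expect_equal(unname(rowSums(M)), rep(1, N))
    expect_true(all(M[upper.tri(M)] == 0.01 / N))
    # uniform stationary distribution
    pi0 <- rep(1 / N, N)
    expect_equal(as.numeric(pi0 %*% M), pi0)
  }
  expect_error(build_transition_matrix(1), "N must be")
})

test_that("rate draws hit the target correlation with mean exactly one", {
  d <- default_state_distribution("morphological")
  set.seed(3)
  n <- sample(d$values, 20000, replace = TRUE, prob = d$prob)
  r0 <- draw_rates(n, d, rho = 0)
  expect_lt(abs(cor(r0, n)), 0.03)
  expect_equal(mean(r0), 1, tolerance = 1e-12)
  expect_true(all(r0 > 0))
  r <- draw_rates(n, d, rho = 0.64)
  expect_equal(cor(r, n), 0.64, tolerance = 0.02)
  expect_equal(mean(r), 1, tolerance = 1e-12)
  expect_warning(rdeg <- draw_rates(1:5 * 0 + 3, list(values = 3, prob = 1)),
                 "degenerate")
  expect_equal(rdeg, rep(1, 5))
})

test_that("single-branch evolution matches the analytic step model", {
  # one branch, k = 1 step: P(change) = 0.01 (N-1)/N
  two <- read_newick(text = "(L1:0.01,L2:0);")
  N <- 4
  set.seed(6)
  sim <- convergia:::.simulate_chars(two, rep(N, 100000), rep(1, 100000))
  changed <- sim$leaf_states[1, ] != sim$leaf_states[2, ]
  p <- 0.01 * (N - 1) / N
  se <- sqrt(p * (1 - p) / 100000)
  expect_equal(mean(changed), p, tolerance = 4 * se / p)
  # with a single 1-step branch, the recorded steps are exactly the changes
  expect_true(all(sim$steps %in% 0:1))
  expect_equal(unname(changed), sim$steps == 1)
  # zero branch lengths: no change anywhere, zero steps
  z <- read_newick(text = "((L1:0,L2:0):0,(L3:0,L4:0):0);")
  simz <- convergia:::.simulate_chars(z, rep(3, 50), rep(1, 50))
  expect_true(all(simz$steps == 0))
  expect_true(all(apply(simz$leaf_states, 2,
                        function(col) length(unique(col)) == 1)))
  # long branch: leaf distribution approaches uniform
  lng <- read_newick(text = "(L1:50,L2:50);")
  set.seed(7)
  siml <- convergia:::.simulate_chars(lng, rep(4, 20000), rep(1, 20000))
  tab <- table(factor(siml$leaf_states[1, ], levels = 1:4))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("negative branch lengths and bad inputs error", {
  bad <- read_newick(text = "(L1:-0.1,L2:0.1);")
  expect_error(simulate_character(bad, 3, 1), "negative branch")
  expect_error(convergia:::.simulate_chars(mammal_tree(), 1L, 1), "N >= 2")
})

test_that("datasets are seed-reproducible with faithful metadata", {
  cfg <- sim_config(n_morph = 150, n_mol = 250, n_replicates = 2, seed = 99)
  d1 <- simulate_dataset(cfg, 1)
  d2 <- simulate_dataset(cfg, 1)
  expect_identical(d1$matrix$state, d2$matrix$state)
  expect_identical(d1$meta, d2$meta)
  d3 <- simulate_dataset(cfg, 2)
  expect_false(identical(d1$matrix$state, d3$matrix$state))
  expect_equal(d1$meta$type, c(rep("morphological", 150), rep("molecular", 250)))
  expect_true(all(d1$meta$steps >= 0))
  # constant columns are flagged and observed counts consistent
  expect_equal(d1$meta$constant, d1$meta$n_states_observed == 1)
  expect_equal(unname(observed_state_counts(d1$matrix)),
               d1$meta$n_states_observed)
  # realised steps correlate positively with the drawn rate
  expect_gt(cor(d1$meta$steps, d1$meta$rate), 0.3)
})

test_that("default state-count distributions emulate the published summaries", {
  dm <- default_state_distribution("morphological")
  expect_equal(sum(dm$prob), 1)
  expect_equal(dm$prob[1], 0.752)          # binary fraction
  ds <- default_state_distribution("molecular")
  expect_equal(sum(ds$prob), 1)
  expect_equal(ds$prob[1], 0.124)
  cdf <- cumsum(ds$prob)
  med <- ds$values[which(cdf >= 0.5)[1]]
  expect_equal(med, 5)                      # median of the molecular mode
  # generated morphological characters: ~75% binary
  cfg <- sim_config(n_morph = 4000, n_mol = 10, n_replicates = 1, seed = 5)
  d <- simulate_dataset(cfg, 1)
  frac2 <- mean(d$meta$n_states_generated[d$meta$type == "morphological"] == 2)
  expect_equal(frac2, 0.752, tolerance = 0.03)
})

test_that("molecular-like mode keeps multistate signal on the mammal tree", {
  # N = 20 for every character: median observed states at the leaves >= 3
  cfg <- sim_config(n_morph = 1, n_mol = 300, n_replicates = 1,
                    state_dist_mol = list(values = 20, prob = 1), seed = 21)
  expect_warning(d <- simulate_dataset(cfg, 1), "degenerate")
  obs <- d$meta$n_states_observed[d$meta$type == "molecular"]
  expect_gte(stats::median(obs), 3)
})
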