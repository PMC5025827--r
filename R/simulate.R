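# Multistate character-evolution simulator.
#
# Each character gets a number of states N drawn from a configurable
# empirical distribution, an N x N one-step ("1 PAM") transition matrix
# with every off-diagonal entry 0.01/N (equal exchange rates, uniform
# equilibrium), and a relative rate r drawn at a target Pearson
# correlation with N and normalised to mean exactly 1.  Evolution starts
# from a uniform random root state and proceeds branch by branch with
# k = round(100 * r * t) one-step transitions, t being the branch length
# in expected substitutions per character.  Rather than looping over the
# k steps, the implementation draws the number of state-changing steps
# m ~ Binomial(k, 0.01 (N-1)/N) and then the end state from the exact
# m-step distribution of the jump chain on the complete graph,
#   P(end = start) = 1/N + (1 - 1/N) * (-1/(N-1))^m ,
# which is algebraically identical to stepping the chain and records the
# realised substitution count m exactly.

#' Default per-character state-count distributions
#'
#' Shipped approximations to the empirical state-number distributions of
#' the mammal data set: morphological characters are mostly binary
#' (75.2% two-state, geometric tail over 3-6 states, median 2);
#' molecular (amino acid) characters have 12.4% binary columns and a
#' geometric tail over 3-20 chosen to put the median at 5 states.
#'
#' @param type `"morphological"` or `"molecular"`.
#' @return list with integer `values` and matching `prob` (summing
#'   to 1).
#' @export
default_state_distribution <- function(type = c("morphological", "molecular")) {
  type <- match.arg(type)
  if (type == "morphological") {
    w <- 0.5^(0:3)
    list(values = 2:6, prob = c(0.752, 0.248 * w / sum(w)))
  } else {
    w <- 0.8^(0:17)
    list(values = 2:20, prob = c(0.124, 0.876 * w / sum(w)))
  }
}

#' Simulation configuration
#'
#' Bundles and validates the simulator parameters. Defaults are the
#' conditions of the full-scale study: the 46-taxon mammal tree, 20000
#' morphological and 40000 molecular characters per replicate, 50
#' replicates, and a rate-vs-state-number correlation of 0.64.
#'
#' @param tree rooted `phylo` with branch lengths (default
#'   [mammal_tree()]).
#' @param n_morph,n_mol characters per replicate.
#' @param n_replicates number of replicate data sets.
#' @param state_dist_morph,state_dist_mol state-count distributions
#'   (`list(values, prob)`).
#' @param rho target Pearson correlation between relative rate and
#'   number of states, in (-1, 1).
#' @param seed integer seed; replicate r uses a sub-seed derived from
#'   `seed` and `r`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(tree = mammal_tree(), n_morph = 20000, n_mol = 40000,
                       n_replicates = 50,
                       state_dist_morph = default_state_distribution("morphological"),
                       state_dist_mol = default_state_distribution("molecular"),
                       rho = 0.64, seed = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0),
            n_morph >= 1, n_mol >= 1, n_replicates >= 1,
            rho > -1, rho < 1)
  for (d in list(state_dist_morph, state_dist_mol)) {
    stopifnot(length(d$values) == length(d$prob), all(d$values >= 2),
              all(d$prob >= 0))
    if (abs(sum(d$prob) - 1) > 1e-8) stop("state-count probabilities must sum to 1")
  }
  structure(list(tree = tree, n_morph = n_morph, n_mol = n_mol,
                 n_replicates = n_replicates,
                 state_dist_morph = state_dist_morph,
                 state_dist_mol = state_dist_mol,
                 rho = rho, seed = as.integer(seed)),
            class = "sim_config")
}

#' One-step ("1 PAM") transition matrix
#'
#' The `N x N` stochastic matrix with every off-diagonal entry `0.01/N`
#' and diagonal `1 - 0.01 (N-1)/N`: equal exchange rates among all
#' states, uniform equilibrium, about 1% total change probability per
#' step.
#'
#' @param N number of states (>= 2).
#' @return an `N x N` row-stochastic matrix.
#' @export
build_transition_matrix <- function(N) {
  if (N < 2) stop("N must be >= 2")
  M <- matrix(0.01 / N, N, N)
  diag(M) <- 1 - 0.01 * (N - 1) / N
  M
}

#' Draw relative evolutionary rates correlated with state number
#'
#' For each character, a second state number `n'` is drawn independently
#' from the same distribution and the raw rate is
#' `rho * z(n) + sqrt(1 - rho^2) * z(n')`, where `z()` standardises by
#' the distribution's theoretical mean and SD. The raw values are
#' shifted positive (minimum mapped to a small floor) and rescaled so
#' the sample mean is exactly 1; both transformations are affine, so the
#' realised correlation with `n` stays at `rho` up to sampling error.
#'
#' @param n_states integer state numbers of the characters.
#' @param dist the state-count distribution the `n_states` were drawn
#'   from (`list(values, prob)`).
#' @param rho target correlation in (-1, 1).
#' @param floor small positive rate assigned to the slowest character
#'   before rescaling (default 0.01).
#' @return positive rates with `mean(r) == 1`.
#' @export
draw_rates <- function(n_states, dist, rho = 0.64, floor = 0.01) {
  stopifnot(length(n_states) >= 1)
  mu <- sum(dist$values * dist$prob)
  sdv <- sqrt(sum(dist$prob * (dist$values - mu)^2))
  if (sdv == 0) {
    warning("degenerate state-count distribution; all rates set to 1")
    return(rep(1, length(n_states)))
  }
  nprime <- sample(dist$values, length(n_states), replace = TRUE,
                   prob = dist$prob)
  raw <- rho * (n_states - mu) / sdv + sqrt(1 - rho^2) * (nprime - mu) / sdv
  r <- raw - min(raw) + floor
  r / mean(r)
}

# sample state counts; robust to length-1 distributions
.sample_states <- function(dist, n) {
  if (length(dist$values) == 1L) return(rep(dist$values, n))
  sample(dist$values, n, replace = TRUE, prob = dist$prob)
}

# vectorised engine: evolve nc characters (state counts N, rates r) down
# the tree; returns leaf states (tips x nc integer matrix, 1-based) and
# realised substitution-step counts
.simulate_chars <- function(tree, N, r) {
  stopifnot(length(N) == length(r), all(N >= 2), all(r > 0))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree <- reorder(tree, "cladewise")            # parents before children
  nc <- length(N)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  state <- matrix(NA_integer_, nnode, nc)
  root <- ntip + 1L
  state[root, ] <- 1L + as.integer(floor(runif(nc) * N)) # uniform root state
  steps <- numeric(nc)
  pc <- 0.01 * (N - 1) / N                      # per-step change probability
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    k <- as.integer(round(100 * r * tree$edge.length[e]))
    mm <- rbinom(nc, k, pc)
    s <- state[u, ]
    pstay <- 1 / N + (1 - 1 / N) * (-1 / (N - 1))^mm
    stay <- runif(nc) < pstay
    oth <- 1L + as.integer(floor(runif(nc) * (N - 1)))
    oth <- oth + as.integer(oth >= s)           # uniform over the other states
    state[v, ] <- ifelse(stay, s, oth)
    steps <- steps + mm
  }
  list(leaf_states = state[seq_len(ntip), , drop = FALSE],
       steps = steps, tip_label = tree$tip.label)
}

#' Simulate a single character
#'
#' Evolves one character with `n_states` states at relative rate `rate`
#' down `tree` (see the module notes for the exact step scheme). Uses
#' the current RNG state; call `set.seed()` for reproducibility.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param n_states number of states N (>= 2).
#' @param rate relative rate r (> 0).
#' @return an object of class `sim_character`: `states` (named leaf
#'   states, integers in `0..N-1`), `n_states`, `rate`, `steps` (the
#'   realised number of state-changing transitions over the whole
#'   tree).
#' @export
simulate_character <- function(tree, n_states, rate = 1) {
  sim <- .simulate_chars(tree, n_states, rate)
  structure(list(states = stats::setNames(sim$leaf_states[, 1] - 1L,
                                          sim$tip_label),
                 n_states = n_states, rate = rate, steps = sim$steps[1]),
            class = "sim_character")
}

#' Simulate a replicate data set of morphological and molecular characters
#'
#' Generates `n_morph` morphological-like and `n_mol` molecular-like
#' characters on the configured tree. State numbers are drawn per type
#' from the configured distributions; rates are drawn per type with
#' [draw_rates()]. Constant-at-the-leaves columns are retained (flag
#' `constant` in the metadata) — the standard informativeness filter
#' removes them before analysis, mirroring the real-data workflow.
#' Deterministic given `config$seed` and `replicate`.
#'
#' @param config a [sim_config()].
#' @param replicate replicate index in `1..config$n_replicates`.
#' @return list of class `sim_dataset`: `matrix` (a `char_matrix` with
#'   type tags) and `meta` (per character: `id`, `type`,
#'   `n_states_generated`, `rate`, `steps`, `n_states_observed`,
#'   `constant`).
#' @export
simulate_dataset <- function(config, replicate = 1) {
  stopifnot(inherits(config, "sim_config"),
            replicate >= 1, replicate <= config$n_replicates)
  set.seed((config$seed + 7919L * (as.integer(replicate) - 1L)) %% 2147483647L)
  nm <- config$n_morph; ns <- config$n_mol
  Nm <- .sample_states(config$state_dist_morph, nm)
  rm_ <- draw_rates(Nm, config$state_dist_morph, config$rho)
  Ns <- .sample_states(config$state_dist_mol, ns)
  rs <- draw_rates(Ns, config$state_dist_mol, config$rho)
  sim <- .simulate_chars(config$tree, c(Nm, Ns), c(rm_, rs))
  ids <- c(sprintf("m%05d", seq_len(nm)), sprintf("s%05d", seq_len(ns)))
  type <- rep(c("morphological", "molecular"), c(nm, ns))
  leaf <- sim$leaf_states
  nc <- nm + ns
  # build the char_matrix directly: all entries are singletons
  state <- matrix(NA_integer_, nrow(leaf), nc,
                  dimnames = list(sim$tip_label, ids))
  alphabet <- vector("list", nc)
  for (j in seq_len(nc)) {
    obs <- sort(unique(leaf[, j]))
    alphabet[[j]] <- as.character(obs - 1L)
    state[, j] <- match(leaf[, j], obs)
  }
  mat <- new_char_matrix(state, alphabet, vector("list", nc), ids, type,
                         sim$tip_label)
  nobs <- vapply(alphabet, length, integer(1))
  meta <- data.frame(id = ids, type = type,
                     n_states_generated = c(Nm, Ns), rate = c(rm_, rs),
                     steps = sim$steps, n_states_observed = nobs,
                     constant = nobs == 1L)
  structure(list(matrix = mat, meta = meta, replicate = replicate),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> replicate", x$replicate, "-",
      sum(x$meta$type == "morphological"), "morphological +",
      sum(x$meta$type == "molecular"), "molecular characters\n")
  invisible(x)
}
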