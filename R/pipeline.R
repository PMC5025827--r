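# Low-convergence filtering pipeline: score each character by its quartet
# Cv/Cs ratio, drop characters above a cutoff, re-infer the
# total-evidence tree, and benchmark against matched random removals.

#' Default Cv/Cs cutoff ladder
#'
#' Ten cutoffs spanning 5 down to 0.03 (only the endpoints and 0.2 are
#' fixed by the study design; the interior values are a convenient
#' geometric-ish ladder and are configurable everywhere they are used).
#'
#' @return numeric vector of length 10.
#' @export
default_cutoffs <- function() c(5, 2, 1, 0.5, 0.3, 0.2, 0.15, 0.1, 0.05, 0.03)

#' Per-character Cv/Cs ratios from congruent quartets
#'
#' Finds the quartets congruent between the morphological and molecular
#' trees and sums, per character, its convergences and consistencies
#' over all of them. `ratio` is `Cv/Cs`; `Inf` when `Cs = 0 < Cv`; `NA`
#' (undefined, `defined = FALSE`) when the character is never scored in
#' any quartet — such characters are retained at any cutoff because
#' removal requires positive evidence.
#'
#' @param m a `char_matrix`.
#' @param tree_morph,tree_mol rooted `phylo` trees (typically inferred
#'   from the morphological and molecular characters separately).
#' @return data.frame: `id`, `type`, `Cv`, `Cs`, `ratio`, `defined`;
#'   the quartet table is attached as attribute `"quartets"`.
#' @export
per_character_cvcs <- function(m, tree_morph, tree_mol) {
  q <- find_congruent_quartets(tree_morph, tree_mol)
  if (nrow(q) == 0L)
    stop("no congruent quartets between the two trees; ",
         "increase taxon overlap or check rooting")
  tl <- quartet_tally(m, q)
  pc <- tl$per_char
  pc$ratio <- ifelse(pc$Cv + pc$Cs == 0, NA_real_, pc$Cv / pc$Cs)
  pc$defined <- pc$Cv + pc$Cs > 0
  attr(pc, "quartets") <- tl$per_quartet
  pc
}

#' Split characters at a Cv/Cs cutoff
#'
#' Removes every character whose *defined* ratio exceeds the cutoff
#' (`Inf` ratios go at any finite cutoff); undefined-ratio characters
#' are always retained. Retained sets are monotone: a smaller cutoff
#' retains a subset of a larger one.
#'
#' @param ratios data.frame from [per_character_cvcs()].
#' @param cutoff non-negative cutoff (may be `Inf`).
#' @return list of class `filter_result`: `retained`, `removed`
#'   (character ids) and `counts` (per-type retained/removed table).
#' @export
filter_at_cutoff <- function(ratios, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0)
    stop("cutoff must be a single non-negative number")
  removed <- ratios$defined & !is.na(ratios$ratio) & ratios$ratio > cutoff
  counts <- as.data.frame(table(type = ratios$type, removed = removed))
  structure(list(cutoff = cutoff,
                 retained = ratios$id[!removed],
                 removed = ratios$id[removed],
                 counts = counts),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> cutoff", x$cutoff, "-", length(x$retained),
      "retained /", length(x$removed), "removed\n")
  invisible(x)
}

#' Matched random-removal control sets
#'
#' Draws, without replacement, `n_morph_keep` morphological and
#' `n_mol_keep` molecular character ids from the matrix — the size-
#' matched control for a filtered set. Seeded and reproducible.
#'
#' @param m a `char_matrix`.
#' @param n_morph_keep,n_mol_keep per-type numbers of characters to keep.
#' @param n_controls number of control draws.
#' @param seed integer seed.
#' @return list of character-id vectors, one per control.
#' @export
random_removal_control <- function(m, n_morph_keep, n_mol_keep,
                                   n_controls = 50, seed = 1) {
  im <- m$id[m$type == "morphological"]
  io <- m$id[m$type == "molecular"]
  if (n_morph_keep > length(im) || n_mol_keep > length(io))
    stop("keep count exceeds available characters of that type")
  set.seed(seed)
  lapply(seq_len(n_controls), function(i)
    c(sample(im, n_morph_keep), sample(io, n_mol_keep)))
}

#' Run the low-convergence filtering sweep
#'
#' For each cutoff: filter characters by their quartet Cv/Cs ratio,
#' infer the total-evidence parsimony tree from the retained characters,
#' infer trees from matched random-removal controls, and (when a
#' reference tree is given) compute Robinson-Foulds distances. The
#' unfiltered all-character tree is computed once and attached.
#'
#' @param m a `char_matrix` (all taxa, both types).
#' @param tree_morph,tree_mol rooted trees used for quartet scoring.
#' @param cutoffs numeric cutoffs (default [default_cutoffs()]).
#' @param true_tree optional reference `phylo` for d_RF evaluation (the
#'   generating tree in simulation mode).
#' @param seed integer seed driving searches and control draws.
#' @param search_reps heuristic-search replicates per tree inference.
#' @param n_controls random-removal controls per cutoff.
#' @return list of class `filter_report_list`: per cutoff a
#'   `filter_report` with `cutoff`, `filter` (the [filter_at_cutoff()]
#'   result), `tree`, `d_rf`, `control_d_rf`; plus attributes
#'   `original_tree` and `original_d_rf`.
#' @export
run_cutoff_sweep <- function(m, tree_morph, tree_mol,
                             cutoffs = default_cutoffs(), true_tree = NULL,
                             seed = 1, search_reps = 2, n_controls = 5) {
  ratios <- per_character_cvcs(m, tree_morph, tree_mol)
  set.seed(seed)
  original <- heuristic_search(m, n_replicates = search_reps)$consensus
  d_orig <- if (is.null(true_tree)) NA_real_ else
    robinson_foulds(original, true_tree)
  reports <- lapply(seq_along(cutoffs), function(ci) {
    co <- cutoffs[ci]
    fl <- filter_at_cutoff(ratios, co)
    mf <- m[fl$retained]
    tree_f <- heuristic_search(mf, n_replicates = search_reps)$consensus
    nmk <- sum(mf$type == "morphological")
    nsk <- sum(mf$type == "molecular")
    ctrl <- random_removal_control(m, nmk, nsk, n_controls = n_controls,
                                   seed = seed + ci)
    ctrl_trees <- lapply(ctrl, function(ids)
      heuristic_search(m[ids], n_replicates = search_reps)$consensus)
    structure(list(cutoff = co, filter = fl, tree = tree_f,
                   d_rf = if (is.null(true_tree)) NA_real_ else
                     robinson_foulds(tree_f, true_tree),
                   control_d_rf = if (is.null(true_tree)) NA_real_ else
                     vapply(ctrl_trees, robinson_foulds, numeric(1),
                            tree_b = true_tree)),
              class = "filter_report")
  })
  attr(reports, "original_tree") <- original
  attr(reports, "original_d_rf") <- d_orig
  attr(reports, "ratios") <- ratios
  class(reports) <- "filter_report_list"
  reports
}

#' Simulate one replicate and run the full evaluation
#'
#' The simulation-mode pipeline end to end: simulate a data set, keep
#' the parsimony-informative characters, infer the morphological and
#' molecular trees, score quartet convergence between them, filter at
#' the requested cutoffs, infer total-evidence / filtered / control
#' trees, and measure every tree against the known generating tree.
#' Inferred component trees are rooted with `outgroup` before quartet
#' scoring (falling back to the first outgroup taxon if the clade is not
#' recovered).
#'
#' @param config a [sim_config()].
#' @param replicate replicate index.
#' @param cutoffs Cv/Cs cutoffs for the sweep.
#' @param search_reps heuristic-search replicates per inference.
#' @param n_controls random-removal controls per cutoff.
#' @param outgroup taxa used to root inferred trees (default the
#'   `(45, 46)` clade of the mammal tree, intersected with the tree's
#'   leaves).
#' @return list: `d_rf` (named: `morph`, `mol`, `original`), `sweep`
#'   (the [run_cutoff_sweep()] report), `quartet_comparison`
#'   (per-quartet mean-convergence comparison between types), `meta`,
#'   `n_informative`.
#' @export
run_simulation_replicate <- function(config, replicate = 1,
                                     cutoffs = c(0.3),
                                     search_reps = 1, n_controls = 1,
                                     outgroup = c("45", "46")) {
  ds <- simulate_dataset(config, replicate)
  m <- filter_parsimony_informative(ds$matrix)
  seed_r <- (config$seed + 104729L * as.integer(replicate)) %% 2147483647L
  set.seed(seed_r)
  mm <- m[m$type == "morphological"]
  ms <- m[m$type == "molecular"]
  tree_morph <- .root_outgroup(
    heuristic_search(mm, n_replicates = search_reps)$consensus, outgroup)
  tree_mol <- .root_outgroup(
    heuristic_search(ms, n_replicates = search_reps)$consensus, outgroup)
  true_tree <- config$tree
  d_rf <- c(morph = robinson_foulds(tree_morph, true_tree),
            mol = robinson_foulds(tree_mol, true_tree))
  sweep <- run_cutoff_sweep(m, tree_morph, tree_mol, cutoffs = cutoffs,
                            true_tree = true_tree, seed = seed_r,
                            search_reps = search_reps,
                            n_controls = n_controls)
  d_rf["original"] <- attr(sweep, "original_d_rf")
  pq <- attr(attr(sweep, "ratios"), "quartets")
  qcmp <- data.frame(
    morph_rate = pq$Cv_morph / pq$n_morph,
    mol_rate = pq$Cv_mol / pq$n_mol,
    defined = pq$defined)
  qcmp$morph_higher <- qcmp$morph_rate > qcmp$mol_rate
  list(d_rf = d_rf, sweep = sweep, quartet_comparison = qcmp,
       meta = ds$meta, n_informative = n_characters(m))
}

.root_outgroup <- function(tree, outgroup) {
  og <- intersect(outgroup, tree$tip.label)
  if (length(og) == 0L) stop("no outgroup taxon present in tree")
  rooted <- tryCatch(ape::root(tree, outgroup = og, resolve.root = TRUE),
                     error = function(e) NULL)
  if (is.null(rooted))
    rooted <- ape::root(tree, outgroup = og[1], resolve.root = TRUE)
  rooted
}
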