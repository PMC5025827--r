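test_that("NEXUS matrices parse tokens, missing and polymorphism", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c(
    "#NEXUS", "BEGIN DATA;",
    "DIMENSIONS NTAX=4 NCHAR=1;",
    "FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"01\";",
    "MATRIX",
    "tA 0", "tB 1", "tC ?", "tD {01}",
    ";", "END;"), f)
  m <- read_character_matrix(f, dialect = "nexus")
  expect_equal(n_taxa(m), 4)
  expect_equal(n_characters(m), 1)
  sets <- convergia:::.col_state_sets(m, 1)
  a <- m$alphabet[[1]]
  expect_equal(a, c("0", "1"))
  expect_equal(sets, list(1L, 2L, 1:2, 1:2))
})

test_that("TNT matrices parse with per-column observed alphabets", {
  f <- withr::local_tempfile(fileext = ".tnt")
  writeLines(c("xread 'four taxa'", "2 4",
               "alpha 01", "beta 12", "gamma 00", "delta 21",
               ";"), f)
  m <- read_character_matrix(f, dialect = "tnt")
  expect_equal(sort(m$taxa), sort(c("alpha", "beta", "gamma", "delta")))
  expect_equal(m$alphabet[[1]], c("0", "1", "2"))
  expect_equal(m$type, rep("morphological", 2))
  expect_equal(m$state[c("alpha", "beta", "gamma", "delta"), 1],
               c(alpha = 1L, beta = 2L, gamma = 1L, delta = 3L))
})

test_that("FASTA alignments give one column per site", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "AC", ">s2", "AC"), f)
  m <- read_character_matrix(f, dialect = "fasta")
  expect_equal(n_characters(m), 2)
  expect_equal(m$type, rep("molecular", 2))
  # both columns: identical singleton entries for the two taxa
  for (j in 1:2)
    expect_equal(m$state["s1", j], m$state["s2", j])
  expect_false(anyNA(m$state))
})

test_that("malformed files raise parse errors; duplicate taxa rejected", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "no matrix here"), f)
  expect_error(read_character_matrix(f, dialect = "nexus"), "MATRIX")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "AC", ">s1", "AC"), f2)
  expect_error(read_character_matrix(f2, dialect = "fasta"), "duplicate")
})

test_that("parsimony-informative filter follows the two-by-two rule", {
  taxa <- paste0("t", 1:4)
  tok <- tok_matrix(c("A", "A", "A"), c("A", "A", "A"),
                    c("B", "A", "B"), c("B", "B", "?"), taxa = taxa)
  m <- character_matrix(tok, id = c("keep", "one_taxon", "missing_support"))
  f <- filter_parsimony_informative(m)
  expect_equal(f$id, "keep")
  expect_equal(attr(f, "removed"), c("one_taxon", "missing_support"))
  # polymorphic entries support no state
  tok2 <- tok_matrix("A", "A", "B", "{AB}", taxa = taxa)
  expect_equal(n_characters(filter_parsimony_informative(
    character_matrix(tok2))), 0)
  # idempotent
  f2 <- filter_parsimony_informative(f)
  expect_equal(f2$id, f$id)
})

test_that("write + read round-trips every state set", {
  set.seed(11)
  taxa <- paste0("t", 1:5)
  tok <- replicate(8, {
    v <- sample(c("0", "1", "2", "?", "{01}", "{12}"), 5, replace = TRUE,
                prob = c(.3, .3, .15, .15, .05, .05))
    v
  })
  rownames(tok) <- taxa
  m <- character_matrix(tok)
  f <- withr::local_tempfile(fileext = ".nex")
  write_character_matrix(m, f)
  m2 <- read_character_matrix(f, dialect = "nexus")
  for (j in seq_len(n_characters(m))) {
    s1 <- convergia:::.col_state_sets(m, j)
    s2 <- convergia:::.col_state_sets(m2, j)
    # compare as symbol sets (alphabets may be indexed differently)
    expect_equal(lapply(s1, function(s) m$alphabet[[j]][s]),
                 lapply(s2, function(s) m2$alphabet[[j]][s]),
                 info = paste("column", j))
  }
})

test_that("newick io: parsing, the 46-taxon tree, round trip, errors", {
  tr <- read_newick(text = "((A,B),(C,D));")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 4)
  big <- mammal_tree()
  expect_equal(ape::Ntip(big), 46)
  expect_equal(big$Nnode, 45)
  expect_true(ape::is.rooted(big))
  s <- "(t1:1,(t2:1,(t3:1,(t4:1,t5:1):1):1):1);"
  expect_equal(write_newick(read_newick(text = s)), s)
  expect_error(read_newick(text = "((A,B),(C,D);"), "unbalanced")
})

test_that("matrix/tree reconciliation fills missing taxa with wildcards", {
  tok <- tok_matrix("0", "1", "0", taxa = c("A", "B", "C"))
  m <- character_matrix(tok)
  tr <- read_newick(text = "((A,B),(C,D));")
  m2 <- align_matrix_to_tree(m, tr)
  expect_equal(m2$taxa, tr$tip.label)
  sets <- convergia:::.col_state_sets(m2, 1)
  expect_equal(sets[[match("D", m2$taxa)]], 1:2)  # all-missing fossil-style
  expect_error(align_matrix_to_tree(m, tr, add_missing = FALSE), "missing")
})
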