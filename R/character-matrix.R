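# Character matrix container.
#
# A `char_matrix` stores one state *set* per taxon per character:
#   singleton set  = observed state
#   full alphabet  = missing ("?" or gap)
#   proper subset  = polymorphism ("{01}")
# Internally the common case (singleton) lives in an integer matrix
# `state` (taxa x characters, values index the per-column alphabet, NA =
# not a singleton); proper subsets are kept in `ambig`, a per-column
# named list taxon -> integer vector.  An NA entry with no `ambig` record
# is the full alphabet.

#' Construct a character matrix
#'
#' Builds a `char_matrix` from a matrix of state tokens. Recognised
#' tokens: a single state symbol (e.g. `"0"`, `"A"`), `"?"` or `"-"` for
#' missing (the full column alphabet), and `"{01}"` / `"(01)"` for
#' polymorphism.
#'
#' @param x character matrix of tokens, taxa in rows, characters in
#'   columns; `rownames(x)` are taxon labels.
#' @param type character type for every column (`"morphological"` or
#'   `"molecular"`), recycled to the number of columns.
#' @param alphabet `NULL` to use, per column, the symbols observed in
#'   that column (the morphological convention), or a character vector
#'   giving a fixed alphabet shared by all columns (e.g. the 20 amino
#'   acids). Symbols outside a fixed alphabet are treated as missing.
#' @param id optional character ids; defaults to `c1`, `c2`, ...
#' @param taxa optional taxon labels overriding `rownames(x)`.
#' @return an object of class `char_matrix`.
#' @export
character_matrix <- function(x, type = "morphological", alphabet = NULL,
                             id = NULL, taxa = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "character"
  if (is.null(taxa)) taxa <- rownames(x)
  if (is.null(taxa)) stop("taxon labels required (rownames or `taxa`)")
  if (anyDuplicated(taxa)) stop("duplicate taxon label: ",
                                taxa[duplicated(taxa)][1L])
  nc <- ncol(x)
  type <- rep_len(type, nc)
  if (!all(type %in% c("morphological", "molecular")))
    stop("`type` entries must be \"morphological\" or \"molecular\"")
  if (is.null(id)) id <- paste0("c", seq_len(nc))
  if (length(id) != nc) stop("`id` must have one entry per column")

  state <- matrix(NA_integer_, nrow(x), nc, dimnames = list(taxa, id))
  alph <- vector("list", nc)
  ambig <- vector("list", nc)
  for (j in seq_len(nc)) {
    sets <- lapply(x[, j], .parse_state_token)
    if (is.null(alphabet)) {
      a <- sort(unique(unlist(sets)))
      if (length(a) == 0L) a <- "0"  # all-missing column; degenerate
    } else a <- alphabet
    amb <- list()
    for (i in seq_along(sets)) {
      s <- sets[[i]]
      if (is.null(s)) next                       # missing -> full alphabet
      idx <- match(s, a)
      idx <- idx[!is.na(idx)]
      if (length(idx) == 0L) next                # symbols outside alphabet
      if (length(idx) == 1L) state[i, j] <- idx
      else amb[[taxa[i]]] <- sort(idx)
    }
    alph[[j]] <- a
    ambig[j] <- list(if (length(amb)) amb else NULL)
  }
  new_char_matrix(state, alph, ambig, id, type, taxa)
}

# token -> character vector of symbols, or NULL for missing
.parse_state_token <- function(tok) {
  tok <- gsub("[[:space:]]", "", tok)
  if (tok %in% c("?", "-", "")) return(NULL)
  if (grepl("^\\{.*\\}$", tok) || grepl("^\\(.*\\)$", tok)) {
    syms <- strsplit(substr(tok, 2L, nchar(tok) - 1L), "")[[1]]
    if (length(syms) == 0L) return(NULL)
    return(unique(syms))
  }
  if (nchar(tok) != 1L)
    stop("unrecognised state token: '", tok, "'")
  tok
}

new_char_matrix <- function(state, alphabet, ambig, id, type, taxa) {
  m <- list(taxa = taxa, state = state, alphabet = alphabet,
            ambig = ambig, id = id, type = type)
  class(m) <- "char_matrix"
  .validate_char_matrix(m)
  m
}

.validate_char_matrix <- function(m) {
  stopifnot(is.matrix(m$state), nrow(m$state) == length(m$taxa),
            ncol(m$state) == length(m$id),
            length(m$alphabet) == length(m$id),
            length(m$ambig) == length(m$id),
            length(m$type) == length(m$id))
  if (anyDuplicated(m$taxa)) stop("duplicate taxon labels")
  for (j in seq_along(m$id)) {
    k <- length(m$alphabet[[j]])
    v <- m$state[, j]
    if (any(!is.na(v) & (v < 1L | v > k)))
      stop("state index out of alphabet range in column ", m$id[j])
    if (!is.null(m$ambig[[j]])) {
      if (!all(names(m$ambig[[j]]) %in% m$taxa))
        stop("ambiguity entry for unknown taxon in column ", m$id[j])
      bad <- vapply(m$ambig[[j]], function(s)
        length(s) == 0L || any(s < 1L | s > k), logical(1))
      if (any(bad)) stop("empty or out-of-range ambiguity set in column ",
                         m$id[j])
    }
  }
  invisible(m)
}

#' @export
print.char_matrix <- function(x, ...) {
  tab <- table(factor(x$type, c("morphological", "molecular")))
  cat("<char_matrix> ", length(x$taxa), " taxa x ", length(x$id),
      " characters (", tab[["morphological"]], " morphological, ",
      tab[["molecular"]], " molecular)\n", sep = "")
  invisible(x)
}

#' Number of taxa / characters
#' @param m a `char_matrix`.
#' @return integer count.
#' @export
n_taxa <- function(m) length(m$taxa)

#' @rdname n_taxa
#' @export
n_characters <- function(m) length(m$id)

#' Subset characters
#'
#' `m[j]` keeps the columns indexed by `j` (integer positions or character
#' ids); duplicate indices are allowed, which is how bootstrap resampling
#' of characters is expressed.
#'
#' @param x a `char_matrix`.
#' @param j column index (integer, logical, or character id).
#' @param ... ignored.
#' @export
`[.char_matrix` <- function(x, j, ...) {
  if (is.character(j)) j <- match(j, x$id)
  if (is.logical(j)) j <- which(j)
  if (anyNA(j)) stop("unknown character id in subset")
  new_char_matrix(x$state[, j, drop = FALSE], x$alphabet[j], x$ambig[j],
                  x$id[j], x$type[j], x$taxa)
}

# state sets of column j as a list over taxa of integer vectors
.col_state_sets <- function(m, j, taxa = m$taxa) {
  k <- length(m$alphabet[[j]])
  amb <- m$ambig[[j]]
  out <- vector("list", length(taxa))
  ii <- match(taxa, m$taxa)
  for (t in seq_along(taxa)) {
    i <- ii[t]
    if (is.na(i)) { out[[t]] <- seq_len(k); next }   # taxon absent -> missing
    s <- m$state[i, j]
    if (!is.na(s)) out[[t]] <- s
    else if (!is.null(amb) && !is.null(amb[[taxa[t]]])) out[[t]] <- amb[[taxa[t]]]
    else out[[t]] <- seq_len(k)
  }
  out
}

#' Observed number of states per character
#'
#' The number of distinct states appearing as unambiguous (singleton)
#' entries in each column; missing and polymorphic entries do not count.
#'
#' @param m a `char_matrix`.
#' @return named integer vector.
#' @export
observed_state_counts <- function(m) {
  out <- vapply(seq_along(m$id), function(j)
    length(unique(m$state[, j][!is.na(m$state[, j])])), integer(1))
  names(out) <- m$id
  out
}

#' Keep parsimony-informative characters
#'
#' A character is parsimony-informative when at least two of its states
#' are each carried, as an unambiguous singleton entry, by at least two
#' taxa. Missing and polymorphic entries support no state. The ids of
#' removed columns are attached as attribute `"removed"`.
#'
#' @param m a `char_matrix`.
#' @return the filtered `char_matrix`.
#' @export
filter_parsimony_informative <- function(m) {
  keep <- vapply(seq_along(m$id), function(j) {
    v <- m$state[, j]
    tab <- table(v[!is.na(v)])
    sum(tab >= 2L) >= 2L
  }, logical(1))
  out <- m[which(keep)]
  attr(out, "removed") <- m$id[!keep]
  out
}

#' Combine two character matrices column-wise
#'
#' Taxa are merged by label (union); a taxon absent from one input gets
#' all-missing entries for that input's characters, which is how fossils
#' lacking molecular data enter a total-evidence matrix.
#'
#' @param a,b `char_matrix` objects.
#' @return a `char_matrix` over the union of taxa.
#' @export
combine_matrices <- function(a, b) {
  taxa <- union(a$taxa, b$taxa)
  expand <- function(m) {
    st <- matrix(NA_integer_, length(taxa), ncol(m$state),
                 dimnames = list(taxa, m$id))
    st[match(m$taxa, taxa), ] <- m$state
    st
  }
  ids <- c(a$id, b$id)
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  new_char_matrix(cbind(expand(a), expand(b)),
                  c(a$alphabet, b$alphabet), c(a$ambig, b$ambig),
                  ids, c(a$type, b$type), taxa)
}

#' Reconcile a matrix with a tree's leaf set
#'
#' Restricts the matrix to taxa present in the tree and adds all-missing
#' rows for tree leaves absent from the matrix, so that every tree leaf
#' has an entry (the wildcard convention used throughout the parsimony
#' machinery).
#'
#' @param m a `char_matrix`.
#' @param tree a rooted `phylo`.
#' @param add_missing add all-missing rows for tree-only leaves
#'   (default `TRUE`); with `FALSE` an error is raised instead.
#' @return a `char_matrix` whose taxa equal `tree$tip.label`.
#' @export
align_matrix_to_tree <- function(m, tree, add_missing = TRUE) {
  leaves <- tree$tip.label
  extra <- setdiff(leaves, m$taxa)
  if (length(extra) && !add_missing)
    stop("tree leaves missing from matrix: ", paste(extra, collapse = ", "))
  st <- matrix(NA_integer_, length(leaves), ncol(m$state),
               dimnames = list(leaves, m$id))
  present <- intersect(leaves, m$taxa)
  st[present, ] <- m$state[present, ]
  ambig <- lapply(m$ambig, function(a) {
    if (is.null(a)) return(NULL)
    a <- a[names(a) %in% leaves]
    if (length(a)) a else NULL
  })
  new_char_matrix(st, m$alphabet, ambig, m$id, m$type, leaves)
}

# render entry (i, j) back to a token
.entry_token <- function(m, i, j) {
  a <- m$alphabet[[j]]
  s <- m$state[i, j]
  if (!is.na(s)) return(a[s])
  amb <- m$ambig[[j]]
  tx <- m$taxa[i]
  if (!is.null(amb) && !is.null(amb[[tx]]))
    return(paste0("{", paste(a[amb[[tx]]], collapse = ""), "}"))
  "?"
}
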