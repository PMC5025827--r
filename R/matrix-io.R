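# Readers and writers for character matrices and trees.
#
# NEXUS and TNT matrices are parsed here directly because polymorphism
# tokens ("{01}", "(01)") must survive the round trip, which the standard
# readers drop.  FASTA and PHYLIP alignments are delegated to ape and
# phangorn.

STANDARD_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")
STANDARD_NT <- c("A", "C", "G", "T")

#' Read a character matrix
#'
#' @param path file path.
#' @param dialect one of `"nexus"`, `"tnt"`, `"fasta"`, `"phylip"`.
#' @param type character type tag applied to all columns
#'   (`"morphological"` for nexus/tnt, `"molecular"` for fasta/phylip by
#'   default).
#' @param alphabet `"observed"` (per-column observed symbols, the
#'   morphological convention), `"aa"` or `"dna"` (fixed standard
#'   alphabets; unknown symbols, gaps and ambiguity codes become
#'   missing), or `"auto"` to guess: sequence dialects pick aa/dna from
#'   their symbols, matrix dialects use observed symbols.
#' @return a [character_matrix()] object.
#' @export
read_character_matrix <- function(path,
                                  dialect = c("nexus", "tnt", "fasta", "phylip"),
                                  type = NULL, alphabet = "auto") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(type))
    type <- if (dialect %in% c("fasta", "phylip")) "molecular" else "morphological"
  toks <- switch(dialect,
                 nexus  = .read_nexus_matrix(path),
                 tnt    = .read_tnt_matrix(path),
                 fasta  = .read_fasta_matrix(path),
                 phylip = .read_phylip_matrix(path))
  alph <- .resolve_alphabet(alphabet, toks, dialect)
  character_matrix(toks, type = type, alphabet = alph)
}

.resolve_alphabet <- function(alphabet, toks, dialect) {
  if (is.character(alphabet) && length(alphabet) == 1L &&
      alphabet %in% c("auto", "observed", "aa", "dna")) {
    if (alphabet == "observed") return(NULL)
    if (alphabet == "aa") return(STANDARD_AA)
    if (alphabet == "dna") return(STANDARD_NT)
    # auto
    if (dialect %in% c("nexus", "tnt")) return(NULL)
    syms <- setdiff(unique(unlist(strsplit(toupper(toks), ""))),
                    c("?", "-", "{", "}", "(", ")"))
    if (all(syms %in% c(STANDARD_NT, "U", "N"))) return(STANDARD_NT)
    return(STANDARD_AA)
  }
  alphabet  # user-supplied vector of symbols
}

# ---- NEXUS ----------------------------------------------------------------

.read_nexus_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\[[^]]*\\]", "", lines)     # strip single-line comments
  up <- toupper(lines)
  mstart <- grep("^\\s*MATRIX\\s*$", up)
  if (length(mstart) != 1L)
    stop("NEXUS parse error: expected exactly one MATRIX line in ", path)
  fmt <- paste(lines[seq_len(mstart)], collapse = " ")
  missing_sym <- .nexus_opt(fmt, "MISSING", "?")
  gap_sym <- .nexus_opt(fmt, "GAP", "-")
  rows <- list()
  for (li in (mstart + 1L):length(lines)) {
    ln <- trimws(lines[li])
    if (ln == "") next
    if (grepl(";", ln)) break
    m <- regmatches(ln, regexec("^('[^']+'|\\S+)\\s+(\\S.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("NEXUS parse error at line ", li, ": cannot split taxon/states")
    taxon <- gsub("^'|'$", "", m[2])
    seq <- gsub("\\s", "", m[3])
    rows[[taxon]] <- paste0(if (is.null(rows[[taxon]])) "" else rows[[taxon]], seq)
  }
  if (length(rows) == 0L) stop("NEXUS parse error: empty MATRIX block")
  tok <- lapply(rows, .split_state_tokens, path = path)
  nlen <- lengths(tok)
  if (length(unique(nlen)) != 1L)
    stop("NEXUS parse error: rows have unequal character counts (",
         paste(unique(nlen), collapse = ", "), ")")
  mat <- do.call(rbind, tok)
  rownames(mat) <- names(rows)
  mat[mat == missing_sym | mat == gap_sym] <- "?"
  mat
}

.nexus_opt <- function(fmt, key, default) {
  m <- regmatches(fmt, regexec(paste0("(?i)", key, "\\s*=\\s*(\\S)"), fmt,
                               perl = TRUE))[[1]]
  if (length(m) == 2L) m[2] else default
}

# split a concatenated row into state tokens, honouring {..} and (..)
.split_state_tokens <- function(seq, path = "") {
  chars <- strsplit(seq, "")[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i
      while (j <= n && chars[j] != close) j <- j + 1L
      if (j > n) stop("parse error in ", path, ": unclosed '", ch, "'")
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

# ---- TNT (xread) ----------------------------------------------------------

.read_tnt_matrix <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("'[^']*'", "", txt)            # drop quoted title
  m <- regmatches(txt, regexec("(?is)xread\\s+(\\d+)\\s+(\\d+)(.*?);", txt,
                               perl = TRUE))[[1]]
  if (length(m) != 4L) stop("TNT parse error: no xread block in ", path)
  nchar_decl <- as.integer(m[2]); ntax_decl <- as.integer(m[3])
  body <- strsplit(trimws(m[4]), "\n")[[1]]
  body <- trimws(body[trimws(body) != "" & !grepl("^&", trimws(body))])
  rows <- list()
  for (ln in body) {
    p <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)$", ln))[[1]]
    if (length(p) != 3L) stop("TNT parse error: bad row '", ln, "'")
    rows[[p[2]]] <- paste0(if (is.null(rows[[p[2]]])) "" else rows[[p[2]]], p[3])
  }
  if (length(rows) != ntax_decl)
    stop("TNT parse error: found ", length(rows), " taxa, declared ", ntax_decl)
  tok <- lapply(rows, .split_state_tokens, path = path)
  if (any(lengths(tok) != nchar_decl))
    stop("TNT parse error: row length != declared nchar")
  mat <- do.call(rbind, tok)
  rownames(mat) <- names(rows)
  mat[mat == "-"] <- "?"
  mat
}

# ---- sequence formats -----------------------------------------------------

.read_fasta_matrix <- function(path) {
  first <- readLines(path, n = 200L, warn = FALSE)
  seqs <- toupper(unlist(strsplit(first[!startsWith(first, ">")], "")))
  type <- if (all(seqs %in% c(STANDARD_NT, "U", "N", "-", "?", ""))) "DNA" else "AA"
  x <- ape::read.FASTA(path, type = type)
  if (anyDuplicated(names(x))) stop("duplicate taxon label in ", path)
  mat <- toupper(as.character(as.matrix(x)))
  rownames(mat) <- names(x)
  mat
}

.read_phylip_matrix <- function(path) {
  first <- paste(readLines(path, n = 50L, warn = FALSE)[-1], collapse = "")
  syms <- unique(strsplit(toupper(gsub("[0-9 ]", "", first)), "")[[1]])
  type <- if (all(syms %in% c(STANDARD_NT, "U", "N", "-", "?", letters, ""))
              && mean(syms %in% c(STANDARD_NT, "U", "N")) > 0.8) "DNA" else "AA"
  x <- phangorn::read.phyDat(path, format = "phylip", type = type)
  mat <- toupper(as.character(x))
  rownames(mat) <- names(x)
  mat
}

# ---- writing --------------------------------------------------------------

#' Write a character matrix as a NEXUS file
#'
#' Writes a `DATA` block with `DATATYPE=STANDARD`, `MISSING=?` and the
#' union of the column alphabets as `SYMBOLS`; polymorphic entries are
#' written as `{..}`. Reading the result back with
#' [read_character_matrix()] preserves every state set.
#'
#' @param m a `char_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(m, path) {
  syms <- sort(unique(unlist(m$alphabet)))
  nt <- length(m$taxa); nc <- length(m$id)
  rows <- vapply(seq_len(nt), function(i)
    paste(vapply(seq_len(nc), function(j) .entry_token(m, i, j),
                 character(1)), collapse = ""), character(1))
  quoted <- ifelse(grepl("\\s", m$taxa), paste0("'", m$taxa, "'"), m$taxa)
  out <- c("#NEXUS", "BEGIN DATA;",
           sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nt, nc),
           sprintf("FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"%s\";",
                   paste(syms, collapse = "")),
           "MATRIX",
           paste(formatC(quoted, width = max(nchar(quoted)), flag = "-"),
                 rows),
           ";", "END;")
  writeLines(out, path)
  invisible(path)
}

# ---- trees ----------------------------------------------------------------

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] with
#' parse-error and leaf-label checks. `write_newick(read_newick(x))`
#' preserves topology, labels and branch lengths to printed precision.
#'
#' @param path file path, or `text =` a Newick string.
#' @param text a Newick string (alternative to `path`).
#' @return `read_newick`: a `phylo`; `write_newick`: the Newick string,
#'   invisibly if written to a file.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  src <- if (is.null(text)) paste(readLines(path, warn = FALSE), collapse = "") else text
  no_q <- gsub("'[^']*'", "", src)
  if (.paren_unbalanced(no_q))
    stop("Newick parse error: unbalanced parentheses")
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("Newick parse error in ", if (is.null(text)) path else "text")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1])
  tr
}

.paren_unbalanced <- function(s) {
  ch <- strsplit(s, "")[[1]]
  depth <- cumsum((ch == "(") - (ch == ")"))
  any(depth < 0) || depth[length(depth)] != 0
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' The 46-taxon mammal reference tree
#'
#' The rooted 46-leaf maximum-likelihood tree (branch lengths in expected
#' substitutions per character) used as the default topology for
#' character-evolution simulation. Leaves are labelled `"1"`..`"46"`.
#'
#' @return a rooted `phylo` with 46 leaves and 45 internal nodes.
#' @export
mammal_tree <- function() {
  path <- system.file("extdata", "mammal_ml_tree.nwk", package = "convergia",
                      mustWork = TRUE)
  read_newick(path)
}
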