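#' @importFrom stats kmeans prcomp pchisq rpois runif setNames complete.cases
#' @importFrom utils write.table read.table combn head tail
NULL

# Alphabet conventions used throughout the package:
#   A,C,G,U   unambiguous bases ('T' normalized to 'U' on input)
#   -         gap / absence of a base
#   ~         non-sequenced (unknown) region; never merged with '-'
#   IUPAC ambiguity codes are accepted and carried through; counting
#   operations skip them.
.BASES <- c("A", "C", "G", "U")
.STATES5 <- c("A", "C", "G", "U", "-")
.IUPAC <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

.OPEN_BRACKETS <- c("(", "[", "{", "<")
.CLOSE_BRACKETS <- c(")", "]", "}", ">")

#' Construct a structural alignment object
#'
#' A structural alignment couples a set of aligned RNA sequences with a
#' single consensus secondary-structure annotation line.  Sequences are
#' strings over `A,C,G,U`, the gap symbol `-`, the non-sequenced symbol
#' `~`, and IUPAC ambiguity codes.  Lowercase letters on input are taken
#' as annotation (e.g. bases marked as mutated) and recorded per column;
#' the stored rows are uppercase.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param rows character vector of aligned sequences, all the same length.
#' @param consensus_structure structure string of the same length, using
#'   round/square/curly/angle brackets and paired `Aa`,`Bb`,... letters
#'   for pseudoknotted stems; `.`/`,`/`_`/`:`/`-`/`~` are unpaired.
#' @param family_label free-text label for the RNA family.
#' @return an object of class `structural_alignment` with elements
#'   `ids`, `rows` (named by id), `consensus_structure`, `family_label`,
#'   `L` (alignment length) and `lowercase` (list of 1-based column
#'   indices that were lowercase in the input).
#' @export
structural_alignment <- function(ids, rows, consensus_structure,
                                 family_label = "") {
  ids <- as.character(ids)
  rows <- as.character(rows)
  if (length(ids) != length(rows))
    stop("ids and rows must have the same length")
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  L <- nchar(consensus_structure)
  bad <- which(nchar(rows) != L)
  if (length(bad))
    stop("alignment rows differ in length from the structure line (",
         L, " columns): ", paste(ids[bad], collapse = ", "))
  lowercase <- lapply(rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    which(ch %in% letters)
  })
  names(lowercase) <- ids
  rows <- toupper(rows)
  rows <- gsub("T", "U", rows, fixed = TRUE)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  ch_ok <- c(.BASES, "-", "~", .IUPAC)
  for (i in seq_along(rows)) {
    ch <- strsplit(rows[i], "", fixed = TRUE)[[1]]
    if (!all(ch %in% ch_ok))
      stop("invalid character(s) in sequence '", ids[i], "': ",
           paste(unique(ch[!ch %in% ch_ok]), collapse = " "))
  }
  .check_structure_balanced(consensus_structure)
  names(rows) <- ids
  structure(list(ids = ids, rows = rows,
                 consensus_structure = consensus_structure,
                 family_label = family_label, L = L,
                 lowercase = lowercase),
            class = "structural_alignment")
}

#' @export
print.structural_alignment <- function(x, ...) {
  cat("Structural alignment", if (nzchar(x$family_label))
    paste0("'", x$family_label, "'") else "", "\n")
  cat("  ", length(x$ids), " sequences x ", x$L, " columns\n", sep = "")
  invisible(x)
}

# split a string into single characters
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Validate that every opening structure symbol has a matching closing
# symbol; errors report the 1-based column of the offending symbol.
.check_structure_balanced <- function(struct) {
  ch <- .chars(struct)
  for (b in seq_along(.OPEN_BRACKETS)) {
    stack <- integer(0)
    for (i in seq_along(ch)) {
      if (ch[i] == .OPEN_BRACKETS[b]) stack <- c(stack, i)
      else if (ch[i] == .CLOSE_BRACKETS[b]) {
        if (!length(stack))
          stop("unbalanced structure: unmatched '", ch[i],
               "' at column ", i)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("unbalanced structure: unmatched '", .OPEN_BRACKETS[b],
           "' at column ", stack[length(stack)])
  }
  for (up in LETTERS) {
    lo <- tolower(up)
    n_up <- sum(ch == up); n_lo <- sum(ch == lo)
    if (n_up != n_lo)
      stop("unbalanced structure: letter class '", up, "' has ", n_up,
           " opening and ", n_lo, " closing symbols (first at column ",
           which(ch %in% c(up, lo))[1], ")")
  }
  invisible(TRUE)
}

# WUSS (Stockholm SS_cons) to bracket-class mapping: brackets map to
# themselves, letters stay as pseudoknot classes, everything else
# (including ',', '_', ':', '-', '.') is unpaired.
.normalize_wuss <- function(struct) {
  ch <- .chars(struct)
  keep <- ch %in% c(.OPEN_BRACKETS, .CLOSE_BRACKETS, LETTERS, letters)
  ch[!keep] <- "."
  paste(ch, collapse = "")
}

#' Read a structural alignment from a file
#'
#' Two dialects are supported.  `"bracket"`: aligned FASTA records
#' followed by a single line starting with `#structure` (or a bare
#' structure line after the records) giving the consensus structure.
#' `"stockholm"`: a Stockholm file whose `#=GC SS_cons` line provides
#' the structure in WUSS notation, mapped onto the same bracket classes.
#' `T` is normalized to `U` and `.` to `-` in sequence rows; lowercase
#' letters are recorded as per-column annotation and uppercased.
#'
#' @param path path to the alignment file.
#' @param dialect `"bracket"` or `"stockholm"`.
#' @param family_label optional family label; defaults to the file name.
#' @return a [structural_alignment] object.
#' @export
read_structural_alignment <- function(path,
                                      dialect = c("bracket", "stockholm"),
                                      family_label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(family_label))
    family_label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "bracket") {
    struct_idx <- grep("^#structure", lines)
    if (length(struct_idx) > 1)
      stop("multiple #structure lines in ", path)
    if (length(struct_idx) == 1) {
      struct <- sub("^#structure\\s*", "", lines[struct_idx])
      lines <- lines[-struct_idx]
    } else struct <- NULL
    lines <- lines[nzchar(trimws(lines))]
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("no FASTA records in ", path)
    ids <- sub("^>\\s*", "", lines[hdr])
    ids <- sub("\\s.*$", "", ids)
    ends <- c(hdr[-1] - 1L, length(lines))
    rows <- vapply(seq_along(hdr), function(i) {
      paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    }, character(1))
    if (is.null(struct))
      stop("no #structure line in ", path)
  } else {
    ss <- grep("^#=GC\\s+SS_cons\\s", lines)
    if (!length(ss)) stop("no #=GC SS_cons line in ", path)
    struct <- paste(vapply(lines[ss], function(l)
      sub("^#=GC\\s+SS_cons\\s+", "", l), character(1)), collapse = "")
    struct <- .normalize_wuss(struct)
    seq_lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                         nzchar(trimws(lines))]
    parts <- strsplit(trimws(seq_lines), "\\s+")
    ids0 <- vapply(parts, `[`, character(1), 1)
    seqs0 <- vapply(parts, function(p) paste(p[-1], collapse = ""),
                    character(1))
    ids <- unique(ids0)
    rows <- vapply(ids, function(id)
      paste(seqs0[ids0 == id], collapse = ""), character(1))
  }
  structural_alignment(ids, rows, struct, family_label)
}

#' Write a structural alignment in the bracket dialect
#'
#' @param aln a [structural_alignment].
#' @param path output path.
#' @export
write_structural_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "structural_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#structure ", aln$consensus_structure), con)
  for (id in aln$ids)
    writeLines(c(paste0(">", id), unname(aln$rows[id])), con)
  invisible(path)
}

#' Read a rooted phylogenetic tree in Newick format
#'
#' Thin wrapper over [ape::read.tree] that validates leaf-name
#' uniqueness and keeps polytomies as they are (multifurcating nodes
#' are never resolved).
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ",
                                            path, ": ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf names in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Write a matrix of counts or log-odds scores as TSV
#'
#' Row and column labels are written; undefined cells (`NA`) are
#' written as the literal string `NA`; numeric values are rounded to
#' 2 decimals, the precision used for log-odds score tables.
#'
#' @param m a numeric matrix with dimnames (a `log_odds_matrix` or the
#'   `counts` of a `substitution_counts` object are accepted directly).
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, "log_odds_matrix") || inherits(m, "substitution_counts"))
    m <- m$matrix %||% m$counts
  stopifnot(is.matrix(m))
  df <- as.data.frame(round(m, 2))
  out <- cbind(state = rownames(m), df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv]
#' @param path path to the TSV file.
#' @return a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   na.strings = "NA", colClasses = "character")
  rn <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
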