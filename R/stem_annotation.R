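# Match all paired symbols in a structure string.  Returns a matrix
# with columns i, j (1-based, i < j) and the symbol class each pair
# belongs to (one class per bracket type or pseudoknot letter).
.match_pairs <- function(struct) {
  ch <- .chars(struct)
  out_i <- integer(0); out_j <- integer(0); out_cls <- character(0)
  for (b in seq_along(.OPEN_BRACKETS)) {
    stack <- integer(0)
    for (k in seq_along(ch)) {
      if (ch[k] == .OPEN_BRACKETS[b]) stack <- c(stack, k)
      else if (ch[k] == .CLOSE_BRACKETS[b]) {
        if (!length(stack))
          stop("unbalanced structure: unmatched '", ch[k],
               "' at column ", k)
        out_i <- c(out_i, stack[length(stack)]); out_j <- c(out_j, k)
        out_cls <- c(out_cls, .OPEN_BRACKETS[b])
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("unbalanced structure: unmatched '", .OPEN_BRACKETS[b],
           "' at column ", stack[length(stack)])
  }
  for (up in LETTERS) {
    lo <- tolower(up)
    stack <- integer(0)
    for (k in seq_along(ch)) {
      if (ch[k] == up) stack <- c(stack, k)
      else if (ch[k] == lo) {
        if (!length(stack))
          stop("unbalanced structure: unmatched '", lo,
               "' at column ", k)
        out_i <- c(out_i, stack[length(stack)]); out_j <- c(out_j, k)
        out_cls <- c(out_cls, up)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("unbalanced structure: unmatched '", up, "' at column ",
           stack[length(stack)])
  }
  cbind.data.frame(i = out_i, j = out_j, cls = out_cls,
                   stringsAsFactors = FALSE)
}

#' Extract stems, loops and pseudoknot flags from a consensus structure
#'
#' Matched symbol pairs are grouped into stems (helices).  Two stacked
#' pairs belong to the same stem when they are directly nested within
#' the same symbol class, no other paired column lies between them, and
#' at most one of the two strands carries unpaired (bulge) columns
#' between them; an internal loop of at least one column on both
#' strands splits the helix, as does interruption by another stem or a
#' multiloop.  Pseudoknots are detected by the arc-crossing rule: stems
#' S and T cross iff some pair (i,j) of S and (k,l) of T satisfy
#' i < k < j < l (or vice versa).
#'
#' Stems are labelled `A`, `B`, ... in order of their 5'-most column.
#'
#' @param struct the consensus structure string.
#' @return an object of class `stem_set`: list with `stems` (each a
#'   list with `label`, `pairs` (2-column matrix, outermost first),
#'   `bulge_cols`, `pseudoknot`, `crossing_partners`), `loops`
#'   (2-column matrix of 1-based closed intervals), and `L`.
#' @export
extract_stems <- function(struct) {
  L <- nchar(struct)
  pairs <- .match_pairs(struct)
  stems <- list()
  if (nrow(pairs)) {
    paired_cols <- sort(c(pairs$i, pairs$j))
    is_paired <- logical(L); is_paired[paired_cols] <- TRUE
    pairs <- pairs[order(pairs$i), , drop = FALSE]
    cur <- NULL; cur_cls <- NULL; cur_bulges <- integer(0)
    flush <- function() {
      if (!is.null(cur))
        stems[[length(stems) + 1]] <<- list(
          pairs = cur, bulge_cols = sort(cur_bulges))
      cur <<- NULL; cur_bulges <<- integer(0)
    }
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]; cls <- pairs$cls[r]
      if (!is.null(cur)) {
        pi <- cur[nrow(cur), 1]; pj <- cur[nrow(cur), 2]
        gap_l <- if (i > pi + 1) (pi + 1):(i - 1) else integer(0)
        gap_r <- if (pj > j + 1) (j + 1):(pj - 1) else integer(0)
        ok <- identical(cls, cur_cls) && i > pi && j < pj &&
          !any(is_paired[gap_l]) && !any(is_paired[gap_r]) &&
          (length(gap_l) == 0 || length(gap_r) == 0)
        if (ok) {
          cur <- rbind(cur, c(i, j))
          cur_bulges <- c(cur_bulges, gap_l, gap_r)
          next
        }
        flush()
      }
      cur <- matrix(c(i, j), 1); cur_cls <- cls
    }
    flush()
  }
  # order stems by 5'-most column and label them
  if (length(stems)) {
    ord <- order(vapply(stems, function(s) s$pairs[1, 1], numeric(1)))
    stems <- stems[ord]
    labs <- if (length(stems) <= 26) LETTERS[seq_along(stems)] else
      paste0("S", seq_along(stems))
    for (k in seq_along(stems)) stems[[k]]$label <- labs[k]
    # pseudoknot detection over all stem pairs
    for (k in seq_along(stems)) {
      stems[[k]]$pseudoknot <- FALSE
      stems[[k]]$crossing_partners <- character(0)
    }
    if (length(stems) > 1) {
      for (a in seq_len(length(stems) - 1)) for (b in (a + 1):length(stems)) {
        if (.stems_cross(stems[[a]]$pairs, stems[[b]]$pairs)) {
          stems[[a]]$pseudoknot <- TRUE
          stems[[b]]$pseudoknot <- TRUE
          stems[[a]]$crossing_partners <-
            c(stems[[a]]$crossing_partners, stems[[b]]$label)
          stems[[b]]$crossing_partners <-
            c(stems[[b]]$crossing_partners, stems[[a]]$label)
        }
      }
    }
  }
  in_stem <- logical(L)
  for (s in stems) in_stem[c(s$pairs)] <- TRUE
  loops <- .runs(which(!in_stem))
  structure(list(stems = stems, loops = loops, L = L), class = "stem_set")
}

# do two sets of arcs cross? (i < k < j < l for some pair of arcs)
.stems_cross <- function(p1, p2) {
  for (a in seq_len(nrow(p1))) for (b in seq_len(nrow(p2))) {
    i <- p1[a, 1]; j <- p1[a, 2]; k <- p2[b, 1]; l <- p2[b, 2]
    if ((i < k && k < j && j < l) || (k < i && i < l && l < j))
      return(TRUE)
  }
  FALSE
}

# maximal runs of consecutive integers -> matrix of [start, end]
.runs <- function(x) {
  if (!length(x)) return(matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("start", "end"))))
  br <- c(0, which(diff(x) > 1), length(x))
  m <- t(vapply(seq_len(length(br) - 1), function(k)
    c(x[br[k] + 1], x[br[k + 1]]), numeric(2)))
  colnames(m) <- c("start", "end")
  m
}

#' @export
print.stem_set <- function(x, ...) {
  cat("Stem set:", length(x$stems), "stems over", x$L, "columns;",
      sum(vapply(x$stems, `[[`, logical(1), "pseudoknot")),
      "pseudoknotted\n")
  invisible(x)
}

.CANONICAL <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Realized length of a stem in one aligned sequence
#'
#' The realized length is the number of the stem's column pairs whose
#' two characters form a canonical base pair (Watson-Crick or G-U
#' wobble).  Pairs involving IUPAC ambiguity codes are skipped (neither
#' counted nor treated as broken).  If any of the stem's columns holds
#' `~` (non-sequenced) the length is unknown and `NA` is returned.
#' With `count_bulges = TRUE`, non-gap bases in the stem's single-strand
#' bulge columns are added to the count.
#'
#' @param row an aligned sequence (single string) from the alignment.
#' @param stem one element of a `stem_set`'s `stems` list.
#' @param count_bulges include stem-internal bulge columns in the count.
#' @return integer count, or `NA` if the region is not sequenced.
#' @export
realized_stem_length <- function(row, stem, count_bulges = FALSE) {
  ch <- .chars(row)
  cols <- c(stem$pairs)
  if (count_bulges) cols <- c(cols, stem$bulge_cols)
  if (any(cols > length(ch)))
    stop("stem column out of range for this row")
  if (any(ch[cols] == "~")) return(NA_integer_)
  n <- 0L
  for (r in seq_len(nrow(stem$pairs))) {
    x <- ch[stem$pairs[r, 1]]; y <- ch[stem$pairs[r, 2]]
    if (x %in% .IUPAC || y %in% .IUPAC) next
    if (paste0(x, y) %in% .CANONICAL) n <- n + 1L
  }
  if (count_bulges)
    n <- n + sum(!ch[stem$bulge_cols] %in% c("-", "~"))
  n
}

#' Stem-length table across an alignment
#'
#' Computes the realized length of every stem in every sequence, flags
#' unknown cells (stem region overlapping `~`), and derives per-stem
#' modal lengths and variability categories.  A stem's category is
#' based on the share of species (with known cells) carrying the modal
#' length: 71-100% conserved, 41-70% intermediate, 1-40% variable.
#' Modal-length ties are broken toward the larger length.
#'
#' @param aln a [structural_alignment].
#' @param stems a `stem_set` from [extract_stems]; defaults to the
#'   stems of `aln`'s own consensus structure.
#' @param count_bulges passed to [realized_stem_length].
#' @return object of class `stem_length_table`: `lengths` (species x
#'   stem integer matrix with `NA` for unknown cells), `unknown`
#'   (logical matrix), `presence` (logical matrix), `modal` (named
#'   integer vector), `category` (named character vector), `stems`.
#' @export
build_stem_length_table <- function(aln, stems = NULL,
                                    count_bulges = FALSE) {
  stopifnot(inherits(aln, "structural_alignment"))
  if (is.null(stems)) stems <- extract_stems(aln$consensus_structure)
  labs <- vapply(stems$stems, `[[`, character(1), "label")
  lengths <- matrix(NA_integer_, length(aln$ids), length(labs),
                    dimnames = list(aln$ids, labs))
  for (s in seq_along(stems$stems))
    lengths[, s] <- vapply(aln$rows, realized_stem_length,
                           integer(1), stem = stems$stems[[s]],
                           count_bulges = count_bulges)
  unknown <- is.na(lengths)
  modal <- vapply(seq_along(labs), function(s) {
    v <- lengths[!unknown[, s], s]
    if (!length(v)) return(NA_integer_)
    tab <- table(v)
    best <- as.integer(names(tab)[tab == max(tab)])
    max(best)  # tie toward the larger length
  }, integer(1))
  names(modal) <- labs
  share <- vapply(seq_along(labs), function(s) {
    v <- lengths[!unknown[, s], s]
    if (!length(v)) return(NA_real_)
    100 * mean(v == modal[s])
  }, numeric(1))
  category <- ifelse(is.na(share), NA_character_,
                     ifelse(share >= 71, "conserved",
                            ifelse(share >= 41, "intermediate",
                                   "variable")))
  names(category) <- labs
  presence <- !unknown & lengths > 0
  structure(list(lengths = lengths, unknown = unknown,
                 presence = presence, modal = modal,
                 category = category, modal_share = share,
                 stems = stems),
            class = "stem_length_table")
}

#' @export
print.stem_length_table <- function(x, ...) {
  cat("Stem-length table:", nrow(x$lengths), "species x",
      ncol(x$lengths), "stems\n")
  cat("Categories:", paste(names(x$category), x$category,
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a stem-length table as TSV (with a #category footer row)
#' @param table a `stem_length_table`.
#' @param path output path.
#' @export
write_stem_length_tsv <- function(table, path) {
  df <- cbind(species = rownames(table$lengths),
              as.data.frame(table$lengths))
  con <- file(path, "w"); on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  writeLines(paste(c("#category", table$category), collapse = "\t"), con)
  invisible(path)
}

#' Drawing-neutral arc-diagram data
#'
#' Produces one arc per stem (outermost pair) with a colour class taken
#' from a per-stem annotation such as the variability category or an
#' ancestral presence state, plus one arc per base pair for detailed
#' rendering.  Crossing (pseudoknotted) arcs are flagged.
#'
#' @param stems a `stem_set`.
#' @param annotations named character vector, one value per stem label
#'   (e.g. `conserved`/`intermediate`/`variable` or
#'   `present`/`absent`/`unresolved`).
#' @return data frame with columns `x1`, `x2`, `label`, `class`,
#'   `crossing`.
#' @export
arc_diagram_data <- function(stems, annotations) {
  labs <- vapply(stems$stems, `[[`, character(1), "label")
  if (is.null(names(annotations)) || !all(labs %in% names(annotations)))
    stop("annotations must be named by stem label; missing: ",
         paste(setdiff(labs, names(annotations)), collapse = ", "))
  data.frame(
    x1 = vapply(stems$stems, function(s) s$pairs[1, 1], numeric(1)),
    x2 = vapply(stems$stems, function(s) s$pairs[1, 2], numeric(1)),
    label = labs,
    class = unname(annotations[labs]),
    crossing = vapply(stems$stems, `[[`, logical(1), "pseudoknot"),
    stringsAsFactors = FALSE)
}

#' Export a stem set as JSON (1-based columns)
#' @param stems a `stem_set`.
#' @param path output path.
#' @export
write_stem_set_json <- function(stems, path) {
  payload <- list(
    L = stems$L,
    stems = lapply(stems$stems, function(s) list(
      label = s$label,
      pairs = unname(apply(s$pairs, 1, function(p) c(p[1], p[2]),
                           simplify = FALSE)),
      bulge_cols = s$bulge_cols,
      pseudoknot = s$pseudoknot,
      crossing_partners = s$crossing_partners)),
    loops = unname(apply(stems$loops, 1, function(r) c(r[1], r[2]),
                         simplify = FALSE)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
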