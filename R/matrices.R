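# state spaces ---------------------------------------------------------
.single_states <- function() .STATES5

# ordered 5'->3' duplets over {A,C,G,U,-} excluding the empty pair (-,-)
.pair_states <- function() {
  g <- expand.grid(second = .STATES5, first = .STATES5,
                   stringsAsFactors = FALSE)
  s <- paste0(g$first, g$second)
  s[s != "--"]
}

.new_counts <- function(states, mode, comparison) {
  m <- matrix(0L, length(states), length(states),
              dimnames = list(states, states))
  structure(list(mode = mode, comparison = comparison, states = states,
                 counts = m, total = 0L),
            class = "substitution_counts")
}

#' @export
print.substitution_counts <- function(x, ...) {
  cat("Substitution counts (", x$mode, ", ", x$comparison, "): ",
      x$total, " events\n", sep = "")
  invisible(x)
}

# a character usable in single-nucleotide tallies
.countable <- function(ch) ch %in% .STATES5

# canonical (unordered) storage: lower triangle in state order,
# i.e. cell [max(idx), min(idx)]
.tally_unordered <- function(counts, a, b, states) {
  ia <- match(a, states); ib <- match(b, states)
  counts[max(ia, ib), min(ia, ib)] <- counts[max(ia, ib), min(ia, ib)] + 1L
  counts
}

# members of a clade usable for a stem: present in the alignment and
# without '~' anywhere in the stem's columns
.clade_members <- function(stem, clade, aln, tree) {
  lv <- .leaves_under(tree)
  members <- intersect(tree$tip.label[lv[[clade]]], aln$ids)
  cols <- sort(c(stem$pairs))
  members[vapply(members, function(m)
    !any(.chars(aln$rows[[m]])[cols] == "~"), logical(1))]
}

#' Count single-nucleotide changes within variable stems
#'
#' Tallies 5-state (`A,C,G,U,-`) juxtapositions over the columns of
#' variable stems.  In `extant_extant` mode every unordered pair of
#' clade members contributes one tally per stem column, stored
#' fold-symmetrically (unordered changes, lower-triangle layout).  In
#' `ancestral_extant` mode the reconstructed ancestral sequence at the
#' clade node is compared with each member, directionally (ancestor in
#' rows, extant in columns).  Columns holding `~`, IUPAC ambiguity
#' codes, or an ancestral `?` are skipped.  No-change (diagonal) cells
#' are tallied too.  The counting unit is one tally per
#' (sequence pair, column).
#'
#' @param aln a [structural_alignment].
#' @param variable data frame from [find_variable_stems].
#' @param stems the `stem_set`.
#' @param tree rooted `phylo`.
#' @param mode `"extant_extant"` or `"ancestral_extant"`.
#' @param anc an `ancestral_sequences` object (required for
#'   `ancestral_extant`).
#' @return a `substitution_counts` object (`mode = "single"`).
#' @export
count_single_changes <- function(aln, variable, stems, tree,
                                 mode = c("extant_extant",
                                          "ancestral_extant"),
                                 anc = NULL) {
  mode <- match.arg(mode)
  states <- .single_states()
  sc <- .new_counts(states, "single", mode)
  if (!nrow(variable)) {
    warning("no variable stems: counts are empty")
    return(sc)
  }
  if (mode == "ancestral_extant" && is.null(anc))
    stop("ancestral_extant mode requires an ancestral reconstruction")
  labs <- vapply(stems$stems, `[[`, character(1), "label")
  counts <- sc$counts
  for (r in seq_len(nrow(variable))) {
    stem <- stems$stems[[match(variable$stem[r], labs)]]
    clade <- variable$node[r]
    cols <- sort(c(stem$pairs))
    members <- .clade_members(stem, clade, aln, tree)
    if (mode == "extant_extant") {
      if (length(members) < 2) next
      seqs <- lapply(members, function(m) .chars(aln$rows[[m]]))
      for (a in seq_len(length(members) - 1))
        for (b in (a + 1):length(members))
          for (col in cols) {
            x <- seqs[[a]][col]; y <- seqs[[b]][col]
            if (.countable(x) && .countable(y))
              counts <- .tally_unordered(counts, x, y, states)
          }
    } else {
      anc_ch <- .chars(anc$sequences[[as.character(clade)]])
      seqs <- lapply(members, function(m) .chars(aln$rows[[m]]))
      for (b in seq_along(members))
        for (col in cols) {
          x <- anc_ch[col]; y <- seqs[[b]][col]
          if (x != "?" && .countable(x) && .countable(y))
            counts[x, y] <- counts[x, y] + 1L
        }
    }
  }
  sc$counts <- counts
  sc$total <- sum(counts)
  sc
}

#' Count base-pair (duplet) changes within variable stems
#'
#' As [count_single_changes], but tallies are over the stem's column
#' pairs (i, j): the state of a sequence is the ordered 5'->3' duplet
#' (char at i, char at j).  The empty duplet `--` is excluded from the
#' state space and never tallied.  Compensatory double changes appear
#' as e.g. (GC) vs (AU); single-side changes as (GC) vs (GU).
#'
#' @inheritParams count_single_changes
#' @return a `substitution_counts` object (`mode = "pair"`).
#' @export
count_pair_changes <- function(aln, variable, stems, tree,
                               mode = c("extant_extant",
                                        "ancestral_extant"),
                               anc = NULL) {
  mode <- match.arg(mode)
  states <- .pair_states()
  sc <- .new_counts(states, "pair", mode)
  if (!nrow(variable)) {
    warning("no variable stems: counts are empty")
    return(sc)
  }
  if (mode == "ancestral_extant" && is.null(anc))
    stop("ancestral_extant mode requires an ancestral reconstruction")
  labs <- vapply(stems$stems, `[[`, character(1), "label")
  counts <- sc$counts
  duplet <- function(ch, i, j) {
    x <- ch[i]; y <- ch[j]
    if (!.countable(x) || !.countable(y)) return(NA_character_)
    d <- paste0(x, y)
    if (d == "--") NA_character_ else d
  }
  for (r in seq_len(nrow(variable))) {
    stem <- stems$stems[[match(variable$stem[r], labs)]]
    clade <- variable$node[r]
    members <- .clade_members(stem, clade, aln, tree)
    if (mode == "extant_extant") {
      if (length(members) < 2) next
      seqs <- lapply(members, function(m) .chars(aln$rows[[m]]))
      for (a in seq_len(length(members) - 1))
        for (b in (a + 1):length(members))
          for (p in seq_len(nrow(stem$pairs))) {
            d1 <- duplet(seqs[[a]], stem$pairs[p, 1], stem$pairs[p, 2])
            d2 <- duplet(seqs[[b]], stem$pairs[p, 1], stem$pairs[p, 2])
            if (!is.na(d1) && !is.na(d2))
              counts <- .tally_unordered(counts, d1, d2, states)
          }
    } else {
      anc_ch <- .chars(anc$sequences[[as.character(clade)]])
      seqs <- lapply(members, function(m) .chars(aln$rows[[m]]))
      for (b in seq_along(members))
        for (p in seq_len(nrow(stem$pairs))) {
          i <- stem$pairs[p, 1]; j <- stem$pairs[p, 2]
          if (anc_ch[i] == "?" || anc_ch[j] == "?") next
          d1 <- duplet(anc_ch, i, j)
          d2 <- duplet(seqs[[b]], i, j)
          if (!is.na(d1) && !is.na(d2))
            counts[d1, d2] <- counts[d1, d2] + 1L
        }
    }
  }
  sc$counts <- counts
  sc$total <- sum(counts)
  sc
}

#' Log-odds (observed/expected) transform of substitution counts
#'
#' Each cell becomes `log2(f_obs / f_expected)` in bits, where `f_obs`
#' is the cell count normalized by the total number of events and the
#' expectation is the product of the marginal frequencies of the two
#' states involved, computed from the count matrix itself.  For
#' fold-symmetric (extant/extant) counts the marginal of a state is its
#' involvement frequency (each tally involves two states) and the
#' expected frequency of an unordered off-diagonal cell uses both
#' orderings (`2 f_i f_j`); directional (ancestral/extant) counts use
#' row and column marginals.  Cells with zero observed count are
#' undefined and reported `NA` (never -Inf).  An optional pseudocount
#' is added to every structural (tallyable) cell before normalization.
#'
#' @param sc a `substitution_counts` object.
#' @param pseudocount added to every cell (default 0).
#' @return object of class `log_odds_matrix`: `matrix` (log2 scores,
#'   `NA` where undefined; for fold-symmetric input only the canonical
#'   lower triangle is populated), `frequencies`, `marginals`, plus the
#'   source `mode`/`comparison`/`total`.
#' @export
log_odds_transform <- function(sc, pseudocount = 0) {
  stopifnot(inherits(sc, "substitution_counts"))
  states <- sc$states
  n <- length(states)
  counts <- sc$counts + 0.0
  if (sc$comparison == "extant_extant") {
    lower <- lower.tri(counts, diag = TRUE)
    if (pseudocount > 0) counts[lower] <- counts[lower] + pseudocount
    total <- sum(counts[lower])
    if (total <= 0) stop("empty counts: no events to transform")
    f <- counts / total
    # involvement marginal: each unordered tally involves two states
    marg <- vapply(seq_len(n), function(i) {
      (2 * counts[i, i] +
         sum(counts[i, seq_len(n) < i]) +
         sum(counts[seq_len(n) > i, i])) / (2 * total)
    }, numeric(1))
    names(marg) <- states
    A <- matrix(NA_real_, n, n, dimnames = dimnames(counts))
    for (i in seq_len(n)) for (j in seq_len(i)) {
      if (counts[i, j] <= 0) next
      e <- if (i == j) marg[i]^2 else 2 * marg[i] * marg[j]
      A[i, j] <- log2(f[i, j] / e)
    }
  } else {
    if (pseudocount > 0) counts <- counts + pseudocount
    total <- sum(counts)
    if (total <= 0) stop("empty counts: no events to transform")
    f <- counts / total
    rmarg <- rowSums(f); cmarg <- colSums(f)
    A <- matrix(NA_real_, n, n, dimnames = dimnames(counts))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (counts[i, j] <= 0) next
      A[i, j] <- log2(f[i, j] / (rmarg[i] * cmarg[j]))
    }
    marg <- list(row = rmarg, col = cmarg)
  }
  structure(list(matrix = A, frequencies = f, marginals = marg,
                 mode = sc$mode, comparison = sc$comparison,
                 total = total),
            class = "log_odds_matrix")
}

#' @export
print.log_odds_matrix <- function(x, ...) {
  cat("Log-odds matrix (", x$mode, ", ", x$comparison, "), ",
      x$total, " events\n", sep = "")
  print(round(x$matrix, 2))
  invisible(x)
}
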