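# leaves (tip ids) under each node, as a list over all node ids
.leaves_under <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  kids <- .children_list(tree)
  post <- .postorder_internal(tree)
  lv <- vector("list", n_node)
  for (l in seq_len(ntip)) lv[[l]] <- l
  for (v in post) lv[[v]] <- sort(unlist(lv[kids[[v]]]))
  lv
}

#' Find variable stems and the clades where they vary
#'
#' For every stem, locates the smallest clades across whose branches
#' the realized stem lengths differ: an internal node qualifies when
#' at least two of its child subtrees disagree in their modal realized
#' length (ties broken toward the larger length, children with no
#' known cells skipped).  A clade that merely contains variation deep
#' inside one child is therefore not reported again at the ancestor;
#' each independent point of between-branch divergence yields one
#' record.  Cells with unknown length (non-sequenced region) are
#' ignored.  This is an algorithmic surrogate for a manual survey of
#' stem variability on the tree.
#'
#' @param table a `stem_length_table`.
#' @param tree rooted `phylo` over the same species.
#' @return data frame with columns `stem` (label) and `node` (internal
#'   node id of the clade).
#' @export
find_variable_stems <- function(table, tree) {
  stopifnot(inherits(table, "stem_length_table"), inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, rownames(table$lengths))
  if (length(miss))
    stop("species in tree but not in table: ", paste(miss, collapse = ", "))
  ntip <- ape::Ntip(tree)
  kids <- .children_list(tree)
  post <- .postorder_internal(tree)
  lv <- .leaves_under(tree)
  labs <- colnames(table$lengths)
  out_stem <- character(0); out_node <- integer(0)
  for (s in labs) {
    vals <- table$lengths[tree$tip.label, s]
    valset <- vector("list", ntip + tree$Nnode)
    for (l in seq_len(ntip))
      valset[[l]] <- if (is.na(vals[l])) integer(0) else vals[l]
    modal_of <- function(vals) {
      if (!length(vals)) return(NA_integer_)
      tab <- table(vals)
      max(as.integer(names(tab)[tab == max(tab)]))
    }
    loci <- integer(0)
    for (v in post) {
      valset[[v]] <- unlist(valset[kids[[v]]])
      cm <- vapply(kids[[v]], function(c) modal_of(valset[[c]]),
                   integer(1))
      cm <- cm[!is.na(cm)]
      if (length(cm) >= 2 && length(unique(cm)) > 1)
        loci <- c(loci, v)
    }
    out_stem <- c(out_stem, rep(s, length(loci)))
    out_node <- c(out_node, loci)
  }
  data.frame(stem = out_stem, node = out_node, stringsAsFactors = FALSE)
}

#' Classify a stem gain/loss event at a clade
#'
#' Distinguishes whole-stem insertion/deletion (diagnosed from the
#' absence/presence of sequence at the ancestral node) from stem
#' gain/loss driven by base substitutions and indels that create or
#' disrupt pairing.  With `g_anc` the gap fraction of the reconstructed
#' ancestral sequence over the stem's columns and `g_ext` the same for
#' each extant clade member:
#' \itemize{
#'  \item `whole_stem_insertion` when `g_anc >= theta_gap` (no sequence
#'    at the ancestor) and some descendant realizes the stem;
#'  \item `whole_stem_deletion` when the ancestor has sequence and a
#'    positive realized length but some descendant's region is gapped
#'    out (`g_ext >= theta_gap`);
#'  \item `pairing_change_substitution_indel` otherwise.
#' }
#' Species with `~` in the region are excluded.  Ancestral `?` columns
#' are resolved toward "sequence present": only definite gaps count in
#' `g_anc`, and a pair whose ambiguous ends can still form a canonical
#' pair within their minimal state sets counts as potentially paired
#' for the deletion test.  At deep nodes where insertion and deletion
#' are equally parsimonious the call therefore stays in the whole-stem
#' class (the dichotomy event-frequency tables use) while the
#' direction inherits the reconstruction's uncertainty.
#'
#' @param stem one stem from a `stem_set`.
#' @param clade internal node id.
#' @param aln the [structural_alignment].
#' @param anc an `ancestral_sequences` reconstruction on the same tree.
#' @param theta_gap gap fraction treated as "no sequence present"
#'   (default 0.9).
#' @param count_bulges passed to [realized_stem_length].
#' @return object of class `event_record`: a list with `stem`, `node`,
#'   `event_class`, `direction` (`gain`/`loss`), and `evidence`
#'   (ancestral gap fraction, ancestral realized length, descendant
#'   realized lengths and gap fractions, species used and excluded).
#' @export
classify_stem_event <- function(stem, clade, aln, anc, theta_gap = 0.9,
                                count_bulges = FALSE) {
  tree <- anc$tree
  lv <- .leaves_under(tree)
  if (clade <= ape::Ntip(tree) || clade > ape::Ntip(tree) + tree$Nnode)
    stop("clade must be an internal node id")
  members <- tree$tip.label[lv[[clade]]]
  cols <- sort(c(stem$pairs))
  anc_seq <- .chars(anc$sequences[[as.character(clade)]])
  known_members <- members[vapply(members, function(m)
    !any(.chars(aln$rows[[m]])[cols] == "~"), logical(1))]
  excluded <- setdiff(members, known_members)
  if (!length(known_members))
    stop("no call possible: all clade members unknown ('~') in the ",
         "region of stem ", stem$label)
  anc_ch <- anc_seq[cols]
  # g_anc counts only definite ancestral gaps; an ambiguous '?' column
  # is resolved toward "sequence present" (the same conservative
  # present-leaning tie-break used for modal lengths), so only an
  # unambiguously empty ancestral region reads as absence
  g_anc <- mean(anc_ch == "-")
  anc_row <- paste(ifelse(anc_seq == "?", "N", anc_seq), collapse = "")
  anc_len <- realized_stem_length(anc_row, stem, count_bulges)
  # upper-bound realized length: a pair whose ambiguous ends can be
  # resolved (within their minimal state sets) to a canonical pair may
  # have been paired in the ancestor
  sets <- anc$state_sets[[as.character(clade)]]
  base_set <- function(col) {
    ch <- anc_seq[col]
    if (ch %in% .BASES) return(ch)
    if (ch == "?") return(intersect(sets[[col]], .BASES))
    character(0)
  }
  anc_len_max <- sum(vapply(seq_len(nrow(stem$pairs)), function(p) {
    xs <- base_set(stem$pairs[p, 1]); ys <- base_set(stem$pairs[p, 2])
    length(xs) > 0 && length(ys) > 0 &&
      any(outer(xs, ys, paste0) %in% .CANONICAL)
  }, logical(1)))
  ext_len <- vapply(known_members, function(m)
    realized_stem_length(aln$rows[[m]], stem, count_bulges), integer(1))
  g_ext <- vapply(known_members, function(m)
    mean(.chars(aln$rows[[m]])[cols] == "-"), numeric(1))
  if (g_anc >= theta_gap && any(ext_len > 0)) {
    cls <- "whole_stem_insertion"; dir <- "gain"
  } else if (g_anc < theta_gap && anc_len_max > 0 &&
             any(g_ext >= theta_gap)) {
    cls <- "whole_stem_deletion"; dir <- "loss"
  } else {
    cls <- "pairing_change_substitution_indel"
    dir <- if (mean(ext_len) >= anc_len) "gain" else "loss"
  }
  structure(list(stem = stem$label, node = clade, event_class = cls,
                 direction = dir,
                 evidence = list(ancestral_gap_fraction = g_anc,
                                 ancestral_realized_length = anc_len,
                                 ancestral_realized_length_max = anc_len_max,
                                 descendant_lengths = ext_len,
                                 descendant_gap_fractions = g_ext,
                                 species = known_members,
                                 excluded_unknown = excluded,
                                 theta_gap = theta_gap)),
            class = "event_record")
}

#' @export
print.event_record <- function(x, ...) {
  cat(sprintf("Event: stem %s at node %d -> %s (%s)\n", x$stem, x$node,
              x$event_class, x$direction))
  invisible(x)
}

#' Classify all variable stems of one family
#'
#' Runs [find_variable_stems] then [classify_stem_event] on each
#' (stem, clade); clades where no call is possible are dropped with a
#' warning.
#'
#' @inheritParams classify_stem_event
#' @param table a `stem_length_table` for the family.
#' @param stems the `stem_set`.
#' @param tree rooted `phylo`.
#' @return list of `event_record`s.
#' @export
classify_family_events <- function(table, stems, tree, aln, anc,
                                   theta_gap = 0.9, count_bulges = FALSE) {
  var <- find_variable_stems(table, tree)
  labs <- vapply(stems$stems, `[[`, character(1), "label")
  events <- list()
  for (r in seq_len(nrow(var))) {
    stem <- stems$stems[[match(var$stem[r], labs)]]
    ev <- tryCatch(
      classify_stem_event(stem, var$node[r], aln, anc, theta_gap,
                          count_bulges),
      error = function(e) {
        warning("no call for stem ", var$stem[r], " at node ",
                var$node[r], ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(ev)) events[[length(events) + 1]] <- ev
  }
  events
}

#' Tabulate family-level event frequencies
#'
#' Pools events into the two top-level classes (whole-stem
#' insertion/deletion vs pairing change by substitutions/indels) and
#' reports per-family percentages and raw counts.
#'
#' @param events list of `event_record`s (possibly from several
#'   families concatenated).
#' @param families character vector of family labels parallel to
#'   `events` (recycled if length 1).
#' @return object of class `event_frequency_table`: data frame with
#'   columns `family`, `whole_stem_pct`, `substitution_indel_pct`,
#'   `whole_stem_n`, `substitution_indel_n`.
#' @export
tabulate_event_frequencies <- function(events, families) {
  if (!length(events)) stop("no events to tabulate")
  families <- rep_len(families, length(events))
  cls <- vapply(events, `[[`, character(1), "event_class")
  whole <- cls %in% c("whole_stem_insertion", "whole_stem_deletion")
  fams <- unique(families)
  rows <- lapply(fams, function(f) {
    sel <- families == f
    n_w <- sum(whole & sel); n_s <- sum(!whole & sel)
    n <- n_w + n_s
    if (n == 0) {
      warning("family '", f, "' has no events; excluded")
      return(NULL)
    }
    data.frame(family = f, whole_stem_pct = 100 * n_w / n,
               substitution_indel_pct = 100 * n_s / n,
               whole_stem_n = n_w, substitution_indel_n = n_s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("event_frequency_table", class(out))
  out
}

#' Chi-square comparison of event rates across families
#'
#' Pearson chi-square test on an r x 2 table of event counts
#' (whole-stem vs substitution/indel, one row per family), df =
#' (r - 1).  Counts, not percentages, are used.
#'
#' @param counts matrix or data frame with r rows and 2 columns of
#'   non-negative counts.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_event_rates <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) != 2) stop("counts must have exactly 2 columns")
  storage.mode(m) <- "double"
  exp_m <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(exp_m <= 0))
    stop("degenerate table: zero expected count in some cell")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Write an event list as JSON
#' @param events list of `event_record`s.
#' @param path output path.
#' @export
write_events_json <- function(events, path) {
  payload <- lapply(events, function(e) {
    ev <- unclass(e)
    ev$evidence$descendant_lengths <-
      as.list(ev$evidence$descendant_lengths)
    ev$evidence$descendant_gap_fractions <-
      as.list(ev$evidence$descendant_gap_fractions)
    ev
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
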