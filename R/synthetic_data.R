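# Simulator of structured-RNA evolution along a tree.
#
# Sequences are tracked as maps from immutable "site" ids to characters;
# a whole-stem insertion creates new site ids that exist only in the
# subtree where it happened, so the final leaf set is a true multiple
# alignment by construction (other lineages read '-' at those sites).

.WC <- c(A = "U", U = "A", G = "C", C = "G")

#' Configuration for the RNA-family simulator
#'
#' Rates are per unit branch length: whole-stem rates per stem (or per
#' branch for insertions), pair substitution and in-stem indel rates
#' per base pair, loop substitution rate per loop site.  A pair
#' substitution is compensated (the partner strand changes to restore
#' Watson-Crick pairing) with probability `compensation_probability`.
#'
#' @param seed integer seed; the same seed reproduces the family
#'   bit-for-bit.
#' @param whole_stem_insertion_rate expected new hairpins per branch
#'   per unit length.
#' @param whole_stem_deletion_rate per stem per unit length.
#' @param pair_substitution_rate per base pair per unit length.
#' @param compensation_probability chance a stem substitution is
#'   matched by its partner.
#' @param in_stem_indel_rate single-base deletions inside stems, per
#'   pair per unit length.
#' @param loop_substitution_rate per loop site per unit length.
#' @param n_stems,stem_length_range,loop_length_range root geometry.
#' @param pseudoknot add one crossing stem to the root structure.
#' @param mask_prob per-leaf probability of censoring a terminal
#'   region with `~` (non-sequenced).
#' @param mask_frac_range fraction of columns censored when masking.
#' @return an `evolution_config` list.
#' @export
evolution_config <- function(seed = 1,
                             whole_stem_insertion_rate = 0.02,
                             whole_stem_deletion_rate = 0.02,
                             pair_substitution_rate = 0.1,
                             compensation_probability = 0.8,
                             in_stem_indel_rate = 0.02,
                             loop_substitution_rate = 0.2,
                             n_stems = 4,
                             stem_length_range = c(5, 8),
                             loop_length_range = c(4, 7),
                             pseudoknot = FALSE,
                             mask_prob = 0,
                             mask_frac_range = c(0.05, 0.2)) {
  cfg <- list(seed = seed,
              whole_stem_insertion_rate = whole_stem_insertion_rate,
              whole_stem_deletion_rate = whole_stem_deletion_rate,
              pair_substitution_rate = pair_substitution_rate,
              compensation_probability = compensation_probability,
              in_stem_indel_rate = in_stem_indel_rate,
              loop_substitution_rate = loop_substitution_rate,
              n_stems = n_stems,
              stem_length_range = stem_length_range,
              loop_length_range = loop_length_range,
              pseudoknot = pseudoknot,
              mask_prob = mask_prob,
              mask_frac_range = mask_frac_range)
  rates <- cfg[grep("_rate$|_prob", names(cfg))]
  if (any(unlist(rates) < 0)) stop("rates must be non-negative")
  if (compensation_probability < 0 || compensation_probability > 1)
    stop("compensation_probability must be in [0, 1]")
  structure(cfg, class = "evolution_config")
}

#' Generate a root sequence and structure
#'
#' Builds a sequence of `n_stems` hairpins (stem + terminal loop)
#' separated by single-stranded linkers, with every stem realized as
#' canonical Watson-Crick pairs.  With `pseudoknot = TRUE` one extra
#' stem pairs the first hairpin's loop with the 3' tail, producing
#' crossing arcs.  Seeded by `config$seed`; bit-reproducible.
#'
#' @param config an [evolution_config].
#' @return list with `chars` (character vector), `stems` (list of
#'   2-column site-index matrices, outermost pair first), `struct`
#'   (the structure string).
#' @export
generate_root <- function(config) {
  set.seed(config$seed)
  chars <- character(0)
  stems <- list()
  rand_bases <- function(n) sample(.BASES, n, replace = TRUE)
  lo <- function(r) sample(seq(r[1], r[2]), 1)
  # leading linker
  chars <- c(chars, rand_bases(lo(config$loop_length_range)))
  for (s in seq_len(config$n_stems)) {
    m <- lo(config$stem_length_range)
    lp <- if (config$pseudoknot && s == 1)
      max(6, lo(config$loop_length_range)) else lo(config$loop_length_range)
    left <- rand_bases(m)
    loop <- rand_bases(lp)
    right <- rev(unname(.WC[left]))
    i0 <- length(chars)
    chars <- c(chars, left, loop, right)
    pairs <- cbind(i0 + seq_len(m), i0 + m + lp + m + 1 - seq_len(m))
    stems[[length(stems) + 1]] <- pairs
    chars <- c(chars, rand_bases(lo(config$loop_length_range)))
  }
  if (config$pseudoknot) {
    # pair part of hairpin 1's loop with the 3' tail
    p1 <- stems[[1]]
    m1 <- nrow(p1)
    loop_start <- p1[m1, 1] + 1; loop_end <- p1[m1, 2] - 1
    k <- 3
    left <- (loop_start + 1):(loop_start + k)
    tail_bases <- rand_bases(2)
    i0 <- length(chars)
    chars <- c(chars, tail_bases,
               rev(unname(.WC[chars[left]])), rand_bases(2))
    right <- (i0 + 3):(i0 + 2 + k)
    pairs <- cbind(left, rev(right))
    stems[[length(stems) + 1]] <- pairs
  }
  st <- .structure_string(length(chars), stems)
  list(chars = chars, stems = stems, struct = st)
}

# build a structure string from stem pair matrices, assigning bracket
# classes by greedy coloring of the arc-crossing graph
.structure_string <- function(L, stems) {
  n <- length(stems)
  cls <- integer(n)
  if (n) {
    cross <- matrix(FALSE, n, n)
    if (n > 1)
      for (a in seq_len(n - 1)) for (b in (a + 1):n)
        cross[a, b] <- cross[b, a] <- .stems_cross(stems[[a]], stems[[b]])
    for (a in seq_len(n)) {
      used <- cls[cross[a, ] & cls > 0]
      cls[a] <- setdiff(seq_len(n + 1), used)[1]
    }
  }
  opens <- c(.OPEN_BRACKETS, LETTERS)
  closes <- c(.CLOSE_BRACKETS, letters)
  ch <- rep(".", L)
  for (a in seq_along(stems)) {
    p <- stems[[a]]
    ch[p[, 1]] <- opens[cls[a]]
    ch[p[, 2]] <- closes[cls[a]]
  }
  paste(ch, collapse = "")
}

#' Evolve a root RNA along a tree
#'
#' Events are drawn per branch as Poisson counts with the configured
#' rates times the branch length (unit lengths if the tree has none).
#' Whole-stem deletions gap all of a stem's paired sites in that
#' lineage (at most one whole-stem event per stem per branch); a
#' whole-stem insertion adds a new canonical hairpin at a random
#' interior position of a single-stranded region, creating fresh
#' alignment columns that are gap-filled in every other lineage.  Pair
#' substitutions respect `compensation_probability`; in-stem indels
#' delete one strand's base of a pair.  All true ancestral sequences
#' and whole-stem events are logged.
#'
#' The random stream is seeded with `config$seed` (root generation)
#' and continues into the branch simulation, so a config fully
#' determines the family.
#'
#' @param tree rooted `phylo` (branch lengths used if present).
#' @param root output of [generate_root] (built from `config` if
#'   `NULL`).
#' @param config an [evolution_config].
#' @return object of class `simulated_family`: `alignment`
#'   (a [structural_alignment] with the evolved consensus structure),
#'   `tree`, `ancestors` (named character vector of true sequences per
#'   internal node id), `events` (list: `event_class`, `stem` label,
#'   `node` = child node of the branch, `leaves` affected tip labels),
#'   `stems` (the `stem_set` of the final consensus), `config`.
#' @export
evolve <- function(tree, root = NULL, config = evolution_config()) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(root)) root <- generate_root(config) else set.seed(config$seed)
  # continue the stream deterministically past root generation
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  kids <- .children_list(tree)
  root_id <- .root_node(tree)
  bl <- tree$edge.length
  if (is.null(bl)) bl <- rep(1, nrow(tree$edge))
  L0 <- length(root$chars)
  reg <- new.env()
  reg$order <- seq_len(L0)
  reg$next_id <- L0 + 1L
  reg$stems <- lapply(root$stems, function(p)
    list(pairs = p))               # site-id pair matrices
  node_chars <- vector("list", n_node)
  rc <- root$chars; names(rc) <- as.character(seq_len(L0))
  node_chars[[root_id]] <- rc
  events <- list()
  lv <- .leaves_under(tree)

  getch <- function(map, ids) {
    out <- unname(map[as.character(ids)])
    out[is.na(out)] <- "-"
    out
  }
  live_pairs <- function(map) {
    # matrix of (stem index, pair row) for pairs with both sides non-gap
    out <- NULL
    for (si in seq_along(reg$stems)) {
      p <- reg$stems[[si]]$pairs
      a <- getch(map, p[, 1]); b <- getch(map, p[, 2])
      ok <- a %in% .BASES & b %in% .BASES
      if (any(ok)) out <- rbind(out, cbind(si, which(ok)))
    }
    out
  }
  stem_present <- function(map, si) {
    p <- reg$stems[[si]]$pairs
    a <- getch(map, p[, 1]); b <- getch(map, p[, 2])
    any(paste0(a, b) %in% .CANONICAL)
  }
  loop_runs <- function() {
    in_stem <- integer(0)
    for (s in reg$stems) in_stem <- c(in_stem, c(s$pairs))
    pos <- which(!reg$order %in% in_stem)
    .runs(pos)  # positions (not site ids) in the current global order
  }

  # preorder edge traversal: each parent is visited before its children
  tr_pre <- ape::reorder.phylo(tree, "cladewise")
  edges <- tr_pre$edge
  bl <- tr_pre$edge.length
  if (is.null(bl)) bl <- rep(1, nrow(edges))
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]; len <- bl[e]
    map <- node_chars[[parent]]
    # -- whole-stem deletions (existing stems present in the parent) --
    for (si in seq_along(reg$stems)) {
      if (!stem_present(map, si)) next
      if (rpois(1, config$whole_stem_deletion_rate * len) >= 1) {
        p <- reg$stems[[si]]$pairs
        # the whole block goes: paired sites plus enclosed sites that
        # belong to no other stem (the hairpin loop)
        other <- unlist(lapply(reg$stems[-si], function(s) c(s$pairs)))
        span <- which(reg$order %in% c(p))
        encl <- reg$order[seq(min(span), max(span))]
        del <- setdiff(encl, other)
        del <- del[as.character(del) %in% names(map)]
        map[as.character(del)] <- "-"
        events[[length(events) + 1]] <- list(
          event_class = "whole_stem_deletion", stem_index = si,
          node = child, leaves = tree$tip.label[lv[[child]]])
      }
    }
    # -- whole-stem insertions (new hairpin, new alignment columns) --
    n_ins <- rpois(1, config$whole_stem_insertion_rate * len)
    for (k in seq_len(n_ins)) {
      runs <- loop_runs()
      runs <- runs[runs[, "end"] > runs[, "start"], , drop = FALSE]
      if (!nrow(runs)) break
      r <- runs[sample.int(nrow(runs), 1), ]
      at <- if (r["end"] - r["start"] >= 2)
        sample(seq(r["start"], r["end"] - 1), 1) else r["start"]
      m <- sample(seq(config$stem_length_range[1],
                      config$stem_length_range[2]), 1)
      lp <- sample(seq(config$loop_length_range[1],
                       config$loop_length_range[2]), 1)
      left <- sample(.BASES, m, replace = TRUE)
      loop <- sample(.BASES, lp, replace = TRUE)
      newch <- c(left, loop, rev(unname(.WC[left])))
      ids <- seq(reg$next_id, length.out = length(newch))
      reg$next_id <- reg$next_id + length(newch)
      reg$order <- append(reg$order, ids, after = at)
      pairs <- cbind(ids[seq_len(m)],
                     ids[m + lp + m + 1 - seq_len(m)])
      reg$stems[[length(reg$stems) + 1]] <- list(pairs = pairs)
      add <- newch; names(add) <- as.character(ids)
      map <- c(map, add)
      events[[length(events) + 1]] <- list(
        event_class = "whole_stem_insertion",
        stem_index = length(reg$stems), node = child,
        n_new_columns = length(newch),
        leaves = tree$tip.label[lv[[child]]])
    }
    # -- pair substitutions --
    lp_mat <- live_pairs(map)
    n_lp <- if (is.null(lp_mat)) 0L else nrow(lp_mat)
    n_sub <- if (n_lp) rpois(1, config$pair_substitution_rate * len * n_lp)
             else 0L
    for (k in seq_len(n_sub)) {
      lp_mat <- live_pairs(map)
      if (is.null(lp_mat)) break
      row <- lp_mat[sample.int(nrow(lp_mat), 1), ]
      p <- reg$stems[[row[1]]]$pairs[row[2], ]
      side <- sample(1:2, 1)
      old <- map[as.character(p[side])]
      new <- sample(setdiff(.BASES, old), 1)
      map[as.character(p[side])] <- new
      if (runif(1) < config$compensation_probability)
        map[as.character(p[3 - side])] <- unname(.WC[new])
    }
    # -- in-stem single-base indels --
    n_ind <- if (n_lp) rpois(1, config$in_stem_indel_rate * len * n_lp)
             else 0L
    for (k in seq_len(n_ind)) {
      lp_mat <- live_pairs(map)
      if (is.null(lp_mat)) break
      row <- lp_mat[sample.int(nrow(lp_mat), 1), ]
      p <- reg$stems[[row[1]]]$pairs[row[2], ]
      map[as.character(p[sample(1:2, 1)])] <- "-"
    }
    # -- loop substitutions --
    in_stem <- unlist(lapply(reg$stems, function(s) c(s$pairs)))
    loop_ids <- setdiff(as.integer(names(map)), in_stem)
    loop_ids <- loop_ids[map[as.character(loop_ids)] %in% .BASES]
    n_ls <- if (length(loop_ids))
      rpois(1, config$loop_substitution_rate * len * length(loop_ids))
      else 0L
    for (k in seq_len(n_ls)) {
      id <- loop_ids[sample.int(length(loop_ids), 1)]
      old <- map[as.character(id)]
      map[as.character(id)] <- sample(setdiff(.BASES, old), 1)
    }
    node_chars[[child]] <- map
  }

  # assemble alignment over the final global column order
  L <- length(reg$order)
  as_string <- function(map) paste(getch(map, reg$order), collapse = "")
  rows <- vapply(seq_len(ntip), function(l) as_string(node_chars[[l]]),
                 character(1))
  names(rows) <- tree$tip.label
  # optional '~' censoring of terminal regions
  if (config$mask_prob > 0) {
    for (l in seq_len(ntip)) {
      if (runif(1) >= config$mask_prob) next
      frac <- runif(1, config$mask_frac_range[1], config$mask_frac_range[2])
      n <- max(1L, floor(frac * L))
      ch <- .chars(rows[l])
      if (runif(1) < 0.5) ch[seq_len(n)] <- "~"
      else ch[(L - n + 1):L] <- "~"
      rows[l] <- paste(ch, collapse = "")
    }
  }
  stem_cols <- lapply(reg$stems, function(s) {
    p <- s$pairs
    cbind(match(p[, 1], reg$order), match(p[, 2], reg$order))
  })
  struct <- .structure_string(L, stem_cols)
  aln <- structural_alignment(tree$tip.label, rows, struct,
                              family_label = "simulated")
  stems <- extract_stems(struct)
  # map simulator stem indices to extracted stem labels by column sets
  key <- vapply(stem_cols, function(p)
    paste(sort(c(p)), collapse = ","), character(1))
  ext_key <- vapply(stems$stems, function(s)
    paste(sort(c(s$pairs)), collapse = ","), character(1))
  lab_of <- vapply(stems$stems, `[[`, character(1), "label")
  idx2lab <- lab_of[match(key, ext_key)]
  events <- lapply(events, function(ev) {
    ev$stem <- idx2lab[ev$stem_index]
    ev
  })
  internal <- (ntip + 1L):n_node
  ancestors <- vapply(internal, function(v) as_string(node_chars[[v]]),
                      character(1))
  names(ancestors) <- as.character(internal)
  structure(list(alignment = aln, tree = tree, ancestors = ancestors,
                 events = events, stems = stems, config = config),
            class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  cat("Simulated RNA family:", length(x$alignment$ids), "leaves,",
      x$alignment$L, "columns,", length(x$stems$stems), "stems,",
      length(x$events), "whole-stem events\n")
  invisible(x)
}

#' Simulate a family on a random tree
#'
#' Convenience wrapper: draws a random rooted tree with `n_leaves`
#' tips (uniform branch lengths) seeded by `config$seed`, then runs
#' [evolve].
#'
#' @param n_leaves number of tips.
#' @param config an [evolution_config].
#' @return a `simulated_family`.
#' @export
simulate_family <- function(n_leaves = 12, config = evolution_config()) {
  set.seed(config$seed)
  tree <- ape::rtree(n_leaves)
  evolve(tree, root = NULL, config = config)
}

#' Compare inferred events and ancestors with simulator truth
#'
#' A planted whole-stem event is recovered when an inferred event has
#' the same stem label, a whole-stem class, and a clade overlapping
#' the affected leaves; insertion and deletion are pooled for the
#' match, as in event-frequency tables, because at nodes where the two
#' directions are equally parsimonious no method can tell them apart.
#' Precision is computed over the inferred whole-stem calls.
#' Ancestral accuracy is the fraction of reconstructed (non-`?`)
#' positions matching the true ancestral sequences, over all internal
#' nodes.
#'
#' @param sim a `simulated_family`.
#' @param inferred_events list of `event_record`s from
#'   [classify_family_events].
#' @param inferred_anc an `ancestral_sequences` object on `sim$tree`.
#' @return list with `recall`, `precision`, `ancestral_accuracy`,
#'   `n_true`, `n_inferred_whole_stem`.
#' @export
recovery_report <- function(sim, inferred_events, inferred_anc) {
  stopifnot(inherits(sim, "simulated_family"))
  lv <- .leaves_under(sim$tree)
  whole <- c("whole_stem_insertion", "whole_stem_deletion")
  inf <- Filter(function(e) e$event_class %in% whole, inferred_events)
  inf_leaves <- lapply(inf, function(e) sim$tree$tip.label[lv[[e$node]]])
  matches_truth <- function(ev) {
    any(vapply(seq_along(inf), function(k)
      inf[[k]]$stem == ev$stem &&
        length(intersect(inf_leaves[[k]], ev$leaves)) > 0,
      logical(1)))
  }
  truth <- Filter(function(e) e$event_class %in% whole, sim$events)
  recall <- if (length(truth))
    mean(vapply(truth, matches_truth, logical(1))) else NA_real_
  matched_inf <- vapply(seq_along(inf), function(k) {
    any(vapply(truth, function(ev)
      inf[[k]]$stem == ev$stem &&
        length(intersect(inf_leaves[[k]], ev$leaves)) > 0,
      logical(1)))
  }, logical(1))
  precision <- if (length(inf)) mean(matched_inf) else NA_real_
  # ancestral accuracy over reconstructed positions
  tot <- 0L; hit <- 0L
  for (id in names(sim$ancestors)) {
    truth_ch <- .chars(sim$ancestors[[id]])
    inf_ch <- .chars(inferred_anc$sequences[[id]])
    use <- inf_ch != "?"
    tot <- tot + sum(use)
    hit <- hit + sum(inf_ch[use] == truth_ch[use])
  }
  list(recall = recall, precision = precision,
       ancestral_accuracy = if (tot) hit / tot else NA_real_,
       n_true = length(truth), n_inferred_whole_stem = length(inf))
}
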