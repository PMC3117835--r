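#' Full stem-evolution analysis of one RNA family
#'
#' Runs the whole analysis chain on a structural alignment and a
#' rooted reference tree: stem annotation and stem-length table,
#' squared-change parsimony mapping of stem lengths, presence and
#' ancestral-sequence reconstruction, variable-stem detection and
#' event classification, the four substitution matrices (single
#' nucleotide and base pair, extant/extant and ancestral/extant) with
#' their log-odds transforms, and k-means + PCA of the stem-length
#' profiles.  Species missing from either input are pruned with a
#' warning (exact name match after whitespace/underscore
#' normalization).
#'
#' @param aln a [structural_alignment].
#' @param tree a rooted `phylo` tree.
#' @param theta_gap gap fraction treated as "no sequence present" when
#'   classifying events (default 0.9).
#' @param k number of k-means clusters (default 3).
#' @param seed seed for clustering restarts.
#' @param count_bulges include bulge columns in realized stem lengths.
#' @param exclude_partial drop partial (`~`-containing) species from
#'   the PCA.
#' @param pseudocount pseudocount for the log-odds transforms.
#' @return an object of class `stem_evolution` with components
#'   `alignment`, `tree`, `stems`, `table`, `continuous` (per-stem
#'   squared-change reconstructions), `presence` (per-stem presence
#'   reconstructions), `ancestral`, `variable`, `events`,
#'   `frequencies`, `matrices` (list of 4 `substitution_counts`),
#'   `log_odds` (their transforms), `pca`, `clusters`, `wcss_profile`,
#'   and `params`.
#' @export
stem_evolution <- function(aln, tree, theta_gap = 0.9, k = 3, seed = 1,
                           count_bulges = FALSE, exclude_partial = TRUE,
                           pseudocount = 0) {
  stopifnot(inherits(aln, "structural_alignment"), inherits(tree, "phylo"))
  norm <- function(x) gsub("[ _]+", "_", trimws(x))
  aln_ids <- setNames(aln$ids, norm(aln$ids))
  tree$tip.label <- norm(tree$tip.label)
  common <- intersect(norm(aln$ids), tree$tip.label)
  if (!length(common))
    stop("no species shared between alignment (",
         paste(head(aln$ids, 3), collapse = ", "), " ...) and tree (",
         paste(head(tree$tip.label, 3), collapse = ", "), " ...)")
  if (length(common) < length(tree$tip.label)) {
    warning("pruning ", length(tree$tip.label) - length(common),
            " tree leaves absent from the alignment")
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, common))
  }
  if (length(common) < length(aln$ids))
    warning("ignoring ", length(aln$ids) - length(common),
            " alignment sequences absent from the tree")
  sub_rows <- unname(aln$rows[aln_ids[common]])
  aln <- structural_alignment(common, sub_rows, aln$consensus_structure,
                              aln$family_label)
  stems <- extract_stems(aln$consensus_structure)
  table <- build_stem_length_table(aln, stems, count_bulges)
  labs <- colnames(table$lengths)
  continuous <- lapply(labs, function(s) {
    vals <- table$lengths[, s]
    if (sum(!is.na(vals)) < 2) return(NULL)
    tryCatch(squared_change_parsimony(tree, setNames(as.numeric(vals),
                                                     rownames(table$lengths))),
             error = function(e) NULL)
  })
  names(continuous) <- labs
  presence <- lapply(labs, function(s) {
    p <- table$presence[, s]
    p[table$unknown[, s]] <- NA
    presence_reconstruction(tree, setNames(p, rownames(table$lengths)))
  })
  names(presence) <- labs
  anc <- parsimony_ancestral_sequences(tree, aln)
  variable <- find_variable_stems(table, tree)
  events <- classify_family_events(table, stems, tree, aln, anc,
                                   theta_gap, count_bulges)
  frequencies <- if (length(events))
    tabulate_event_frequencies(events, aln$family_label) else NULL
  if (nrow(variable)) {
    matrices <- list(
      single_extant = count_single_changes(aln, variable, stems, tree,
                                           "extant_extant"),
      single_ancestral = count_single_changes(aln, variable, stems, tree,
                                              "ancestral_extant", anc),
      pair_extant = count_pair_changes(aln, variable, stems, tree,
                                       "extant_extant"),
      pair_ancestral = count_pair_changes(aln, variable, stems, tree,
                                          "ancestral_extant", anc))
    log_odds <- lapply(matrices, function(m)
      if (m$total > 0) log_odds_transform(m, pseudocount) else NULL)
  } else {
    warning("no variable stems: substitution matrices skipped")
    matrices <- NULL; log_odds <- NULL
  }
  n_complete <- sum(complete.cases(table$lengths))
  pca <- if (n_complete >= 2 && ncol(table$lengths) >= 2 &&
             !all(apply(table$lengths[complete.cases(table$lengths), ,
                                      drop = FALSE], 2,
                        function(v) stats::var(v) == 0)))
    tryCatch(pca_stems(table, exclude_partial), error = function(e) NULL)
  else NULL
  clusters <- if (k >= 1 && nrow(table$lengths) >= k)
    tryCatch(kmeans_stems(table, k, seed), error = function(e) {
      warning("clustering skipped: ", conditionMessage(e))
      NULL
    }) else NULL
  wcss <- if (nrow(table$lengths) > 2)
    wcss_profile(table, seed = seed) else NULL
  structure(list(alignment = aln, tree = tree, stems = stems,
                 table = table, continuous = continuous,
                 presence = presence, ancestral = anc,
                 variable = variable, events = events,
                 frequencies = frequencies, matrices = matrices,
                 log_odds = log_odds, pca = pca, clusters = clusters,
                 wcss_profile = wcss,
                 params = list(theta_gap = theta_gap, k = k, seed = seed,
                               count_bulges = count_bulges,
                               exclude_partial = exclude_partial,
                               pseudocount = pseudocount,
                               canonical_pairs = .CANONICAL)),
            class = "stem_evolution")
}

#' @export
print.stem_evolution <- function(x, ...) {
  cat("Stem-evolution analysis of",
    if (nzchar(x$alignment$family_label)) x$alignment$family_label
    else "an RNA family", "\n")
  cat("  ", length(x$alignment$ids), " species, ", x$alignment$L,
      " columns, ", length(x$stems$stems), " stems (",
      sum(vapply(x$stems$stems, `[[`, logical(1), "pseudoknot")),
      " pseudoknotted)\n", sep = "")
  cat("  ", nrow(x$variable), " variable (stem, clade) records, ",
      length(x$events), " classified events\n", sep = "")
  if (!is.null(x$frequencies))
    cat(sprintf("  whole-stem indel %.1f%% vs substitution/indel %.1f%%\n",
                x$frequencies$whole_stem_pct[1],
                x$frequencies$substitution_indel_pct[1]))
  if (!is.null(x$pca))
    cat(sprintf("  PCA: first two components explain %.1f%% of variance\n",
                100 * x$pca$cumvar2))
  invisible(x)
}

#' @export
summary.stem_evolution <- function(object, ...) {
  x <- object
  cat("== Stems ==\n")
  df <- data.frame(stem = names(x$table$modal),
                   pairs = vapply(x$stems$stems, function(s)
                     nrow(s$pairs), integer(1)),
                   pseudoknot = vapply(x$stems$stems, `[[`, logical(1),
                                       "pseudoknot"),
                   modal_length = x$table$modal,
                   category = x$table$category,
                   root_state = vapply(names(x$table$modal), function(s) {
                     pr <- x$presence[[s]]
                     rt <- as.character(.root_node(x$tree))
                     pr$states[[rt]]
                   }, character(1)))
  print(df, row.names = FALSE)
  if (length(x$events)) {
    cat("\n== Events ==\n")
    for (e in x$events) print(e)
  }
  if (!is.null(x$pca)) {
    cat("\n== PCA ==\n"); print(x$pca)
  }
  invisible(df)
}

#' Arc-diagram plot of a stem-evolution analysis
#'
#' Draws the stems of the consensus structure as arcs over the
#' alignment columns, coloured by variability category (default) or by
#' ancestral root presence state.
#'
#' @param x a `stem_evolution` object.
#' @param colour_by `"category"` or `"root_state"`.
#' @param ... ignored.
#' @export
plot.stem_evolution <- function(x, colour_by = c("category", "root_state"),
                                ...) {
  colour_by <- match.arg(colour_by)
  ann <- if (colour_by == "category") x$table$category else
    vapply(names(x$table$modal), function(s) {
      rt <- as.character(.root_node(x$tree))
      x$presence[[s]]$states[[rt]]
    }, character(1))
  arcs <- arc_diagram_data(x$stems, ann)
  pal <- c(conserved = "black", intermediate = "brown", variable = "red",
           present = "black", absent = "red", unresolved = "brown")
  L <- x$alignment$L
  hmax <- max((arcs$x2 - arcs$x1) / 2)
  graphics::plot(NULL, xlim = c(1, L), ylim = c(0, hmax * 1.15),
                 xlab = "alignment column", ylab = "", yaxt = "n",
                 main = x$alignment$family_label)
  graphics::segments(1, 0, L, 0)
  th <- seq(0, pi, length.out = 100)
  for (r in seq_len(nrow(arcs))) {
    cx <- (arcs$x1[r] + arcs$x2[r]) / 2
    rad <- (arcs$x2[r] - arcs$x1[r]) / 2
    graphics::lines(cx + rad * cos(th), rad * sin(th),
                    col = pal[[arcs$class[r]]],
                    lty = if (arcs$crossing[r]) 2 else 1)
    graphics::text(cx, rad * 1.05, arcs$label[r], cex = 0.8)
  }
  graphics::legend("topright", legend = names(pal)[unique(match(arcs$class,
                                                                names(pal)))],
                   col = pal[unique(match(arcs$class, names(pal)))],
                   lty = 1, bty = "n", cex = 0.8)
  invisible(arcs)
}

#' Run the pipeline on files and write all outputs
#'
#' Reads a structural alignment and a Newick tree, runs
#' [stem_evolution], and writes the stem-length table, ancestral
#' sequences, event log, frequency table, the four log-odds matrices,
#' PCA/cluster tables and a JSON run manifest into `out_dir`.  Given
#' fixed inputs and seeds the outputs are byte-identical across runs.
#'
#' @param alignment_path path to the alignment (bracket dialect unless
#'   `dialect` says otherwise).
#' @param tree_path path to the Newick tree.
#' @param out_dir output directory (created if needed).
#' @param dialect alignment dialect for [read_structural_alignment].
#' @param ... passed to [stem_evolution].
#' @return the `stem_evolution` object, invisibly.
#' @export
run_pipeline <- function(alignment_path, tree_path, out_dir,
                         dialect = "bracket", ...) {
  aln <- read_structural_alignment(alignment_path, dialect)
  tree <- read_newick(tree_path)
  fit <- stem_evolution(aln, tree, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_stem_length_tsv(fit$table, p("stem_lengths.tsv"))
  write_stem_set_json(fit$stems, p("stems.json"))
  write_ancestral_fasta(fit$ancestral, p("ancestral_sequences.fasta"))
  write_events_json(fit$events, p("events.json"))
  if (!is.null(fit$frequencies))
    write.table(fit$frequencies, p("event_frequencies.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(fit$log_odds))
    for (nm in names(fit$log_odds))
      if (!is.null(fit$log_odds[[nm]]))
        write_matrix_tsv(fit$log_odds[[nm]], p(paste0("logodds_", nm,
                                                      ".tsv")))
  if (!is.null(fit$pca)) {
    write.table(cbind(species = rownames(fit$pca$scores),
                      round(as.data.frame(fit$pca$scores), 4)),
                p("pca_scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(cbind(stem = rownames(fit$pca$loadings),
                      round(as.data.frame(fit$pca$loadings), 4)),
                p("pca_loadings.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(fit$clusters))
    write.table(data.frame(species = names(fit$clusters$cluster),
                           cluster = fit$clusters$cluster),
                p("clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  manifest <- list(
    inputs = list(alignment = alignment_path, tree = tree_path,
                  alignment_md5 = unname(tools::md5sum(alignment_path)),
                  tree_md5 = unname(tools::md5sum(tree_path))),
    params = fit$params,
    counting_unit = "one tally per sequence pair and column (single) or column pair (duplet)",
    records = list(species = length(fit$alignment$ids),
                   stems = length(fit$stems$stems),
                   variable_records = nrow(fit$variable),
                   events = length(fit$events)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(fit)
}
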