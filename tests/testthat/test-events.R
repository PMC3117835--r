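test_that("variable stems are located at the clades where branches diverge", {
  tf <- toy_family()
  tab <- build_stem_length_table(tf$aln)
  var <- find_variable_stems(tab, tf$tree)
  # stem A constant everywhere; stem B differs between the two root
  # clades (4/3 vs 0/0) and between A and B (4 vs 3)
  expect_false("A" %in% var$stem)
  expect_true("B" %in% var$stem)
  # single deviant species: locus is its parent clade
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  rows <- c(A = "----...----", B = "GGGC...GCCC", C = "GGGC...GCCC",
            D = "GGGC...GCCC")
  aln <- structural_alignment(names(rows), unname(rows), "(((....))).")
  tab2 <- build_stem_length_table(aln)
  var2 <- find_variable_stems(tab2, tr)
  mrca_ab <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(nrow(var2), 1)
  expect_equal(var2$node, mrca_ab)
  # constant table -> nothing
  aln3 <- structural_alignment(names(rows), rep("GGGC...GCCC", 4),
                               "(((....))).")
  expect_equal(nrow(find_variable_stems(build_stem_length_table(aln3),
                                        tr)), 0)
})

test_that("whole-stem insertion is called when the ancestral region is empty", {
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  rows <- c(A = "AC.GGGAUAUCCC..", B = "AC.GGGAUAUCCC..",
            C = "AC.-------...--", D = "AC.-------...--")
  aln <- structural_alignment(names(rows), unname(rows),
                              "...(((....))).." )
  anc <- parsimony_ancestral_sequences(tr, aln)
  st <- extract_stems(aln$consensus_structure)
  tab <- build_stem_length_table(aln, st)
  var <- find_variable_stems(tab, tr)
  clade <- ape::getMRCA(tr, c("A", "B", "C"))
  expect_true(clade %in% var$node)
  ev <- classify_stem_event(st$stems[[1]], clade, aln, anc)
  expect_equal(ev$event_class, "whole_stem_insertion")
  expect_equal(ev$direction, "gain")
  expect_gte(ev$evidence$ancestral_gap_fraction, 0.9)
})

test_that("whole-stem deletion is called when derived sequences lose the region", {
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  rows <- c(A = "AC.GGGAUAUCCC..", B = "AC.----------..",
            C = "AC.GGGAUAUCCC..", D = "AC.GGGAUAUCCC..")
  aln <- structural_alignment(names(rows), unname(rows),
                              "...(((....))).." )
  anc <- parsimony_ancestral_sequences(tr, aln)
  st <- extract_stems(aln$consensus_structure)
  var <- find_variable_stems(build_stem_length_table(aln, st), tr)
  ev <- classify_stem_event(st$stems[[1]], var$node[1], aln, anc)
  expect_equal(ev$event_class, "whole_stem_deletion")
  expect_equal(ev$direction, "loss")
})

test_that("pairing changes by substitution are distinguished from indels of stems", {
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  rows <- c(A = "AC.GGGAUAUCCC..", B = "AC.GGAAUAUCCC..",
            C = "AC.GGGAUAUCCC..", D = "AC.GGGAUAUCCC..")
  aln <- structural_alignment(names(rows), unname(rows),
                              "...(((....))).." )
  anc <- parsimony_ancestral_sequences(tr, aln)
  st <- extract_stems(aln$consensus_structure)
  var <- find_variable_stems(build_stem_length_table(aln, st), tr)
  ev <- classify_stem_event(st$stems[[1]], var$node[1], aln, anc)
  expect_equal(ev$event_class, "pairing_change_substitution_indel")
})

test_that("species with unsequenced regions are excluded from event calls", {
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  rows <- c(A = "AC.GGGAUAUCCC..", B = "AC.~~~~~~~~~~~.",
            C = "AC.GGGAUAUCCC..", D = "AC.GGGAUAUCCC..")
  aln <- structural_alignment(names(rows), unname(rows),
                              "...(((....))).." )
  anc <- parsimony_ancestral_sequences(tr, aln)
  st <- extract_stems(aln$consensus_structure)
  clade <- ape::getMRCA(tr, c("A", "B"))
  ev <- classify_stem_event(st$stems[[1]], clade, aln, anc)
  expect_equal(ev$evidence$excluded_unknown, "B")
  # all members unknown -> no call
  rows2 <- c(A = "AC.~~~~~~~~~~~.", B = "AC.~~~~~~~~~~~.",
             C = "AC.GGGAUAUCCC..", D = "AC.GGGAUAUCCC..")
  aln2 <- structural_alignment(names(rows2), unname(rows2),
                               "...(((....))).." )
  anc2 <- parsimony_ancestral_sequences(tr, aln2)
  expect_error(classify_stem_event(st$stems[[1]], clade, aln2, anc2),
               "no call")
})

test_that("event classification ignores the order of species", {
  tf <- toy_family()
  fit1 <- stem_evolution(tf$aln, tf$tree)
  perm <- c(3, 1, 4, 2)
  aln2 <- structural_alignment(tf$aln$ids[perm],
                               unname(tf$aln$rows[perm]),
                               tf$aln$consensus_structure, "toy")
  fit2 <- stem_evolution(aln2, tf$tree)
  key <- function(f) sort(vapply(f$events, function(e)
    paste(e$stem, e$event_class), character(1)))
  expect_equal(key(fit1), key(fit2))
})

test_that("event frequencies pool the two top-level classes per family", {
  mk_ev <- function(cls) structure(list(stem = "A", node = 1,
                                        event_class = cls,
                                        direction = "gain",
                                        evidence = list()),
                                   class = "event_record")
  evs <- c(replicate(3, mk_ev("whole_stem_insertion"), simplify = FALSE),
           replicate(1, mk_ev("whole_stem_deletion"), simplify = FALSE),
           replicate(6, mk_ev("pairing_change_substitution_indel"),
                     simplify = FALSE))
  tab <- tabulate_event_frequencies(evs, "fam1")
  expect_equal(tab$whole_stem_pct, 40)
  expect_equal(tab$substitution_indel_pct, 60)
  expect_equal(tab$whole_stem_pct + tab$substitution_indel_pct, 100)
  # single-class family
  tab2 <- tabulate_event_frequencies(evs[1:4], "fam2")
  expect_equal(tab2$whole_stem_pct, 100)
  expect_equal(tab2$substitution_indel_pct, 0)
})

test_that("chi-square on event counts follows the Pearson statistic", {
  # identical row proportions: statistic 0
  even <- rbind(c(10, 30), c(5, 15), c(20, 60))
  cs <- chi_square_event_rates(even)
  expect_equal(cs$statistic, 0)
  expect_equal(cs$df, 2)  # three families -> df = 2
  # hand-computed 2x2
  cs2 <- chi_square_event_rates(rbind(c(10, 10), c(20, 0)))
  expect_equal(cs2$statistic, 40 / 3, tolerance = 1e-10)
  expect_equal(cs2$df, 1)
  expect_error(chi_square_event_rates(rbind(c(0, 0), c(1, 2))),
               "degenerate")
  expect_error(chi_square_event_rates(cbind(1:3)), "2 columns")
})

test_that("a planted whole-stem deletion is recovered at its clade", {
  cfg <- evolution_config(seed = 8, whole_stem_insertion_rate = 0,
                          whole_stem_deletion_rate = 0.08,
                          pair_substitution_rate = 0,
                          in_stem_indel_rate = 0,
                          loop_substitution_rate = 0)
  found <- FALSE
  for (s in 8:40) {
    cfg$seed <- s
    sim <- simulate_family(10, cfg)
    if (length(sim$events) != 1) next
    found <- TRUE
    fit <- suppressWarnings(stem_evolution(sim$alignment, sim$tree))
    rep <- recovery_report(sim, fit$events, fit$ancestral)
    expect_equal(rep$recall, 1)
    break
  }
  expect_true(found)
})
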