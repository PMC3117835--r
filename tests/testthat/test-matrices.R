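# a minimal fixture: one 3-pair stem over a cherry tree, with the
# variable record supplied directly so tallies are fully controlled
pair_fixture <- function(rowA, rowB) {
  tr <- ape::read.tree(text = "(A,B);")
  aln <- structural_alignment(c("A", "B"), c(rowA, rowB),
                              "(((...)))")
  st <- extract_stems(aln$consensus_structure)
  list(tree = tr, aln = aln, stems = st,
       variable = data.frame(stem = "A", node = 3L))
}

test_that("identical sequences put all single-change mass on the diagonal", {
  fx <- pair_fixture("GGC...GCC", "GGC...GCC")
  sc <- count_single_changes(fx$aln, fx$variable, fx$stems, fx$tree)
  expect_equal(sc$total, 6L)  # 6 stem columns, one sequence pair
  expect_equal(sum(diag(sc$counts)), 6)
  expect_equal(sc$counts["G", "G"], 3L)
  expect_equal(sc$counts["C", "C"], 3L)
})

test_that("single-nucleotide changes are tallied unordered with gaps as a state", {
  fx <- pair_fixture("ACG...CGU", "ACU...AGU")
  sc <- count_single_changes(fx$aln, fx$variable, fx$stems, fx$tree)
  # canonical (lower-triangle) storage: changed pairs {G,U} and {C,A}
  expect_equal(sc$counts["A", "A"], 1L)
  expect_equal(sc$counts["C", "C"], 1L)
  expect_equal(sc$counts["U", "U"], 1L)
  expect_equal(sc$counts["U", "G"], 1L)
  expect_equal(sc$counts["C", "A"], 1L)
  expect_equal(sc$total, 6L)
  # gap involved in a change
  fx2 <- pair_fixture("ACG...CGU", "AC-...CGU")
  sc2 <- count_single_changes(fx2$aln, fx2$variable, fx2$stems, fx2$tree)
  expect_equal(sc2$counts["-", "G"], 1L)
})

test_that("ancestral/extant single counts are directional", {
  fx <- pair_fixture("AG-...CGU", "AG-...CGU")
  anc <- structure(list(sequences = c("3" = "G-G...C?U"),
                        state_sets = list("3" = rep(list("A"), 9)),
                        tree = fx$tree),
                   class = "ancestral_sequences")
  sc <- count_single_changes(fx$aln, fx$variable, fx$stems, fx$tree,
                             "ancestral_extant", anc)
  # per member: G->A, - -> G, G -> -, C->C, U->U; '?' column skipped
  expect_equal(sc$counts["G", "A"], 2L)
  expect_equal(sc$counts["A", "G"], 0L)
  expect_equal(sc$counts["-", "G"], 2L)
  expect_equal(sc$counts["G", "-"], 2L)
  expect_equal(sc$total, 10L)
  # directional: ancestor rows, extant columns, not fold-symmetric
  expect_false(isTRUE(all.equal(sc$counts, t(sc$counts))))
})

test_that("base-pair changes capture compensatory and one-sided mutations", {
  # pair columns (1,9),(2,8),(3,7): A/B states per pair:
  # (G,C)->(A,U) compensatory, (G,C)->(G,U) one-sided, (C,G) unchanged
  fx <- pair_fixture("GGC...GCC", "AGC...GUU")
  pc <- count_pair_changes(fx$aln, fx$variable, fx$stems, fx$tree)
  expect_equal(pc$total, 3L)
  i <- which(rownames(pc$counts) == "GC")
  j_au <- which(colnames(pc$counts) == "AU")
  j_gu <- which(colnames(pc$counts) == "GU")
  get_unordered <- function(m, a, b)
    m[max(a, b), min(a, b)]
  expect_equal(get_unordered(pc$counts, i, j_au), 1L)
  expect_equal(get_unordered(pc$counts, i, j_gu), 1L)
  expect_equal(pc$counts["CG", "CG"], 1L)
  # the empty duplet (-,-) is excluded from tallies
  fx2 <- pair_fixture("GGC...GCC", "-GC...GC-")
  pc2 <- count_pair_changes(fx2$aln, fx2$variable, fx2$stems, fx2$tree)
  expect_equal(pc2$total, 2L)
  expect_false("--" %in% rownames(pc2$counts))
})

test_that("swapping the two sequences leaves extant/extant counts unchanged", {
  fx1 <- pair_fixture("GGC...GCC", "AGC...GUU")
  fx2 <- pair_fixture("AGC...GUU", "GGC...GCC")
  s1 <- count_single_changes(fx1$aln, fx1$variable, fx1$stems, fx1$tree)
  s2 <- count_single_changes(fx2$aln, fx2$variable, fx2$stems, fx2$tree)
  expect_equal(s1$counts, s2$counts)
  p1 <- count_pair_changes(fx1$aln, fx1$variable, fx1$stems, fx1$tree)
  p2 <- count_pair_changes(fx2$aln, fx2$variable, fx2$stems, fx2$tree)
  expect_equal(p1$counts, p2$counts)
})

test_that("log-odds transform reproduces hand-computed scores", {
  sc <- structure(list(mode = "single", comparison = "extant_extant",
                       states = c("A", "C", "G", "U", "-"),
                       counts = matrix(0L, 5, 5,
                                       dimnames = list(c("A","C","G","U","-"),
                                                       c("A","C","G","U","-"))),
                       total = 10L), class = "substitution_counts")
  sc$counts["A", "A"] <- 8L
  sc$counts["C", "A"] <- 2L
  lo <- log_odds_transform(sc)
  expect_equal(lo$matrix["A", "A"], log2(0.8 / 0.81))
  expect_equal(lo$matrix["C", "A"], log2(0.2 / (2 * 0.9 * 0.1)))
  expect_true(is.na(lo$matrix["C", "C"]))  # zero observed -> undefined
  # degenerate single-cell matrix: frequency one, marginals one, score 0
  sc2 <- sc; sc2$counts[] <- 0L; sc2$counts["A", "A"] <- 10L
  lo2 <- log_odds_transform(sc2)
  expect_equal(lo2$matrix["A", "A"], 0)
})

test_that("log-odds identities: sum to one, zero at independence, scale-free", {
  set.seed(13)
  states <- c("A", "C", "G", "U", "-")
  for (i in 1:20) {
    cm <- matrix(0, 5, 5, dimnames = list(states, states))
    cm[lower.tri(cm, diag = TRUE)] <- rpois(15, 4)
    if (sum(cm) == 0) cm["A", "A"] <- 1
    sc <- structure(list(mode = "single", comparison = "extant_extant",
                         states = states, counts = cm, total = sum(cm)),
                    class = "substitution_counts")
    lo <- log_odds_transform(sc)
    expect_equal(sum(lo$frequencies), 1)
    sc10 <- sc; sc10$counts <- cm * 10; sc10$total <- sum(cm) * 10
    expect_equal(log_odds_transform(sc10)$matrix, lo$matrix)
    # directional matrices behave the same way
    cmd <- matrix(rpois(25, 4), 5, 5, dimnames = list(states, states))
    if (sum(cmd) == 0) cmd[1, 1] <- 1
    scd <- structure(list(mode = "single", comparison = "ancestral_extant",
                          states = states, counts = cmd,
                          total = sum(cmd)),
                     class = "substitution_counts")
    lod <- log_odds_transform(scd)
    expect_equal(sum(lod$frequencies), 1)
    scd10 <- scd; scd10$counts <- cmd * 7
    expect_equal(log_odds_transform(scd10)$matrix, lod$matrix)
  }
  # counts built exactly from independent marginals give an all-zero matrix
  p <- c(0.4, 0.3, 0.2, 0.08, 0.02)
  cmi <- outer(p, p) * 1e6
  dimnames(cmi) <- list(states, states)
  sci <- structure(list(mode = "single", comparison = "ancestral_extant",
                        states = states, counts = cmi, total = sum(cmi)),
                   class = "substitution_counts")
  expect_equal(max(abs(log_odds_transform(sci)$matrix)), 0,
               tolerance = 1e-12)
  # fold-symmetric analogue: c_ij proportional to 2 p_i p_j off-diagonal
  cms <- matrix(0, 5, 5, dimnames = list(states, states))
  for (a in 1:5) for (b in 1:a)
    cms[a, b] <- (if (a == b) p[a]^2 else 2 * p[a] * p[b]) * 1e6
  scs <- structure(list(mode = "single", comparison = "extant_extant",
                        states = states, counts = cms, total = sum(cms)),
                   class = "substitution_counts")
  expect_equal(max(abs(log_odds_transform(scs)$matrix), na.rm = TRUE), 0,
               tolerance = 1e-12)
})

test_that("planted compensatory changes dominate the pair change counts", {
  can <- c("AU", "UA", "GC", "CG", "GU", "UG")
  wins <- logical(0)
  for (s in 1:5) {
    cfg <- evolution_config(seed = s, pair_substitution_rate = 0.15,
                            compensation_probability = 0.9)
    sim <- simulate_family(12, cfg)
    fit <- suppressWarnings(stem_evolution(sim$alignment, sim$tree))
    sc <- fit$matrices$pair_extant
    if (is.null(sc) || sc$total == 0) next
    m <- sc$counts
    comp <- c(); oth <- c()
    for (i in seq_len(nrow(m))) for (j in seq_len(i - 1)) {
      a <- rownames(m)[i]; b <- colnames(m)[j]
      if (a %in% can && b %in% can) comp <- c(comp, m[i, j])
      else oth <- c(oth, m[i, j])
    }
    wins <- c(wins, mean(comp) > mean(oth))
  }
  expect_true(all(wins))
})
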