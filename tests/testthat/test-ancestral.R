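test_that("squared-change parsimony solves the mean-of-neighbours system", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  r <- squared_change_parsimony(star, c(A = 5, B = 5, C = 5, D = 5))
  expect_equal(unname(r$node_values[5]), 5)
  expect_equal(r$cost, 0)
  # two leaves 0 and 6: root at the mean, cost 3^2 + 3^2
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  r2 <- squared_change_parsimony(cherry, c(A = 0, B = 6))
  expect_equal(unname(r2$node_values[3]), 3)
  expect_equal(r2$cost, 18)
  expect_error(squared_change_parsimony(cherry, c(A = 0)), "B")
})

test_that("squared-change cost matches a numerical optimizer on random trees", {
  set.seed(101)
  for (i in 1:10) {
    tr <- random_tree(sample(4:10, 1), polytomy = i %% 2 == 0)
    v <- setNames(runif(ape::Ntip(tr), 0, 10), tr$tip.label)
    r <- squared_change_parsimony(tr, v)
    obj <- function(x) {
      all <- c(v[tr$tip.label], x)
      sum((all[tr$edge[, 1]] - all[tr$edge[, 2]])^2)
    }
    o <- stats::optim(rep(mean(v), tr$Nnode), obj, method = "BFGS")
    expect_lt(abs(r$cost - o$value) / max(o$value, 1e-9), 1e-6)
  }
})

test_that("squared-change reconstruction ignores child order (polytomies)", {
  tr <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:1);")
  v <- c(A = 1, B = 4, C = 7, D = 10)
  r1 <- squared_change_parsimony(tr, v)
  tr2 <- ape::read.tree(text = "((C:1,A:1,B:1):1,D:1);")
  r2 <- squared_change_parsimony(tr2, v)
  expect_equal(r1$cost, r2$cost)
})

test_that("Sankoff ancestral sequences match exhaustive enumeration", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  aln <- structural_alignment(c("A", "B", "C", "D"),
                              c("A", "A", "C", "C"), ".")
  anc <- parsimony_ancestral_sequences(tr, aln)
  expect_equal(anc$score, 1)
  expect_equal(unname(anc$sequences["5"]), "?")  # root A/C tie
  expect_setequal(anc$state_sets[["5"]][[1]], c("A", "C"))
  oracle <- brute_force_parsimony(tr, list("A", "A", "C", "C"))
  expect_equal(anc$score, oracle$score)
  expect_setequal(anc$state_sets[["5"]][[1]], oracle$root_states)
  # constant column
  aln2 <- structural_alignment(c("A", "B", "C", "D"), rep("A", 4), ".")
  anc2 <- parsimony_ancestral_sequences(tr, aln2)
  expect_equal(anc2$score, 0)
  expect_equal(unname(anc2$sequences["5"]), "A")
})

test_that("Sankoff score equals the exhaustive minimum on random small trees", {
  set.seed(77)
  states <- c("A", "C", "G", "U", "-")
  for (i in 1:15) {
    n <- sample(3:5, 1)
    tr <- random_tree(n, polytomy = i %% 3 == 0)
    chars <- sample(c(states, "~"), n, replace = TRUE)
    aln <- structural_alignment(tr$tip.label, chars, ".")
    anc <- parsimony_ancestral_sequences(tr, aln)
    allowed <- lapply(chars, function(ch)
      if (ch == "~") states else ch)
    oracle <- brute_force_parsimony(tr, allowed)
    expect_equal(anc$score, oracle$score)
  }
})

test_that("Sankoff on binary trees agrees with an independent Fitch count", {
  skip_if_not_installed("phangorn")
  set.seed(55)
  for (i in 1:5) {
    tr <- ape::rtree(7)
    chars <- sample(c("A", "C", "G", "U"), 7, replace = TRUE)
    aln <- structural_alignment(tr$tip.label, chars, ".")
    anc <- parsimony_ancestral_sequences(tr, aln)
    dat <- phangorn::phyDat(setNames(as.list(tolower(gsub("U", "T",
                                                          chars))),
                                     tr$tip.label), type = "DNA")
    expect_equal(anc$score, phangorn::parsimony(tr, dat))
  }
})

test_that("non-sequenced leaves contribute no parsimony cost", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  aln <- structural_alignment(c("A", "B", "C", "D"),
                              c("A", "A", "A", "~"), ".")
  anc <- parsimony_ancestral_sequences(tr, aln)
  expect_equal(anc$score, 0)
  expect_equal(unname(anc$sequences["5"]), "A")
  tr2 <- ape::read.tree(text = "(A,B,C);")
  aln_missing <- structural_alignment(c("A", "B"), c("A", "A"), ".")
  expect_error(parsimony_ancestral_sequences(tr2, aln_missing), "C")
})

test_that("duplicating a leaf never increases the per-column score", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n)
    chars <- sample(c("A", "C", "G", "-"), n, replace = TRUE)
    aln <- structural_alignment(tr$tip.label, chars, ".")
    s0 <- parsimony_ancestral_sequences(tr, aln)$score
    # attach a twin next to a random leaf (text-level graft)
    leaf <- sample(tr$tip.label, 1)
    nwk <- ape::write.tree(tr)
    nwk2 <- sub(paste0("(^|[(,])", leaf, ":"),
                paste0("\\1(", leaf, ":0,X:0):"), nwk)
    tr2 <- ape::read.tree(text = nwk2)
    aln2 <- structural_alignment(c(tr$tip.label, "X"),
                                 c(chars, chars[tr$tip.label == leaf]),
                                 ".")
    s1 <- parsimony_ancestral_sequences(tr2, aln2)$score
    expect_lte(s1, s0 + 0)
    expect_gte(s1, s0)  # a twin adds no new change either
  }
})

test_that("presence reconstruction resolves roots and flags ties", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  all_p <- presence_reconstruction(tr, c(A = TRUE, B = TRUE, C = TRUE,
                                         D = TRUE))
  expect_equal(unname(all_p$states["5"]), "present")
  # balanced 50/50 on a cherry is unresolved
  ch <- ape::read.tree(text = "(A,B);")
  tie <- presence_reconstruction(ch, c(A = TRUE, B = FALSE))
  expect_equal(unname(tie$states["3"]), "unresolved")
  # a stem confined to one derived clade is absent at the root
  vt <- ape::read.tree(text = "((((m1,m2),m3),bird),fish);")
  pres <- c(m1 = TRUE, m2 = TRUE, m3 = TRUE, bird = FALSE, fish = FALSE)
  rec <- presence_reconstruction(vt, pres)
  root <- as.character(setdiff(unique(vt$edge[, 1]), vt$edge[, 2]))
  expect_equal(unname(rec$states[root]), "absent")
  # unknown leaves contribute no cost
  rec2 <- presence_reconstruction(vt, c(pres[-5], fish = NA))
  expect_lte(rec2$score, rec$score)
})
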