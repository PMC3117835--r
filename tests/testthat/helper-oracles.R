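# Independent oracles used by the test suite.  These deliberately share
# no code with the package implementation.

# exhaustive unit-cost parsimony: enumerate every internal labelling
# and return the minimal number of state changes plus the set of root
# states attaining it.  `leaf_allowed` is a list (in tip order) of
# allowed state vectors; a leaf contributes no change when its allowed
# set contains the parent state.
brute_force_parsimony <- function(tree, leaf_allowed,
                                  states = c("A", "C", "G", "U", "-")) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  internal <- (ntip + 1L):(ntip + nn)
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  grid <- as.matrix(do.call(expand.grid,
                            c(rep(list(states), nn),
                              stringsAsFactors = FALSE)))
  colnames(grid) <- as.character(internal)
  cost <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    a <- as.character(tree$edge[e, 1]); b <- tree$edge[e, 2]
    if (b <= ntip) {
      cost <- cost + !(grid[, a] %in% leaf_allowed[[b]])
    } else {
      cost <- cost + (grid[, a] != grid[, as.character(b)])
    }
  }
  best <- min(cost)
  list(score = best,
       root_states = sort(unique(grid[cost == best, as.character(root)])))
}

# random rooted tree, optionally with polytomies (collapse random
# internal edges)
random_tree <- function(n, polytomy = FALSE) {
  tr <- ape::rtree(n)
  if (polytomy && tr$Nnode > 2) {
    tr$edge.length[sample(which(tr$edge[, 2] > n), 1)] <- 0
    tr <- ape::di2multi(tr, tol = 1e-8)
  }
  tr
}

# random structure built from explicitly placed stems, each with its
# own pseudoknot letter class so the string is unambiguous; stems are
# separated by at least one unpaired column on every side.  Returns
# the string, the list of per-stem pair matrices, and which stems
# cross (computed here by the naive arc test, independently of the
# package).
random_knotted_structure <- function(L = 60, max_stems = 4) {
  occupied <- rep(FALSE, L + 2)  # sentinel margins
  stems <- list()
  for (s in seq_len(max_stems)) {
    for (try in 1:30) {
      m <- sample(2:4, 1)
      i <- sample(seq_len(L - 2 * m - 2), 1)
      j <- sample(seq(i + 2 * m + 1, L), 1)
      left <- i:(i + m - 1); right <- (j - m + 1):j
      block <- c(left, right)
      guard <- unique(c(block, block - 1, block + 1))
      guard <- guard[guard >= 0 & guard <= L + 1]
      if (any(occupied[guard + 1])) next
      if (max(left) >= min(right)) next
      occupied[block + 1] <- TRUE
      stems[[length(stems) + 1]] <- cbind(left, rev(right))
      break
    }
  }
  ch <- rep(".", L)
  for (k in seq_along(stems)) {
    ch[stems[[k]][, 1]] <- LETTERS[k]
    ch[stems[[k]][, 2]] <- letters[k]
  }
  crossing <- rep(FALSE, length(stems))
  if (length(stems) > 1) {
    for (a in seq_len(length(stems) - 1))
      for (b in (a + 1):length(stems))
        for (p in seq_len(nrow(stems[[a]])))
          for (q in seq_len(nrow(stems[[b]]))) {
            i <- stems[[a]][p, 1]; j <- stems[[a]][p, 2]
            k <- stems[[b]][q, 1]; l <- stems[[b]][q, 2]
            if ((i < k && k < j && j < l) || (k < i && i < l && l < j))
              crossing[a] <- crossing[b] <- TRUE
          }
  }
  list(struct = paste(ch, collapse = ""), stems = stems,
       crossing = crossing)
}

# adjusted Rand index between two partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# write a bracket-dialect alignment file from raw pieces
write_bracket_file <- function(path, ids, rows, struct) {
  writeLines(c(paste0("#structure ", struct),
               unlist(mapply(function(i, r) c(paste0(">", i), r),
                             ids, rows, SIMPLIFY = FALSE))), path)
  path
}

# small worked family used across tests: four leaves, two stems, the
# second stem deleted in C and D, one pairing change in B
toy_family <- function() {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  struct <- ".((((...))))..((((...)))).."
  rows <- c(
    A = ".GCGC...GCGC..AUGC...GCAU..",
    B = ".GCGC...GCGC..AAGC...GCAU..",
    C = ".GCGC...GCGC..----...----..",
    D = ".GCGC...GCGC..----...----..")
  aln <- structural_alignment(names(rows), unname(rows), struct, "toy")
  list(tree = tree, aln = aln)
}
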