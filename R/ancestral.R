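# Tree helpers ---------------------------------------------------------
# Trees are ape "phylo" objects; leaves are numbered 1..Ntip and
# internal nodes Ntip+1..Ntip+Nnode (the root is Ntip+1 after
# reordering).  All reconstructions key their output by these node ids.

.children_list <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  kids
}

.root_node <- function(tree) {
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
}

# internal nodes in post-order (children before parents)
.postorder_internal <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  unique(tr$edge[, 1])
}

#' Squared-change parsimony reconstruction of a continuous character
#'
#' Estimates internal-node values of a continuous character (here a
#' stem length) that minimize the sum over branches of squared
#' parent-child differences.  Branch lengths are ignored (unweighted);
#' polytomies are handled naturally.  At the minimum every internal
#' node equals the mean of its neighbours (parent and children), which
#' gives a linear system solved exactly.
#'
#' @param tree a rooted `phylo` tree (polytomies allowed).
#' @param leaf_values named numeric vector, one value per leaf.  Leaves
#'   with `NA` values are pruned from the tree before fitting.
#' @return object of class `continuous_reconstruction`: `node_values`
#'   (numeric vector over all node ids of the possibly pruned tree),
#'   `cost` (minimal total squared change), `tree` (the tree used).
#' @export
squared_change_parsimony <- function(tree, leaf_values) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, names(leaf_values))
  if (length(miss))
    stop("missing value for leaf/leaves: ", paste(miss, collapse = ", "))
  drop <- tree$tip.label[is.na(leaf_values[tree$tip.label])]
  if (length(drop)) {
    if (length(drop) >= ape::Ntip(tree) - 1)
      stop("fewer than two leaves with known values")
    tree <- ape::drop.tip(tree, drop, collapse.singles = TRUE)
  }
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  internal <- (ntip + 1L):n_node
  x <- numeric(n_node)
  x[seq_len(ntip)] <- leaf_values[tree$tip.label]
  # neighbour structure
  nb <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  k <- length(internal)
  A <- matrix(0, k, k); rhs <- numeric(k)
  idx <- setNames(seq_len(k), internal)
  for (v in internal) {
    r <- idx[as.character(v)]
    A[r, r] <- length(nb[[v]])
    for (u in nb[[v]]) {
      if (u > ntip) A[r, idx[as.character(u)]] <-
          A[r, idx[as.character(u)]] - 1
      else rhs[r] <- rhs[r] + x[u]
    }
  }
  x[internal] <- solve(A, rhs)
  cost <- sum((x[tree$edge[, 1]] - x[tree$edge[, 2]])^2)
  structure(list(node_values = x, cost = cost, tree = tree),
            class = "continuous_reconstruction")
}

#' @export
print.continuous_reconstruction <- function(x, ...) {
  cat("Squared-change parsimony reconstruction:",
      ape::Ntip(x$tree), "leaves, cost", format(x$cost), "\n")
  invisible(x)
}

# Sankoff machinery -----------------------------------------------------
# Unit-cost Sankoff parsimony over an arbitrary state set, with leaves
# given as allowed-state sets (a leaf with all states allowed is
# "missing" and contributes no cost).  Works on polytomies.  Returns,
# per node, the set of states attainable in at least one globally
# minimal labelling restricted to that node (argmin of down + up
# costs), and the minimal total score.
.sankoff_column <- function(tree, allowed, n_states) {
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  kids <- .children_list(tree)
  post <- .postorder_internal(tree)
  root <- post[length(post)]
  INF <- 1e9
  S <- matrix(0, n_states, n_node)          # cost of subtree below
  for (l in seq_len(ntip)) S[, l] <- ifelse(allowed[[l]], 0, INF)
  contrib <- vector("list", n_node)          # child's contribution to parent
  for (v in post) {
    tot <- numeric(n_states)
    for (c in kids[[v]]) {
      cc <- pmin(S[, c], min(S[, c]) + 1)
      contrib[[c]] <- cc
      tot <- tot + cc
    }
    S[, v] <- tot
  }
  score <- min(S[, root])
  U <- matrix(0, n_states, n_node)          # cost of the rest of the tree
  for (v in rev(post)) {
    for (c in kids[[v]]) {
      R <- U[, v] + S[, v] - contrib[[c]]
      U[, c] <- pmin(R, min(R) + 1)
    }
  }
  total <- S + U
  state_sets <- lapply(seq_len(n_node), function(v) {
    which(abs(total[, v] - min(total[, v])) < 0.5)
  })
  list(score = score, state_sets = state_sets, root = root)
}

.leaf_allowed <- function(ch, states, gaps_as_missing = FALSE) {
  amb <- list(R = c("A", "G"), Y = c("C", "U"), S = c("G", "C"),
              W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
              B = c("C", "G", "U"), D = c("A", "G", "U"),
              H = c("A", "C", "U"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "U"))
  if (ch == "~") return(rep(TRUE, length(states)))
  if (ch == "-") {
    if (gaps_as_missing) return(rep(TRUE, length(states)))
    return(states == "-")
  }
  if (ch %in% names(amb)) return(states %in% amb[[ch]])
  if (ch %in% states) return(states == ch)
  rep(TRUE, length(states))
}

#' Parsimony reconstruction of ancestral sequences
#'
#' Per alignment column, runs unit-cost Sankoff parsimony over the
#' five states `A,C,G,U,-` (the gap is a regular fifth state, so an
#' ancestor can be reconstructed as having no sequence in a region).
#' Columns are treated independently.  A `~` at a leaf allows all
#' states at no cost, as do IUPAC ambiguity codes for their base sets.
#' At each internal node the minimal-state set is computed; a unique
#' minimum gives that state, a tie gives `?` (the full set is kept in
#' `state_sets`).
#'
#' @param tree rooted `phylo`; every leaf must appear in the alignment.
#' @param aln a [structural_alignment] whose ids cover the leaves.
#' @param gaps_as_missing treat `-` as missing data instead of a fifth
#'   state.
#' @return object of class `ancestral_sequences`: `sequences` (named
#'   character vector of aligned strings over `A,C,G,U,-,?`, one per
#'   internal node id), `score` (total parsimony score), `column_scores`,
#'   `state_sets` (list: per internal node, per column, the minimal
#'   state set), `tree`.
#' @export
parsimony_ancestral_sequences <- function(tree, aln,
                                          gaps_as_missing = FALSE) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "structural_alignment"))
  miss <- setdiff(tree$tip.label, aln$ids)
  if (length(miss))
    stop("leaf/leaves absent from alignment: ",
         paste(miss, collapse = ", "))
  states <- .STATES5
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  internal <- (ntip + 1L):n_node
  rows <- lapply(tree$tip.label, function(id) .chars(aln$rows[[id]]))
  L <- aln$L
  chars <- matrix("?", length(internal), L)
  col_scores <- numeric(L)
  sets <- rep(list(vector("list", L)), length(internal))
  for (col in seq_len(L)) {
    allowed <- lapply(rows, function(r)
      .leaf_allowed(r[col], states, gaps_as_missing))
    res <- .sankoff_column(tree, allowed, length(states))
    col_scores[col] <- res$score
    for (k in seq_along(internal)) {
      ss <- res$state_sets[[internal[k]]]
      sets[[k]][[col]] <- states[ss]
      chars[k, col] <- if (length(ss) == 1) states[ss] else "?"
    }
  }
  sequences <- apply(chars, 1, paste, collapse = "")
  names(sequences) <- as.character(internal)
  names(sets) <- as.character(internal)
  structure(list(sequences = sequences, score = sum(col_scores),
                 column_scores = col_scores, state_sets = sets,
                 tree = tree, gaps_as_missing = gaps_as_missing),
            class = "ancestral_sequences")
}

#' @export
print.ancestral_sequences <- function(x, ...) {
  cat("Ancestral sequences at", length(x$sequences),
      "internal nodes; parsimony score", x$score, "\n")
  invisible(x)
}

#' Write ancestral sequences as aligned FASTA with node-id headers
#' @param anc an `ancestral_sequences` object.
#' @param path output path.
#' @export
write_ancestral_fasta <- function(anc, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (id in names(anc$sequences))
    writeLines(c(paste0(">node_", id), anc$sequences[[id]]), con)
  invisible(path)
}

#' Parsimony reconstruction of stem presence/absence
#'
#' Two-state (present/absent) unit-cost Sankoff parsimony.  Leaves with
#' unknown state (stem region not sequenced) allow both states at no
#' cost.  Internal nodes whose minimal-state set contains both states
#' are reported `unresolved`.
#'
#' @param tree rooted `phylo`.
#' @param presence named vector over leaves with values `TRUE`/`FALSE`
#'   (or `"present"`/`"absent"`), `NA` (or `"unknown"`) for unknown.
#' @return object of class `presence_reconstruction`: `states` (named
#'   character vector over internal node ids with values `present`,
#'   `absent`, `unresolved`), `score`, `tree`.
#' @export
presence_reconstruction <- function(tree, presence) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, names(presence))
  if (length(miss))
    stop("missing presence state for: ", paste(miss, collapse = ", "))
  p <- presence[tree$tip.label]
  if (is.character(p))
    p <- ifelse(p == "present", TRUE, ifelse(p == "absent", FALSE, NA))
  allowed <- lapply(p, function(v) {
    if (is.na(v)) c(TRUE, TRUE) else c(v, !v)  # states: present, absent
  })
  res <- .sankoff_column(tree, allowed, 2L)
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  states <- vapply(internal, function(v) {
    ss <- res$state_sets[[v]]
    if (length(ss) == 2) "unresolved" else
      c("present", "absent")[ss]
  }, character(1))
  names(states) <- as.character(internal)
  structure(list(states = states, score = res$score, tree = tree),
            class = "presence_reconstruction")
}

#' @export
print.presence_reconstruction <- function(x, ...) {
  cat("Presence reconstruction:", sum(x$states == "present"), "present,",
      sum(x$states == "absent"), "absent,",
      sum(x$states == "unresolved"), "unresolved nodes; score",
      x$score, "\n")
  invisible(x)
}
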