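# Shared fixtures and independent oracles used across test files.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# G-free random DNA: cannot contain a GCGC (HhaI) site, so planted sites
# are the only cut positions
rand_act <- function(n) paste(sample(c("A", "C", "T"), n, TRUE), collapse = "")

rand_iupac <- function(n) {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  paste(sample(codes, n, TRUE), collapse = "")
}

# Brute-force expansion count of an IUPAC string (independent of
# degeneracy(): multiplies set sizes taken from a locally defined table).
oracle_expansion_count <- function(s) {
  sets <- list(A = 1, C = 1, G = 1, T = 1, R = 2, Y = 2, S = 2, W = 2,
               K = 2, M = 2, B = 3, D = 3, H = 3, V = 3, N = 4)
  length(oracle_expand(s))
}

oracle_expand <- function(s) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  parts <- lapply(strsplit(s, "")[[1]], function(b) sets[[b]])
  out <- ""
  for (p in parts) out <- as.vector(outer(out, p, paste0))
  sort(out)
}

# All unrooted topologies on n taxa as a plain list of phylo objects
# (multiPhylo stores tip labels in an attribute that plain iteration
# would miss).
all_topologies <- function(n, taxa = paste0("t", seq_len(n))) {
  tt <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  lapply(seq_along(tt), function(k) tt[[k]])
}

# Random unrooted tree with positive branch lengths and its additive
# distance matrix (path lengths computed by ape, not by the package).
rand_additive <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  tr$tip.label <- paste0("t", seq_len(n))
  m <- ape::cophenetic.phylo(tr)
  m <- m[tr$tip.label, tr$tip.label]
  list(tree = tr, matrix = m)
}

# Tips on the child side of each internal edge of a phylo (test-local
# implementation, used to build least-squares design matrices and
# bipartition sets independently of the package internals).
edge_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) desc(tree$edge[e, 2]))
}

canonical_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  sides <- edge_splits(tree)
  out <- vapply(sides, function(s) {
    side <- if (tips[1] %in% s) setdiff(tips, s) else s
    if (length(side) < 2 || length(side) > length(tips) - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  sort(unique(out[!is.na(out)]))
}

# Ordinary least-squares fit of branch lengths for a fixed topology and
# the residual sum of squares against a distance matrix.
ls_residual <- function(tree, m) {
  tips <- rownames(m)
  sides <- edge_splits(tree)
  prs <- t(combn(tips, 2))
  A <- matrix(0, nrow(prs), length(sides))
  for (k in seq_len(nrow(prs)))
    for (e in seq_along(sides))
      A[k, e] <- xor(prs[k, 1] %in% sides[[e]], prs[k, 2] %in% sides[[e]])
  d <- m[cbind(prs[, 1], prs[, 2])]
  fit <- qr.solve(crossprod(A), crossprod(A, d))
  sum((A %*% fit - d)^2)
}

# Exhaustive minimum-changes parsimony score by enumerating all internal
# state assignments, column by column.
oracle_parsimony <- function(tree, seqs) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  L <- nchar(seqs[[1]])
  mat <- t(vapply(seqs[tree$tip.label], function(s) strsplit(s, "")[[1]],
                  character(L)))
  total <- 0
  for (col in seq_len(L)) {
    states <- unique(mat[, col])
    grid <- do.call(expand.grid,
                    c(rep(list(states), nint), stringsAsFactors = FALSE))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(node) {
        if (node <= ntip) mat[node, col] else grid[g, node - ntip]
      }
      changes <- sum(vapply(seq_len(nrow(tree$edge)), function(e)
        assign_state(tree$edge[e, 1]) != assign_state(tree$edge[e, 2]),
        logical(1)))
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}

# A template carrying expansions of a forward/reverse primer pair around a
# given interior, for panel construction.
planted_template <- function(forward, reverse, interior, lead = 40, trail = 40) {
  paste0(rand_dna(lead),
         oracle_expand(forward)[1], interior,
         ampliseek::revcomp(oracle_expand(reverse)[1]),
         rand_dna(trail))
}
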