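# Distance corrections, sequence-type clustering, neighbour joining with
# bootstrap supports, and Fitch parsimony scoring. Trees are ape `phylo`
# objects throughout.

#' Uncorrected p-distance between two aligned sequences
#'
#' @param a,b aligned sequences of equal length (nucleotide or protein)
#' @param pairwise_deletion drop columns with a gap in either sequence
#'   (default TRUE); with no comparable columns left this is an error
#' @return proportion of differing comparable columns, in \[0, 1\]
#' @export
p_distance <- function(a, b, pairwise_deletion = TRUE) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb))
    stop("sequences must have equal aligned length", call. = FALSE)
  if (pairwise_deletion) {
    keep <- ca != "-" & cb != "-"
    ca <- ca[keep]; cb <- cb[keep]
  }
  if (length(ca) == 0) stop("no comparable columns", call. = FALSE)
  mean(ca != cb)
}

#' Jukes-Cantor distance correction (nucleotide)
#'
#' d = -(3/4) ln(1 - 4p/3); valid for p < 0.75, above which the model is
#' saturated.
#'
#' @param p observed proportion of differing sites
#' @return corrected distance (>= p)
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0) || any(p >= 0.75))
    stop("Jukes-Cantor saturation: p must lie in [0, 0.75)", call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

#' Kimura distance correction (protein)
#'
#' d = -ln(1 - p - 0.2 p^2), the standard correction for amino-acid
#' p-distances; saturates when 1 - p - 0.2 p^2 <= 0 (p >= ~0.8541).
#'
#' @param p observed proportion of differing residues
#' @return corrected distance (>= p)
#' @export
kimura_protein <- function(p) {
  if (any(p < 0)) stop("negative p-distance", call. = FALSE)
  arg <- 1 - p - 0.2 * p^2
  if (any(arg <= 0))
    stop("Kimura protein saturation: p too large", call. = FALSE)
  -log(arg)
}

#' Pairwise distance matrix under a correction model
#'
#' Models: `"p"` (uncorrected), `"jukes_cantor"` (nucleotide),
#' `"kimura_protein"` (amino acid). Pairwise deletion of gapped columns.
#' Any saturated pair aborts with an error naming the pair.
#'
#' @param seqs named character vector of >= 3 aligned sequences
#' @param model distance model
#' @return symmetric numeric matrix with a `"model"` attribute
#' @export
build_matrix <- function(seqs, model = c("p", "jukes_cantor", "kimura_protein")) {
  model <- match.arg(model)
  if (length(seqs) < 3) stop("need at least 3 sequences", call. = FALSE)
  ids <- names(seqs)
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  fun <- switch(model, p = identity,
                jukes_cantor = jukes_cantor,
                kimura_protein = kimura_protein)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- p_distance(seqs[[i]], seqs[[j]])
    d <- tryCatch(fun(p), error = function(e)
      stop(sprintf("saturated pair %s / %s: %s", ids[i], ids[j],
                   conditionMessage(e)), call. = FALSE))
    m[i, j] <- m[j, i] <- d
  }
  attr(m, "model") <- model
  m
}

#' Cluster sequences into types at a distance cutoff
#'
#' Furthest-neighbour (complete-linkage) agglomeration, stopped before any
#' cluster's maximum pairwise distance would exceed `cutoff` — the
#' historical default for distance-based OTU/sequence-type definition. The
#' representative of a type is the member with the smallest sum of
#' within-type distances, ties broken by lowest id.
#'
#' @param m symmetric distance matrix with dimnames
#' @param cutoff maximum within-type pairwise distance (e.g. 0.01)
#' @return data.frame: id, type ("ST1", ...; numbered by first appearance
#'   in matrix order), representative (logical)
#' @export
cluster_sequence_types <- function(m, cutoff) {
  stopifnot(cutoff >= 0, !is.null(dimnames(m)))
  ids <- rownames(m)
  if (length(ids) == 1) {
    return(data.frame(id = ids, type = "ST1", representative = TRUE,
                      stringsAsFactors = FALSE))
  }
  if (length(ids) == 2) {
    grp <- if (m[1, 2] <= cutoff) c(1L, 1L) else c(1L, 2L)
  } else {
    hc <- hclust(as.dist(m), method = "complete")
    grp <- cutree(hc, h = cutoff)
  }
  # renumber types by first appearance
  first <- match(unique(grp), grp)
  type_num <- match(grp, grp[sort(first)])
  out <- data.frame(id = ids, type = paste0("ST", type_num),
                    representative = FALSE, stringsAsFactors = FALSE)
  for (ty in unique(out$type)) {
    members <- which(out$type == ty)
    if (length(members) == 1) { out$representative[members] <- TRUE; next }
    sums <- rowSums(m[members, members, drop = FALSE])
    best <- members[order(sums, ids[members])][1]
    out$representative[best] <- TRUE
  }
  out
}

# Neighbour joining ------------------------------------------------------------

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken deterministically by the lowest (row, column) index pair.
#' Negative branch lengths are clamped to 0 with the deficit transferred to
#' the sister branch, preserving path lengths through the joined pair. The
#' three remaining nodes are resolved by the three-point formulas.
#'
#' @param m symmetric distance matrix (>= 3 taxa, dimnames required)
#' @return an unrooted `phylo` object
#' @export
neighbor_joining <- function(m) {
  ids <- rownames(m)
  n <- length(ids)
  stopifnot(n >= 3, identical(ids, colnames(m)))
  labels <- ids           # newick fragment per active node
  d <- m
  while (length(labels) > 3) {
    k <- nrow(d)
    r <- rowSums(d)
    q <- (k - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest (i, j) among minima, column-major over the upper triangle
    best <- which(q == min(q[upper.tri(q)]), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_lab <- sprintf("(%s:%.17g,%s:%.17g)", labels[i], li, labels[j], lj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d <- rbind(cbind(d, u = du), u = c(du, 0))
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    labels <- c(labels[-c(i, j)], new_lab)
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- "u"
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 labels[1], la, labels[2], lb, labels[3], lc)
  ape::read.tree(text = nwk)
}

# Canonical bipartition strings for every internal edge of an unrooted
# phylo (the side not containing the alphabetically first tip, sorted).
.bipartitions <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  anchor <- sort(tips)[1]
  out <- character(0)
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    if (node == ntip + 1) next   # root (basal trifurcation): no parent edge
    desc <- .descendant_tips(tree, node)
    side <- if (anchor %in% desc) setdiff(tips, desc) else desc
    if (length(side) >= 2 && length(side) <= ntip - 2)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

.descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- c(tips, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  tree$tip.label[tips]
}

#' Bootstrap supports on a neighbour-joining tree
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_reps` times; the support of each internal edge is the
#' percentage of successful replicate trees containing the same
#' bipartition, mapped onto the full-data tree as internal node labels.
#' Replicates whose resampled matrix saturates under the correction model
#' are skipped and tallied in the `"skipped_replicates"` attribute.
#'
#' @param seqs named character vector of aligned sequences (>= 4 for any
#'   internal edge to exist)
#' @param n_reps number of bootstrap replicates (e.g. 1000)
#' @param model distance model, see [build_matrix()]
#' @param seed integer seed; supports are reproducible for a fixed seed
#' @return `phylo` with node labels holding integer percent supports
#' @export
bootstrap_support <- function(seqs, n_reps, model = "p", seed = 1) {
  stopifnot(n_reps >= 1)
  full <- neighbor_joining(build_matrix(seqs, model))
  target <- .bipartitions(full)
  counts <- setNames(numeric(length(target)), target)
  ncol_aln <- nchar(seqs[[1]])
  mat <- .seq_matrix(seqs)
  skipped <- 0
  done <- 0
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    rs <- setNames(apply(mat[, cols, drop = FALSE], 1, paste, collapse = ""),
                   names(seqs))
    bm <- tryCatch(build_matrix(rs, model), error = function(e) NULL)
    if (is.null(bm)) { skipped <- skipped + 1; next }
    bp <- .bipartitions(neighbor_joining(bm))
    hit <- target %in% bp
    counts[hit] <- counts[hit] + 1
    done <- done + 1
  }
  if (skipped > 0)
    warning(skipped, " bootstrap replicate(s) skipped (saturated distances)")
  support <- if (done > 0) round(100 * counts / done) else counts * NA
  # write supports as labels of the matching internal nodes
  ntip <- length(full$tip.label)
  labs <- character(full$Nnode)
  anchor <- sort(full$tip.label)[1]
  for (node in (ntip + 2):(ntip + full$Nnode)) {
    desc <- .descendant_tips(full, node)
    side <- if (anchor %in% desc) setdiff(full$tip.label, desc) else desc
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support))
      labs[node - ntip] <- as.character(support[[key]])
  }
  full$node.label <- labs
  attr(full, "skipped_replicates") <- skipped
  full
}

#' Fitch parsimony score of a tree for an alignment
#'
#' Sum over alignment columns of the minimal number of state changes under
#' Fitch's algorithm (each distinct character, including gaps, is one
#' state). Scores the fixed topology only; no tree search.
#'
#' @param tree a `phylo` whose tip labels match `names(seqs)`
#' @param seqs named character vector of aligned sequences
#' @return non-negative integer
#' @export
fitch_score <- function(tree, seqs) {
  stopifnot(setequal(tree$tip.label, names(seqs)))
  ntip <- length(tree$tip.label)
  ncol_aln <- nchar(seqs[[1]])
  mat <- .seq_matrix(seqs[tree$tip.label])
  # post-order over edges
  root <- ntip + 1
  order_nodes <- rev(.preorder_nodes(tree, root))
  children <- split(tree$edge[, 2], tree$edge[, 1])
  total <- 0
  for (col in seq_len(ncol_aln)) {
    sets <- vector("list", ntip + tree$Nnode)
    for (t in seq_len(ntip)) sets[[t]] <- mat[t, col]
    changes <- 0
    for (nd in order_nodes) {
      if (nd <= ntip) next
      kid_sets <- lapply(children[[as.character(nd)]], function(k) sets[[k]])
      # Hartigan counting: exact for multifurcations (e.g. the basal
      # trifurcation of an unrooted tree), reduces to Fitch on binary nodes
      tab <- table(unlist(kid_sets))
      mx <- max(tab)
      sets[[nd]] <- names(tab)[tab == mx]
      changes <- changes + length(kid_sets) - mx
    }
    total <- total + changes
  }
  total
}

.preorder_nodes <- function(tree, root) {
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, nd)
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    stack <- c(stack, kids)
  }
  out
}

#' Newick serialization
#'
#' Thin wrappers over the ape readers/writers; bootstrap supports travel as
#' internal node labels and branch lengths survive a round trip to 1e-9.
#'
#' @param tree a `phylo`
#' @return `to_newick`: a Newick string; `from_newick`: a `phylo`
#' @export
to_newick <- function(tree) {
  ape::write.tree(tree, digits = 12)
}

#' @rdname to_newick
#' @param text Newick string
#' @export
from_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text), error = function(e)
    stop("Newick parse error: ", conditionMessage(e), call. = FALSE),
    warning = function(w)
      stop("Newick parse error: ", conditionMessage(w), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error", call. = FALSE)
  tr
}
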