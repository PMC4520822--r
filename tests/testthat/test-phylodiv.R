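test_that("p-distance counts mismatches over comparable columns", {
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0.0)   # gapped column excluded
  expect_equal(p_distance("ACGT", "ACGT"), 0.0)
  expect_error(p_distance("ACG", "ACGT"), "equal")
  expect_error(p_distance("---", "AAA"), "comparable")
})

test_that("distance corrections match their closed forms and domains", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.3), -0.75 * log(1 - 4 * 0.3 / 3), tolerance = 1e-12)
  expect_error(jukes_cantor(0.75), "saturation")
  expect_equal(kimura_protein(0), 0)
  expect_equal(kimura_protein(0.5), -log(0.45), tolerance = 1e-12)
  expect_error(kimura_protein(0.86), "saturation")
  expect_silent(kimura_protein(0.854))
})

test_that("corrections are strictly increasing and dominate p", {
  p <- seq(0, 0.74, by = 0.01)
  jc <- jukes_cantor(p)
  expect_true(all(diff(jc) > 0))
  expect_true(all(jc >= p))
  p2 <- seq(0, 0.85, by = 0.01)
  kp <- kimura_protein(p2)
  expect_true(all(diff(kp) > 0))
  expect_true(all(kp >= p2))
})

test_that("build_matrix composes p-distance with the model", {
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC")
  m <- build_matrix(seqs, "jukes_cantor")
  expect_true(all(m == 0))
  expect_equal(attr(m, "model"), "jukes_cantor")
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 99), "G"), collapse = "")
  m2 <- build_matrix(c(x = s1, y = s2, z = s1), "jukes_cantor")
  expect_equal(m2["x", "y"], jukes_cantor(0.01), tolerance = 1e-12)
  sat <- c(p = paste(rep("A", 10), collapse = ""),
           q = paste(rep("G", 10), collapse = ""),
           r = paste(rep("A", 10), collapse = ""))
  expect_error(build_matrix(sat, "jukes_cantor"), "p / q")
  expect_error(build_matrix(seqs[1:2], "p"), "at least 3")
})

test_that("matrix entries recover the generator's divergence scale", {
  fam <- generate_family(family_spec(seed = 12))
  m <- build_matrix(fam$proteins, "p")
  off <- m[upper.tri(m)]
  # expected pairwise aa difference at variable sites: both mutated
  # independently at 0.15, random replacement among 19 alternatives
  rate <- 0.15
  p_site <- 2 * rate * (1 - rate) + rate^2 * 18 / 19
  n_var <- 8 + 70 + 70 + 99 + 10
  n_tot <- nchar(fam$proteins[1])
  expected <- p_site * n_var / n_tot
  expect_lt(abs(mean(off) - expected), 0.03)
})

test_that("sequence typing follows complete linkage with a certificate", {
  m <- matrix(c(0, .005, .02, .005, 0, .02, .02, .02, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ty <- cluster_sequence_types(m, 0.01)
  expect_equal(ty$type[ty$id == "A"], ty$type[ty$id == "B"])
  expect_false(ty$type[ty$id == "C"] == ty$type[ty$id == "A"])
  ty0 <- cluster_sequence_types(m, 0)
  expect_equal(length(unique(ty0$type)), 3)
  ty1 <- cluster_sequence_types(m, 0.5)
  expect_equal(length(unique(ty1$type)), 1)
  # one representative per type, certificate holds at every cutoff
  set.seed(61)
  n <- 12
  mm <- matrix(runif(n * n, 0, 0.4), n, n)
  mm <- (mm + t(mm)) / 2; diag(mm) <- 0
  dimnames(mm) <- list(letters[1:n], letters[1:n])
  prev <- Inf
  for (cut in c(0.05, 0.1, 0.2, 0.3, 0.5)) {
    tt <- cluster_sequence_types(mm, cut)
    k <- length(unique(tt$type))
    expect_lte(k, prev)          # non-increasing in cutoff
    prev <- k
    expect_equal(sum(tt$representative), k)
    for (ty2 in unique(tt$type)) {
      mem <- tt$id[tt$type == ty2]
      if (length(mem) > 1)
        expect_lte(max(mm[mem, mem]), cut)
    }
  }
})

test_that("neighbour joining recovers additive trees exactly", {
  m <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(m)
  cm <- ape::cophenetic.phylo(tr)[rownames(m), colnames(m)]
  expect_lt(max(abs(cm - m)), 1e-9)
  expect_equal(canonical_bipartitions(tr), "C|D")   # the A,B side anchored away
  # three taxa: closed-form star lengths
  m3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(m3)
  el <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(el[["x"]], 0)   # (2 + 3 - 5)/2
  expect_equal(el[["y"]], 2)
  expect_equal(el[["z"]], 3)
  # equal distances: deterministic under the tie-break
  me <- matrix(1, 5, 5); diag(me) <- 0
  dimnames(me) <- list(letters[1:5], letters[1:5])
  expect_identical(to_newick(neighbor_joining(me)),
                   to_newick(neighbor_joining(me)))
})

test_that("neighbour joining agrees with ape's implementation on random matrices", {
  set.seed(62)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    ra <- rand_additive(n)
    noisy <- ra$matrix + matrix(runif(n * n, 0, 0.05), n, n)
    noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
    mine <- neighbor_joining(noisy)
    apes <- ape::nj(noisy)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(apes)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are seeded, mapped, and calibrated", {
  # every column supports AB|CD
  seqs <- c(A = paste(rep(c("A", "T"), 25), collapse = ""),
            B = paste(rep(c("A", "T"), 25), collapse = ""),
            C = paste(rep(c("G", "C"), 25), collapse = ""),
            D = paste(rep(c("G", "C"), 25), collapse = ""))
  tr <- bootstrap_support(seqs, n_reps = 200, model = "p", seed = 5)
  expect_true("100" %in% tr$node.label)
  expect_identical(to_newick(bootstrap_support(seqs, 200, "p", seed = 5)),
                   to_newick(tr))
  # two conflicting signal blocks of equal size leave a contested edge
  block1 <- c(A = "A", B = "A", C = "G", D = "G")
  block2 <- c(A = "A", B = "G", C = "A", D = "G")
  seqs2 <- setNames(paste0(strrep(block1, 30), strrep(block2, 30)),
                    names(block1))
  tr2 <- bootstrap_support(seqs2, n_reps = 400, model = "p", seed = 9)
  sup <- suppressWarnings(as.numeric(tr2$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(any(abs(sup - 50) <= 15))
})

test_that("Fitch scoring matches hand counts and is relabel-invariant", {
  t_abcd <- ape::read.tree(text = "((A,B),C,D);")
  expect_equal(fitch_score(t_abcd, c(A = "A", B = "A", C = "C", D = "C")), 1)
  t_acbd <- ape::read.tree(text = "((A,C),B,D);")
  expect_equal(fitch_score(t_acbd, c(A = "A", B = "A", C = "C", D = "C")), 2)
  const <- c(A = "AAAA", B = "AAAA", C = "AAAA", D = "AAAA")
  expect_equal(fitch_score(t_abcd, const), 0)
  # swapping tips within the same unrooted topology preserves the score
  set.seed(63)
  seqs <- setNames(vapply(1:4, function(i) rand_dna(30), character(1)),
                   LETTERS[1:4])
  t1 <- ape::read.tree(text = "((A,B),C,D);")
  t2 <- ape::read.tree(text = "((B,A),D,C);")
  expect_equal(fitch_score(t1, seqs), fitch_score(t2, seqs))
})

test_that("newick serialization round trips topology, lengths, and supports", {
  m <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(m)
  tr$node.label <- c("", "87")
  back <- from_newick(to_newick(tr))
  expect_identical(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(canonical_bipartitions(back), canonical_bipartitions(tr))
  expect_lt(max(abs(sort(back$edge.length) - sort(tr$edge.length))), 1e-9)
  expect_true("87" %in% back$node.label)
  z <- from_newick("((A:0,B:1):0.5,C:1,D:2);")
  expect_true(0 %in% z$edge.length)
  u <- from_newick("((A,B),C,D);")   # unlabeled internals accepted
  expect_equal(length(u$tip.label), 4)
  expect_error(from_newick("((A,B,C);"), "parse")
})
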