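make_aln <- function(rows) setNames(rows, paste0("r", seq_along(rows)))

test_that("column conservation is modal-residue frequency with gaps as mismatches", {
  aln <- make_aln(c("HHHAH", "HHHBH", "HHHCH", "HP-DH", "HHHEH"))
  sc <- column_conservation(aln)
  expect_equal(sc[1], 1.0, ignore_attr = TRUE)
  expect_equal(sc[2], 0.8, ignore_attr = TRUE)
  expect_equal(sc[3], 0.8, ignore_attr = TRUE)   # gap counts against the mode
  expect_equal(sc[4], 0.2, ignore_attr = TRUE)
  aln4 <- make_aln(c("H", "H", "H", "P"))
  expect_equal(column_conservation(aln4), 0.75, ignore_attr = TRUE)
  aln_gap <- make_aln(c("H", "-", "H", "H"))
  expect_equal(column_conservation(aln_gap), 0.75, ignore_attr = TRUE)
})

test_that("find_conserved_blocks returns maximal qualifying runs", {
  # columns 5-10 identical, all others fully variable over 4 rows
  set.seed(7)
  var_col <- function() sample(c("A", "C", "D", "E"), 4)
  cols <- replicate(14, var_col())
  cols[, 5:10] <- matrix(rep(c("H", "H", "H", "H"), 6), nrow = 4)
  rows <- apply(cols, 1, paste, collapse = "")
  aln <- make_aln(rows)
  b <- find_conserved_blocks(aln, min_len = 6, min_score = 1.0)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(5, 10))
  expect_equal(b$consensus, "HHHHHH")
  # fully variable alignment
  cols2 <- matrix(c("A", "C", "D", "E"), 4, 12)
  aln2 <- make_aln(apply(cols2, 1, paste, collapse = ""))
  expect_equal(nrow(find_conserved_blocks(aln2, 5, 1.0)), 0)
  expect_error(find_conserved_blocks(aln, min_len = 20), "min_len")
})

test_that("conserved blocks contain every planted anchor and are row-order invariant", {
  fam <- generate_family(family_spec(seed = 5))
  b <- find_conserved_blocks(fam$proteins, min_len = 5, min_score = 1.0)
  for (k in seq_len(nrow(fam$anchor_positions))) {
    a <- fam$anchor_positions[k, ]
    covered <- any(b$start <= a$aa_start & b$end >= a$aa_end)
    expect_true(covered, label = paste("anchor", a$anchor, "covered"))
  }
  perm <- fam$proteins[c(3, 1, 5, 2, 4)]
  expect_equal(find_conserved_blocks(perm, 5, 1.0)[, c("start", "end")],
               b[, c("start", "end")])
})

test_that("raising min_score never increases block coverage", {
  set.seed(21)
  fam <- generate_family(family_spec(divergence = 0.3, seed = 21))
  cover <- function(ms) {
    b <- find_conserved_blocks(fam$proteins, min_len = 5, min_score = ms)
    if (nrow(b) == 0) 0 else sum(b$end - b$start + 1)
  }
  cv <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), cover, numeric(1))
  expect_true(all(diff(cv) <= 0))
})

test_that("degeneracy matches brute-force expansion counts", {
  pp <- printed_primers()
  for (k in seq_len(nrow(pp)))
    expect_equal(degeneracy(pp$sequence[k]),
                 oracle_expansion_count(pp$sequence[k]),
                 label = pp$name[k])
  set.seed(9)
  for (i in 1:40) {
    s <- rand_iupac(sample(4:10, 1))
    if (degeneracy(s) <= 4096)
      expect_equal(degeneracy(s), oracle_expansion_count(s))
  }
  expect_identical(sort(expand_degenerate("ATS")), c("ATC", "ATG"))
})

test_that("melting temperature follows the Wallace rule with set averaging", {
  expect_equal(melting_temp("AAAATTTT"), 16)
  expect_equal(melting_temp("GGGGCCCC"), 32)
  # A contributes 2, S averages to 4, R averages to 3
  expect_equal(melting_temp("ASASASAS"), 24)
  expect_equal(melting_temp("ARARARAR"), 20)
  expect_error(melting_temp("ATGC"), "shorter")
})

test_that("reverse translation merges codons by usage under the degeneracy cap", {
  u <- codon_usage_uniform()
  expect_equal(reverse_translate("M", u, 1), "ATG")
  # H with CAC 0.6 / CAT 0.4 merges to CAY once the cap allows two codons
  u2 <- u
  u2$relative_frequency[u2$codon == "CAC"] <- 0.6
  u2$relative_frequency[u2$codon == "CAT"] <- 0.4
  expect_equal(reverse_translate("H", u2, 1), "CAC")
  expect_equal(reverse_translate("H", u2, 2), "CAY")
  expect_error(reverse_translate("HPM", u, 0), "cap")
  expect_error(reverse_translate("HXM", u), "wildcard")
})

test_that("a genus-specific primer core is reproduced from usage fractions", {
  # HPMHV with two-codon usage for H and P and the budget spent left to
  # right gives the core of the printed Rhodococcus forward primer
  u <- codon_usage_uniform()
  u$relative_frequency[u$codon == "CAC"] <- 0.6
  u$relative_frequency[u$codon == "CAT"] <- 0.4
  u$relative_frequency[u$codon %in% c("CCA", "CCT")] <- 0
  u$relative_frequency[u$codon %in% c("CCG", "CCC")] <- 0.5
  u$relative_frequency[u$amino_acid == "V"] <- 0
  u$relative_frequency[u$codon == "GTG"] <- 0.9
  u$relative_frequency[u$codon == "GTC"] <- 0.1
  core <- reverse_translate("HPMHV", u, degeneracy_cap = 4)
  expect_equal(core, "CAYCCSATGCACGTG")
  expect_true(grepl(core, "GCAYCCSATGCACGTGGG", fixed = TRUE))
})

test_that("every expansion of a reverse translation folds back to the peptide", {
  set.seed(13)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (usage in list(codon_usage_uniform(), codon_usage_gc_biased())) {
    for (i in 1:15) {
      p <- paste(sample(aas, sample(3:6, 1), TRUE), collapse = "")
      cap <- sample(c(1, 4, 16, 64), 1)
      nt <- reverse_translate(p, usage, cap)
      expect_lte(degeneracy(nt), max(cap, 1))
      if (degeneracy(nt) <= 64)
        for (e in oracle_expand(nt)) expect_equal(translate(e), p)
    }
  }
})

test_that("primer pairs are emitted for block spacings inside the product range", {
  # blocks at consensus codons 10-15 and 105-110 imply a 303 bp product
  set.seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- 120
  base <- sample(aas, n, TRUE)
  rows <- lapply(1:4, function(i) {
    r <- base
    var <- setdiff(seq_len(n), c(10:15, 105:110))
    flip <- sample(var, length(var) %/% 2)
    r[flip] <- vapply(r[flip], function(a) sample(setdiff(aas, a), 1), "")
    paste(r, collapse = "")
  })
  aln <- make_aln(unlist(rows))
  pairs <- design_primer_pairs(aln, product_range = c(250, 350),
                               min_len = 6, min_score = 1.0)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$product_size, 303)
  expect_equal(pairs$forward_codon_start, 10)
  expect_equal(pairs$reverse_codon_end, 110)
  expect_equal(nrow(design_primer_pairs(aln, product_range = c(10, 20),
                                        min_len = 6, min_score = 1.0)), 0)
})

test_that("designed primers on a planted family sit near the target product size", {
  fam <- generate_family(family_spec(seed = 2))
  pairs <- design_primer_pairs(fam$proteins, product_range = c(750, 850),
                               min_len = 6, min_score = 1.0)
  expect_gte(nrow(pairs), 1)
  expect_true(all(pairs$product_size >= 750 & pairs$product_size <= 850))
  expect_equal(pairs$forward_degeneracy[1],
               degeneracy(pairs$forward[1]))
})

test_that("reverse primers are emitted 5'->3' as synthesized", {
  fam <- generate_family(family_spec(seed = 2))
  pairs <- design_primer_pairs(fam$proteins, product_range = c(750, 850),
                               min_len = 6, min_score = 1.0)
  p <- pairs[1, ]
  # reverse complement of the reverse primer translates to the anchor
  expect_true(any(vapply(oracle_expand(revcomp(p$reverse))[1],
                         function(e) translate(e) == p$reverse_anchor,
                         logical(1))))
})

test_that("codon usage tables validate and round trip as TSV", {
  u <- codon_usage_gc_biased()
  f <- tempfile(fileext = ".tsv")
  write_codon_usage(u, f)
  expect_equal(read_codon_usage(f), u, tolerance = 1e-12)
  bad <- u[u$amino_acid != "W", ]
  expect_error(write_codon_usage(bad, f), "missing")
  u2 <- u
  u2$relative_frequency[1] <- u2$relative_frequency[1] + 0.5
  expect_error(write_codon_usage(u2, f), "sum to 1")
})
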