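# Degenerate primer design from conserved blocks of a protein alignment.
#
# The workflow mirrors classical degenerate-primer construction for
# protein-coding marker surveys: score alignment columns by conservation,
# extract maximal conserved blocks, reverse translate block consensus
# peptides under a codon usage table while capping total degeneracy, and
# pair blocks whose spacing yields a product in the requested size range.

#' Per-column conservation of a protein alignment
#'
#' Score of a column is the frequency of its modal non-gap residue over all
#' rows; gaps count as mismatching symbols (an all-gap column scores 0).
#'
#' @param aln named character vector of aligned protein sequences
#'   (equal lengths, gaps as `-`)
#' @return numeric vector of scores in \[0, 1\], one per column
#' @export
column_conservation <- function(aln) {
  mat <- .aln_matrix(aln)
  apply(mat, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0) return(0)
    max(table(res)) / length(col)
  })
}

.aln_matrix <- function(aln) {
  stopifnot(length(aln) >= 2)
  lens <- nchar(aln)
  if (length(unique(lens)) != 1)
    stop("alignment rows must have identical length", call. = FALSE)
  .seq_matrix(aln)
}

# Modal non-gap residue per column; ties broken alphabetically.
.consensus <- function(mat) {
  apply(mat, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0) return("-")
    tab <- table(res)
    names(tab)[which.max(tab)]   # which.max takes first => alphabetical tie-break
  })
}

#' Maximal conserved blocks of a protein alignment
#'
#' A block is a maximal run of columns whose conservation score is at least
#' `min_score`, kept when it spans at least `min_len` columns. Blocks are
#' disjoint and sorted by start column (1-based inclusive).
#'
#' @inheritParams column_conservation
#' @param min_len minimum block length in columns (>= 5 recommended for
#'   primer anchors)
#' @param min_score minimum per-column conservation in \[0, 1\]
#' @return data.frame with columns start, end, consensus (peptide),
#'   min_score_observed
#' @export
find_conserved_blocks <- function(aln, min_len = 5, min_score = 0.9) {
  mat <- .aln_matrix(aln)
  if (min_len > ncol(mat)) stop("min_len exceeds alignment length", call. = FALSE)
  sc <- column_conservation(aln)
  cons <- .consensus(mat)
  ok <- sc >= min_score
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$consensus <- vapply(seq_len(nrow(out)), function(i)
    paste(cons[out$start[i]:out$end[i]], collapse = ""), character(1))
  out$min_score_observed <- vapply(seq_len(nrow(out)), function(i)
    min(sc[out$start[i]:out$end[i]]), numeric(1))
  out[order(out$start), , drop = FALSE]
}

#' Degeneracy of an IUPAC primer
#'
#' Product over positions of the IUPAC base-set sizes; equals the number of
#' distinct plain-base expansions.
#'
#' @param primer IUPAC nucleotide string (no gaps)
#' @return positive integer
#' @examples
#' degeneracy("CGCCCGCTSTGGGAGATG")  # 2
#' @export
degeneracy <- function(primer) {
  ch <- seq_chars(primer)
  .check_alphabet(paste(ch, collapse = ""), setdiff(.NUC_ALPHABET, "-"),
                  "nucleotide")
  prod(vapply(ch, function(b) length(.IUPAC_SETS[[b]]), numeric(1)))
}

#' All plain-base expansions of an IUPAC string
#'
#' Intended for small degeneracies (primer verification); expansion count
#' equals [degeneracy()].
#'
#' @inheritParams degeneracy
#' @return character vector of A/C/G/T strings
#' @export
expand_degenerate <- function(primer) {
  sets <- lapply(seq_chars(primer), function(b) .IUPAC_SETS[[b]])
  out <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  sort(apply(out, 1, paste, collapse = ""))
}

#' Wallace-rule melting temperature of a (degenerate) primer
#'
#' 2 °C per A/T and 4 °C per G/C; a degenerate position contributes the
#' average over its base set (so S counts 4, R counts 3, N counts 3).
#'
#' @inheritParams degeneracy
#' @return estimated melting temperature in °C
#' @export
melting_temp <- function(primer) {
  ch <- seq_chars(primer)
  if (length(ch) < 8) stop("primer shorter than 8 nt", call. = FALSE)
  per_base <- c(A = 2, T = 2, G = 4, C = 4)
  sum(vapply(ch, function(b) mean(per_base[.IUPAC_SETS[[b]]]), numeric(1)))
}

#' Reverse translate a peptide into a degenerate oligonucleotide
#'
#' Residues are processed left to right. For each residue the synonymous
#' codons are taken in descending usage order (ties alphabetical) and merged
#' position-wise into one IUPAC codon, adding codons while (a) every
#' expansion of the merged codon still translates to the residue and (b)
#' the total primer degeneracy stays within `degeneracy_cap`. At minimum the
#' single most-used codon is taken, so any expansion of the result
#' translates back to `p`.
#'
#' @param p peptide (no wildcards)
#' @param usage codon usage table (see [codon_usage_uniform()])
#' @param degeneracy_cap maximum total degeneracy (default 128)
#' @return IUPAC nucleotide string of length `3 * nchar(p)`
#' @export
reverse_translate <- function(p, usage = codon_usage_uniform(),
                              degeneracy_cap = 128) {
  if (degeneracy_cap < 1) stop("degeneracy_cap must be >= 1", call. = FALSE)
  usage <- .validate_usage(usage)
  res <- seq_chars(p)
  if (any(!res %in% setdiff(.AA_ALPHABET, c("*", "X", "-"))))
    stop("peptide contains wildcard or invalid residues", call. = FALSE)
  total <- 1
  out <- character(length(res))
  for (i in seq_along(res)) {
    cods <- .codons_for(usage, res[i])$codon
    chosen <- cods[1]
    merged <- chosen
    deg <- 1
    for (k in seq_along(cods)[-1]) {
      cand <- .merge_codons(c(chosen, cods[k]))
      cand_deg <- degeneracy(cand)
      if (total * cand_deg > degeneracy_cap) break
      exps <- expand_degenerate(cand)
      if (!all(vapply(exps, function(e) translate(e) == res[i], logical(1))))
        next  # merging would admit codons of another residue
      chosen <- c(chosen, cods[k])
      merged <- cand
      deg <- cand_deg
    }
    out[i] <- merged
    total <- total * deg
  }
  paste(out, collapse = "")
}

# Position-wise union of plain codons into one IUPAC codon.
.merge_codons <- function(codons) {
  mat <- vapply(codons, seq_chars, character(3))
  paste(vapply(1:3, function(i) .iupac_code(unique(mat[i, ])), character(1)),
        collapse = "")
}

.iupac_code <- function(bases) {
  bases <- sort(unique(bases))
  for (code in names(.IUPAC_SETS))
    if (identical(sort(.IUPAC_SETS[[code]]), bases)) return(code)
  stop("no IUPAC code for base set ", paste(bases, collapse = ""), call. = FALSE)
}

# Map an alignment column to the ungapped residue coordinate of a reference
# row (position of the last non-gap residue at or before the column).
.ungapped_pos <- function(row_chars, column) {
  sum(row_chars[seq_len(column)] != "-")
}

#' Design degenerate primer pairs from conserved blocks
#'
#' Every ordered pair of conserved blocks whose implied product size falls
#' in `product_range` yields a primer pair. The product spans the first
#' nucleotide of the upstream block's first codon through the last
#' nucleotide of the downstream block's last codon, on the ungapped
#' coordinates of `reference_row`; with 1-based codons s and e the size is
#' `3*e - 3*s + 3` bp. The reverse primer is emitted 5'->3' as synthesized,
#' i.e. the reverse complement of the coding-strand anchor. An optional
#' `flank` of 1-2 nt extends each primer into the adjacent consensus codon
#' (using its modal codon under `usage`), reproducing the partial-codon ends
#' seen in hand-designed degenerate primers; flanks do not enter the product
#' size arithmetic.
#'
#' @inheritParams find_conserved_blocks
#' @param usage codon usage table for reverse translation
#' @param product_range numeric length-2, acceptable product size in bp
#' @param degeneracy_cap maximum degeneracy per primer
#' @param reference_row index or name of the alignment row whose ungapped
#'   coordinates define codon numbering (default 1)
#' @param flank 0, 1 or 2 nt of adjacent-codon extension at each primer's
#'   inner end
#' @return data.frame, one row per pair: name, forward, reverse, anchor
#'   peptides, codon coordinates, degeneracies, melting temperatures,
#'   product_size
#' @export
design_primer_pairs <- function(aln, usage = codon_usage_uniform(),
                                product_range = c(600, 1000),
                                min_len = 5, min_score = 0.9,
                                degeneracy_cap = 128,
                                reference_row = 1, flank = 0) {
  stopifnot(length(product_range) == 2, flank %in% 0:2)
  blocks <- find_conserved_blocks(aln, min_len = min_len, min_score = min_score)
  if (nrow(blocks) < 2)
    stop("need at least two conserved blocks to design a pair", call. = FALSE)
  ref <- seq_chars(aln[[reference_row]])
  cons <- .consensus(.aln_matrix(aln))
  blocks$codon_start <- vapply(blocks$start, function(cl) .ungapped_pos(ref, cl),
                               numeric(1))
  blocks$codon_end <- vapply(blocks$end, function(cl) .ungapped_pos(ref, cl),
                             numeric(1))
  out <- list()
  for (i in seq_len(nrow(blocks) - 1)) {
    for (j in (i + 1):nrow(blocks)) {
      s <- blocks$codon_start[i]
      e <- blocks$codon_end[j]
      size <- 3 * e - 3 * s + 3
      if (size < product_range[1] || size > product_range[2]) next
      fwd_anchor <- blocks$consensus[i]
      rev_anchor <- blocks$consensus[j]
      fwd <- reverse_translate(fwd_anchor, usage, degeneracy_cap)
      rev_coding <- reverse_translate(rev_anchor, usage, degeneracy_cap)
      if (flank > 0) {
        nxt <- if (blocks$end[i] < length(cons)) cons[blocks$end[i] + 1] else "-"
        prv <- if (blocks$start[j] > 1) cons[blocks$start[j] - 1] else "-"
        if (nxt != "-")
          fwd <- paste0(fwd, substr(.modal_codon(usage, nxt), 1, flank))
        if (prv != "-") {
          pc <- .modal_codon(usage, prv)
          rev_coding <- paste0(substr(pc, 4 - flank, 3), rev_coding)
        }
      }
      rv <- revcomp(rev_coding)
      out[[length(out) + 1]] <- data.frame(
        name = sprintf("blk%d_blk%d", s, e),
        forward = fwd, reverse = rv,
        forward_anchor = fwd_anchor, reverse_anchor = rev_anchor,
        forward_codon_start = s, reverse_codon_end = e,
        forward_degeneracy = degeneracy(fwd),
        reverse_degeneracy = degeneracy(rv),
        forward_tm = melting_temp(fwd), reverse_tm = melting_temp(rv),
        product_size = size,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(name = character(0), forward = character(0),
                      reverse = character(0), forward_anchor = character(0),
                      reverse_anchor = character(0),
                      forward_codon_start = numeric(0),
                      reverse_codon_end = numeric(0),
                      forward_degeneracy = numeric(0),
                      reverse_degeneracy = numeric(0),
                      forward_tm = numeric(0), reverse_tm = numeric(0),
                      product_size = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Primer pairs printed for the WS/DGAT survey
#'
#' The degenerate and genus-specific pairs used to amplify bacterial
#' *ws/dgat* genes, as published: TgsX-up/down (Actinobacteria and
#' gamma-Proteobacteria, ~800 bp), AAP-F/R alias Gram-F/R (Gram-negative
#' bacteria), RhodoF/R (*Rhodococcus*; the Methods text and the primer
#' table print different sequences under the same names, so both variants
#' are shipped), Maratf1/Mar130F (*Marinobacter*), and the
#' actinomycete-specific 16S rDNA pair Act-0235/Act-0878.
#'
#' @return data.frame: name, sequence (5'->3'), orientation, pair, variant
#' @export
printed_primers <- function() {
  data.frame(
    name = c("TgsXup", "TgsXdown",
             "AAP-F", "AAP-R",
             "RhodoF", "RhodoR",
             "RhodoF", "RhodoR",
             "Maratf1", "Mar130F",
             "Act-0235", "Act-0878"),
    sequence = c("CGCCCGCTSTGGGAGATG", "CGGGCCSGSGACGTTSGA",
                 "CARCCYATGCAYGTWGG", "ATMAYCASRTTGAAGGC",
                 "GCAYCCSATGCACGTGGG", "ATCACGTTGAACGGCGG",
                 "CCGATGTGGGARMTGCAC", "ATSATCACGTTGAACGGC",
                 "ACGCCCCTGAATCCCACT", "TGTCATGTTCAGGGCCAGYC",
                 "CGCGGCCTATCAGCTTGTTG", "CCGTACTCCCCAGGCGGGG"),
    orientation = rep(c("forward", "reverse"), 6),
    pair = rep(c("TgsX", "AAP", "Rhodo", "Rhodo", "Marat", "Act16S"),
               each = 2),
    variant = c("methods", "methods", "methods", "methods",
                "methods", "methods", "table", "table",
                "methods", "methods", "methods", "methods"),
    stringsAsFactors = FALSE)
}
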