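#' @importFrom stats as.dist cutree hclust setNames runif
#' @importFrom utils read.delim write.table combn head tail
NULL

# IUPAC nucleotide algebra ----------------------------------------------------

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_COMP <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

.NUC_ALPHABET <- c(names(.IUPAC_SETS), "-")

# precomputed pairwise compatibility over the IUPAC alphabet plus gap
# (gaps never match); used by the vectorized scanners
.COMPAT_CODES <- .NUC_ALPHABET
.COMPAT_MAT <- local({
  n <- length(.COMPAT_CODES)
  m <- matrix(FALSE, n, n, dimnames = list(.COMPAT_CODES, .COMPAT_CODES))
  for (a in names(.IUPAC_SETS)) for (b in names(.IUPAC_SETS))
    m[a, b] <- length(intersect(.IUPAC_SETS[[a]], .IUPAC_SETS[[b]])) > 0
  m
})

# logical vector over all windows: does `site` match tmpl at each offset?
.iupac_window_hits <- function(tmpl_idx, site_chars) {
  m <- length(site_chars)
  n <- length(tmpl_idx)
  if (n < m) return(logical(0))
  si <- match(site_chars, .COMPAT_CODES)
  noff <- n - m + 1
  hit <- rep(TRUE, noff)
  for (i in seq_len(m))
    hit <- hit & .COMPAT_MAT[cbind(si[i], tmpl_idx[i:(i + noff - 1)])]
  hit
}
.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*", "X", "-")

.check_alphabet <- function(s, alphabet, what = "sequence") {
  ch <- unique(strsplit(s, "")[[1]])
  bad <- setdiff(ch, alphabet)
  if (length(bad) > 0)
    stop(sprintf("invalid %s character(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Split a sequence string into single characters
#' @param s a character scalar
#' @return character vector of single letters
#' @keywords internal
seq_chars <- function(s) strsplit(toupper(s), "")[[1]]

# rows = sequences, columns = positions; robust to single-position inputs
.seq_matrix <- function(seqs) {
  L <- nchar(seqs[[1]])
  m <- vapply(seqs, seq_chars, character(L))
  if (is.null(dim(m))) m <- matrix(m, nrow = L, dimnames = list(NULL, names(seqs)))
  t(m)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' IUPAC ambiguity codes are complemented set-wise (R <-> Y, S and W are
#' self-complementary, ...), so `revcomp` is an involution on the full
#' degenerate alphabet. Gap characters are rejected.
#'
#' @param s nucleotide string (A/C/G/T plus IUPAC ambiguity codes)
#' @return the reverse complement, same length
#' @examples
#' revcomp("ATGC")    # "GCAT"
#' revcomp("GTYRAC")  # HincII site, its own reverse complement
#' @export
revcomp <- function(s) {
  ch <- seq_chars(s)
  .check_alphabet(paste(ch, collapse = ""), setdiff(.NUC_ALPHABET, "-"),
                  "nucleotide")
  paste(rev(unname(.IUPAC_COMP[ch])), collapse = "")
}

#' Do two IUPAC codes denote intersecting base sets?
#'
#' `N` intersects everything; a gap never matches anything (including
#' another gap).
#'
#' @param a,b single IUPAC nucleotide codes (vectorised, recycled)
#' @return logical vector
#' @examples
#' iupac_compatible("S", "G")  # TRUE,  {C,G} meets {G}
#' iupac_compatible("R", "Y")  # FALSE, {A,G} vs {C,T}
#' @export
iupac_compatible <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  ok <- function(x) x %in% names(.IUPAC_SETS) | x == "-"
  if (!all(ok(a)) || !all(ok(b)))
    stop("non-IUPAC code passed to iupac_compatible", call. = FALSE)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) {
    if (a[i] == "-" || b[i] == "-") return(FALSE)
    length(intersect(.IUPAC_SETS[[a[i]]], .IUPAC_SETS[[b[i]]])) > 0
  }, logical(1))
}

# Translation ------------------------------------------------------------------

.GENETIC_CODE <- Biostrings::GENETIC_CODE

#' Translate a nucleotide sequence
#'
#' Standard genetic code; stops become `*`. Any codon containing an
#' ambiguity code or gap translates to `X` (deterministic flagging rather
#' than expansion). A trailing partial codon is dropped.
#'
#' @param s nucleotide string
#' @param frame 0, 1 or 2 (bases skipped before the first codon)
#' @return amino-acid string
#' @examples
#' translate("ACGCCCCTGAATCCCACT")  # "TPLNPT"
#' @export
translate <- function(s, frame = 0) {
  stopifnot(frame %in% 0:2)
  ch <- seq_chars(s)
  .check_alphabet(paste(ch, collapse = ""), .NUC_ALPHABET, "nucleotide")
  usable <- length(ch) - frame
  if (usable < 3) stop("sequence shorter than one codon", call. = FALSE)
  n_codon <- usable %/% 3
  idx <- frame + seq_len(n_codon * 3)
  codons <- apply(matrix(ch[idx], nrow = 3), 2, paste, collapse = "")
  aa <- .GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"   # ambiguous or gapped codon
  paste(aa, collapse = "")
}

# Motifs -----------------------------------------------------------------------

#' Find a peptide motif with single-residue wildcards
#'
#' Lowercase `x` in the pattern matches any one residue (the convention of
#' the WS/DGAT active-site motif HHxxxDG). Overlapping occurrences are all
#' reported.
#'
#' @param p amino-acid string
#' @param pattern motif such as `"HHxxxDG"` or `"ND"`
#' @return integer vector of 1-based start positions (possibly empty)
#' @examples
#' find_motif("MKHHAVIDGLND", "HHxxxDG")  # 3
#' find_motif("MKHHAVIDGLND", "ND")       # 11
#' @export
find_motif <- function(p, pattern) {
  if (nchar(pattern) < 2) stop("motif pattern must have length >= 2", call. = FALSE)
  pc <- strsplit(pattern, "")[[1]]
  sc <- seq_chars(p)
  m <- length(pc); n <- length(sc)
  if (n < m) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - m + 1)) {
    win <- sc[i:(i + m - 1)]
    if (all(pc == "x" | win == toupper(pc))) hits <- c(hits, i)
  }
  hits
}

# FASTA I/O --------------------------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read; duplicate ids are an error. Both
#' wrapped and single-line records are accepted.
#'
#' @param path FASTA file
#' @param type `"nuc"` or `"prot"`; controls the alphabet check
#' @return named character vector (possibly empty)
#' @export
read_fasta <- function(path, type = c("nuc", "prot")) {
  type <- match.arg(type)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  alpha <- if (type == "nuc") .NUC_ALPHABET else .AA_ALPHABET
  for (i in seq_along(seqs)) .check_alphabet(seqs[i], alpha, type)
  seqs
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output file
#' @param width line-wrap width
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
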