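# Codon usage tables: data.frame(codon, amino_acid, relative_frequency),
# frequencies summing to 1 within each amino acid.

.codon_table <- function() {
  codons <- names(.GENETIC_CODE)
  data.frame(codon = codons, amino_acid = unname(.GENETIC_CODE),
             stringsAsFactors = FALSE)
}

.validate_usage <- function(usage) {
  need <- c("codon", "amino_acid", "relative_frequency")
  if (!all(need %in% names(usage)))
    stop("codon usage table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  usage$codon <- toupper(usage$codon)
  usage$amino_acid <- toupper(usage$amino_acid)
  tr <- unname(.GENETIC_CODE[usage$codon])
  if (any(is.na(tr)) || any(tr != usage$amino_acid))
    stop("codon usage table contains codons not translating to their amino acid",
         call. = FALSE)
  aa20 <- setdiff(unique(unname(.GENETIC_CODE)), "*")
  missing <- setdiff(aa20, usage$amino_acid)
  if (length(missing) > 0)
    stop("codon usage table missing amino acid(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sums <- tapply(usage$relative_frequency, usage$amino_acid, sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("relative frequencies must sum to 1 per amino acid", call. = FALSE)
  usage
}

#' Uniform codon usage table
#'
#' Every synonymous codon of an amino acid gets equal relative frequency.
#' Useful as a neutral default when no organism-specific table is given.
#'
#' @return data.frame with columns codon, amino_acid, relative_frequency
#' @export
codon_usage_uniform <- function() {
  tab <- .codon_table()
  tab <- tab[tab$amino_acid != "*", ]
  n <- table(tab$amino_acid)
  tab$relative_frequency <- 1 / as.numeric(n[tab$amino_acid])
  rownames(tab) <- NULL
  .validate_usage(tab)
}

#' GC-biased codon usage table
#'
#' Weights synonymous codons by the share of G/C at the third position,
#' emulating the strong GC3 bias of actinobacterial genomes. `gc3` is the
#' weight multiplier per G or C at codon position 3.
#'
#' @param gc3 relative weight of a G/C third base (default 4, strongly biased)
#' @return codon usage data.frame
#' @export
codon_usage_gc_biased <- function(gc3 = 4) {
  stopifnot(gc3 > 0)
  tab <- .codon_table()
  tab <- tab[tab$amino_acid != "*", ]
  third <- substr(tab$codon, 3, 3)
  w <- ifelse(third %in% c("G", "C"), gc3, 1)
  tot <- tapply(w, tab$amino_acid, sum)
  tab$relative_frequency <- w / as.numeric(tot[tab$amino_acid])
  rownames(tab) <- NULL
  .validate_usage(tab)
}

#' Read / write a codon usage table (TSV)
#'
#' Columns: codon, amino_acid, relative_frequency.
#'
#' @param path TSV file
#' @return validated codon usage data.frame
#' @export
read_codon_usage <- function(path) {
  .validate_usage(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_codon_usage
#' @param usage codon usage data.frame
#' @export
write_codon_usage <- function(usage, path) {
  write.table(.validate_usage(usage), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Codons of one residue, highest usage first, ties alphabetical.
.codons_for <- function(usage, aa) {
  sub <- usage[usage$amino_acid == aa, ]
  sub <- sub[order(-sub$relative_frequency, sub$codon), ]
  sub
}

.modal_codon <- function(usage, aa) .codons_for(usage, aa)$codon[1]
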