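# In-silico PCR: degenerate primer binding-site search and amplicon
# prediction on resolved (A/C/G/T) templates.

.check_template <- function(template) {
  .check_alphabet(toupper(template), c("A", "C", "G", "T"), "template")
}

# Positions along a plain-base template where an IUPAC query matches with
# <= max_mismatch incompatibilities and an exact (compatible) 3'-terminal
# window. `three_prime_left = TRUE` when the query's 3' end is its leftmost
# position (minus-strand search with the reverse-complemented primer).
.scan <- function(tmpl_chars, query, max_mismatch, three_prime_exact,
                  three_prime_left = FALSE) {
  q <- seq_chars(query)
  m <- length(q)
  n <- length(tmpl_chars)
  if (n < m) return(data.frame(start = integer(0), mismatches = integer(0)))
  tp <- if (three_prime_left) seq_len(min(three_prime_exact, m))
        else (m - min(three_prime_exact, m) + 1):m
  qi <- match(q, .COMPAT_CODES)
  ti <- match(tmpl_chars, .COMPAT_CODES)
  noff <- n - m + 1
  mism <- integer(noff)
  ok3 <- rep(TRUE, noff)
  for (i in seq_len(m)) {
    compat <- .COMPAT_MAT[cbind(qi[i], ti[i:(i + noff - 1)])]
    mism <- mism + !compat
    if (i %in% tp) ok3 <- ok3 & compat
  }
  sel <- ok3 & mism <= max_mismatch
  data.frame(start = which(sel), mismatches = mism[sel])
}

#' Find binding sites of a degenerate primer on a template
#'
#' Both strands are searched. A site is reported when at most
#' `max_mismatch` positions fail IUPAC compatibility and the
#' `three_prime_exact` bases at the primer's 3' end all match (the PCR
#' 3'-extension requirement). Starts are 1-based on the plus strand of the
#' matched region; on the minus strand the primer's 3' end faces the start
#' of the region.
#'
#' @param template plain A/C/G/T string (ambiguity codes are rejected:
#'   templates are resolved clone or genome sequence)
#' @param primer IUPAC string
#' @param max_mismatch mismatch budget outside the 3' window (default 2)
#' @param three_prime_exact length of the exact-match 3' window (default 3)
#' @return data.frame: strand (`+`/`-`), start, mismatches
#' @export
find_binding_sites <- function(template, primer, max_mismatch = 2,
                               three_prime_exact = 3) {
  .check_template(template)
  tmpl <- seq_chars(template)
  plus <- .scan(tmpl, primer, max_mismatch, three_prime_exact)
  minus <- .scan(tmpl, revcomp(primer), max_mismatch, three_prime_exact,
                 three_prime_left = TRUE)
  out <- rbind(
    if (nrow(plus)) cbind(strand = "+", plus),
    if (nrow(minus)) cbind(strand = "-", minus))
  if (is.null(out))
    out <- data.frame(strand = character(0), start = integer(0),
                      mismatches = integer(0))
  out[order(out$start), , drop = FALSE]
}

#' Predict PCR products of a primer pair on a template
#'
#' Reports every convergent forward-site/reverse-site combination whose
#' product length falls within `size_range`: forward primer on the plus
#' strand upstream of a reverse primer on the minus strand, and the
#' mirror-image orientation on the other strand. Amplicon sequences are
#' strand-normalized (forward-primer end first); coordinates are 1-based
#' inclusive on the plus strand of the template.
#'
#' @inheritParams find_binding_sites
#' @param forward,reverse IUPAC primer strings (reverse as synthesized,
#'   5'->3')
#' @param size_range length-2 numeric, accepted product sizes in bp
#' @return data.frame: template start/end, length, strand of the forward
#'   primer, sequence, forward/reverse mismatch counts; sorted by start
#'   then length
#' @export
amplify <- function(template, forward, reverse, max_mismatch = 2,
                    three_prime_exact = 3, size_range = c(1, Inf)) {
  .check_template(template)
  tmpl <- seq_chars(template)
  n <- length(tmpl)
  lf <- nchar(forward); lr <- nchar(reverse)
  fsites <- find_binding_sites(template, forward, max_mismatch, three_prime_exact)
  rsites <- find_binding_sites(template, reverse, max_mismatch, three_prime_exact)
  out <- list()
  add <- function(start, end, fwd_strand, fmm, rmm) {
    seq <- paste(tmpl[start:end], collapse = "")
    if (fwd_strand == "-") seq <- revcomp(seq)
    out[[length(out) + 1]] <<- data.frame(
      start = start, end = end, length = end - start + 1,
      forward_strand = fwd_strand, sequence = seq,
      forward_mismatches = fmm, reverse_mismatches = rmm,
      stringsAsFactors = FALSE)
  }
  # forward on plus, reverse on minus, convergent
  fp <- fsites[fsites$strand == "+", ]
  rm_ <- rsites[rsites$strand == "-", ]
  for (i in seq_len(nrow(fp))) for (j in seq_len(nrow(rm_))) {
    start <- fp$start[i]
    end <- rm_$start[j] + lr - 1
    len <- end - start + 1
    if (rm_$start[j] >= start && len >= size_range[1] && len <= size_range[2])
      add(start, end, "+", fp$mismatches[i], rm_$mismatches[j])
  }
  # forward on minus, reverse on plus (product read off the minus strand)
  fm <- fsites[fsites$strand == "-", ]
  rp <- rsites[rsites$strand == "+", ]
  for (i in seq_len(nrow(fm))) for (j in seq_len(nrow(rp))) {
    start <- rp$start[j]
    end <- fm$start[i] + lf - 1
    len <- end - start + 1
    if (fm$start[i] >= start && len >= size_range[1] && len <= size_range[2])
      add(start, end, "-", fm$mismatches[i], rp$mismatches[j])
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), forward_strand = character(0),
                      sequence = character(0), forward_mismatches = integer(0),
                      reverse_mismatches = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pure-culture style validation panel
#'
#' Runs every primer pair against every template and reports whether at
#' least one product within the pair's size window is predicted — the
#' in-silico analogue of a positive/negative amplification panel on genomic
#' DNA from reference strains.
#'
#' @param pairs data.frame with columns name, forward, reverse and
#'   optionally size_min, size_max (defaults: any size)
#' @param templates named character vector of templates
#' @param max_mismatch,three_prime_exact matching stringency
#' @return list with `amplified` (logical template x pair matrix) and
#'   `sizes` (character matrix of predicted sizes, "" when negative)
#' @export
validation_panel <- function(pairs, templates, max_mismatch = 2,
                             three_prime_exact = 3) {
  stopifnot(all(c("name", "forward", "reverse") %in% names(pairs)))
  amp <- matrix(FALSE, nrow = length(templates), ncol = nrow(pairs),
                dimnames = list(names(templates), pairs$name))
  sizes <- matrix("", nrow = length(templates), ncol = nrow(pairs),
                  dimnames = dimnames(amp))
  for (ti in seq_along(templates)) for (pi in seq_len(nrow(pairs))) {
    rng <- c(if (!is.null(pairs$size_min)) pairs$size_min[pi] else 1,
             if (!is.null(pairs$size_max)) pairs$size_max[pi] else Inf)
    prods <- amplify(templates[[ti]], pairs$forward[pi], pairs$reverse[pi],
                     max_mismatch, three_prime_exact, size_range = rng)
    amp[ti, pi] <- nrow(prods) > 0
    if (nrow(prods) > 0)
      sizes[ti, pi] <- paste(sort(unique(prods$length)), collapse = ",")
  }
  list(amplified = amp, sizes = sizes)
}

#' Render a validation panel as a character table
#'
#' Cells show `+ <size bp>` for positive template/pair combinations and
#' `-` for negatives.
#'
#' @param panel result of [validation_panel()]
#' @return character matrix (templates x pairs)
#' @export
report_validation <- function(panel) {
  out <- ifelse(panel$amplified, paste0("+ ", panel$sizes, " bp"), "-")
  dimnames(out) <- dimnames(panel$amplified)
  out
}
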