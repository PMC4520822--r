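# Clone-library processing: size filter, primer trimming, in-silico RFLP
# dereplication, reading-frame selection, active-site motif screen, and a
# split-half chimera flag.

#' Restriction enzymes used for RFLP dereplication
#'
#' HhaI (GCG^C) and HincII (GTY^RAC); both sites are their own reverse
#' complements, so digestion is strand-invariant. `offset` is the cut
#' position in nt from the site start on the top strand.
#'
#' @return data.frame: name, site (IUPAC), offset
#' @export
enzymes <- function() {
  data.frame(name = c("HhaI", "HincII"),
             site = c("GCGC", "GTYRAC"),
             offset = c(3L, 3L),
             stringsAsFactors = FALSE)
}

#' Read an enzyme definition table (TSV: name, site, offset)
#' @param path TSV file
#' @return data.frame like [enzymes()]
#' @export
read_enzymes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "site", "offset") %in% names(tab)))
  bad <- tab$offset < 0 | tab$offset > nchar(tab$site)
  if (any(bad)) stop("cut offset outside recognition site", call. = FALSE)
  tab
}

.get_enzyme <- function(enzyme) {
  if (is.character(enzyme)) {
    tab <- enzymes()
    row <- tab[tab$name == enzyme, ]
    if (nrow(row) != 1) stop("unknown enzyme: ", enzyme, call. = FALSE)
    return(row)
  }
  stopifnot(all(c("site", "offset") %in% names(enzyme)))
  enzyme[1, ]
}

#' Complete restriction digest of a sequence
#'
#' Cuts at every occurrence of the recognition site (overlapping sites all
#' cut, i.e. complete-digest semantics) at `offset` nt from the site start.
#' Fragment lengths always sum to the input length.
#'
#' @param seq plain A/C/G/T sequence
#' @param enzyme an enzyme name ("HhaI", "HincII") or a one-row data.frame
#'   with columns site and offset
#' @return sorted integer vector of fragment lengths
#' @examples
#' digest("AAGCGCTT", "HhaI")      # 3 5
#' digest("AAGTTAACTT", "HincII")  # 5 5
#' @export
digest <- function(seq, enzyme) {
  .check_template(seq)
  enz <- .get_enzyme(enzyme)
  ch <- seq_chars(seq)
  site <- seq_chars(enz$site)
  n <- length(ch)
  hits <- which(.iupac_window_hits(match(ch, .COMPAT_CODES), site))
  cuts <- hits + enz$offset - 1   # cut after this position
  cuts <- sort(unique(cuts[cuts >= 1 & cuts < n]))
  sort(diff(c(0, cuts, n)))
}

#' Filter clones by insert size
#'
#' Keeps clones whose length is within `tolerance_fraction * expected_bp`
#' of the expected size (inclusive); others are flagged `undersized` or
#' `oversized` — the in-silico analogue of discarding inserts that do not
#' run at the expected size.
#'
#' @param clones named character vector of clone sequences
#' @param expected_bp expected insert size
#' @param tolerance_fraction accepted relative deviation (default 0.15)
#' @return list with `kept` (named character vector) and `discarded`
#'   (data.frame id, length, flag)
#' @export
size_filter <- function(clones, expected_bp, tolerance_fraction = 0.15) {
  stopifnot(expected_bp > 0)
  len <- nchar(clones)
  ok <- abs(len - expected_bp) <= tolerance_fraction * expected_bp
  disc <- data.frame(id = names(clones)[!ok], length = len[!ok],
                     flag = ifelse(len[!ok] < expected_bp,
                                   "undersized", "oversized"),
                     stringsAsFactors = FALSE)
  rownames(disc) <- NULL
  list(kept = clones[ok], discarded = disc)
}

#' Trim amplification primers off a clone sequence
#'
#' Locates the forward primer at the 5' end and the reverse primer (as its
#' reverse complement) at the 3' end, trying both orientations of the
#' clone, and returns the insert between them normalized to
#' forward-primer-first orientation.
#'
#' @param seq clone sequence (plain bases)
#' @param forward,reverse the amplification primer pair (IUPAC)
#' @param max_mismatch,three_prime_exact matching stringency
#' @return the trimmed insert string, or `NA_character_` when either primer
#'   cannot be located (caller flags the record)
#' @export
trim_primers <- function(seq, forward, reverse, max_mismatch = 2,
                         three_prime_exact = 3) {
  for (s in c(seq, revcomp(seq))) {
    prods <- amplify(s, forward, reverse, max_mismatch, three_prime_exact)
    prods <- prods[prods$forward_strand == "+", , drop = FALSE]
    if (nrow(prods) == 0) next
    # widest product: outermost primer sites
    p <- prods[which.max(prods$length), ]
    inner_start <- p$start + nchar(forward)
    inner_end <- p$end - nchar(reverse)
    if (inner_end < inner_start) return(NA_character_)
    return(substr(s, inner_start, inner_end))
  }
  NA_character_
}

#' Group clones by RFLP fragment pattern
#'
#' Two clones share a pattern iff their sorted fragment-length lists have
#' the same number of fragments and corresponding entries differ by at most
#' `bin_tolerance_bp` (0 by default: in-silico fragments are exact; a
#' positive tolerance emulates gel resolution). Singleton patterns are
#' retained; the representative of a pattern is its lexicographically
#' lowest clone id.
#'
#' @param clones named character vector of trimmed inserts
#' @param enzyme see [digest()]
#' @param bin_tolerance_bp per-fragment length tolerance (default 0)
#' @return data.frame: clone id, pattern id (P1, P2, ... in order of first
#'   appearance over id-sorted clones), fragments (comma string),
#'   representative (logical)
#' @export
group_by_pattern <- function(clones, enzyme, bin_tolerance_bp = 0) {
  ids <- sort(names(clones))
  frags <- lapply(clones[ids], digest, enzyme = enzyme)
  pat_of <- integer(length(ids))
  exemplars <- list()
  for (i in seq_along(ids)) {
    f <- frags[[i]]
    hit <- 0
    for (k in seq_along(exemplars)) {
      g <- exemplars[[k]]
      if (length(f) == length(g) && all(abs(f - g) <= bin_tolerance_bp)) {
        hit <- k; break
      }
    }
    if (hit == 0) {
      exemplars[[length(exemplars) + 1]] <- f
      hit <- length(exemplars)
    }
    pat_of[i] <- hit
  }
  out <- data.frame(id = ids,
                    pattern = paste0("P", pat_of),
                    fragments = vapply(frags, paste, character(1),
                                       collapse = ","),
                    stringsAsFactors = FALSE)
  out$representative <- FALSE
  for (k in unique(pat_of))
    out$representative[which(pat_of == k)[1]] <- TRUE  # ids sorted => lowest id
  rownames(out) <- NULL
  out
}

#' Choose the reading frame and strand of an insert
#'
#' Among the six frame/strand combinations, picks the translation with the
#' fewest stop codons; ties are broken by presence of the HHxxxDG
#' active-site motif, then by plus strand before minus and lowest frame
#' index — a deterministic stand-in for how one settles the frame of a
#' protein-coding amplicon before translation.
#'
#' @param insert nucleotide string, length >= 60
#' @return list: frame (0/1/2), strand ("+"/"-"), translation
#' @export
best_frame <- function(insert) {
  if (nchar(insert) < 60) stop("insert shorter than 60 nt", call. = FALSE)
  cand <- expand.grid(frame = 0:2, strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  cand <- cand[order(match(cand$strand, c("+", "-")), cand$frame), ]
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    s <- if (cand$strand[i] == "+") insert else revcomp(insert)
    tr <- translate(s, cand$frame[i])
    stops <- lengths(regmatches(tr, gregexpr("*", tr, fixed = TRUE)))
    has_motif <- length(find_motif(tr, "HHxxxDG")) > 0
    score <- c(stops, -as.integer(has_motif))
    if (is.null(best) || stops < best$stops ||
        (stops == best$stops && has_motif && !best$has_motif)) {
      best <- list(frame = cand$frame[i], strand = cand$strand[i],
                   translation = tr, stops = stops, has_motif = has_motif)
    }
  }
  best[c("frame", "strand", "translation")]
}

#' Screen a translated clone for conserved WS/DGAT motifs
#'
#' Checks the active-site heptapeptide HHxxxDG and the ND motif. The PLW
#' motif is reported as skipped when the amplifying primer covers it (it is
#' then primer-derived, not informative); otherwise it is evaluated too.
#'
#' @param translation amino-acid string
#' @param plw_in_primer logical; TRUE when the primer pair spans the PLW
#'   motif (e.g. the TgsX forward anchor RPLWEM)
#' @return data.frame: motif, status ("present"/"absent"/"skipped"),
#'   position (first occurrence, NA otherwise)
#' @export
screen_motifs <- function(translation, plw_in_primer = FALSE) {
  stopifnot(nchar(translation) > 0)
  one <- function(motif) {
    pos <- find_motif(translation, motif)
    data.frame(motif = motif,
               status = if (length(pos)) "present" else "absent",
               position = if (length(pos)) pos[1] else NA_integer_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("HHxxxDG"), one("ND"))
  plw <- if (plw_in_primer)
    data.frame(motif = "PLW", status = "skipped", position = NA_integer_,
               stringsAsFactors = FALSE)
  else one("PLW")
  rbind(out, plw)
}

#' Flag chimeric clones by split-half nearest references
#'
#' A deliberately simple screen with the same intent as reference-based
#' chimera detectors: each insert is split at its midpoint, each half is
#' assigned its nearest reference by p-distance (computed over the
#' corresponding reference half), and the clone is flagged when the two
#' halves disagree on the nearest reference and each half is closer to its
#' own best reference than to the other half's best by more than `delta`.
#'
#' @param clones named character vector of trimmed inserts
#' @param references named character vector (>= 2) of trusted full-length
#'   inserts on the same coordinates
#' @param delta distance margin (default 0.05)
#' @return named logical vector over the clone ids
#' @export
flag_chimeras <- function(clones, references, delta = 0.05) {
  if (length(references) < 2)
    stop("need at least 2 references for chimera screening", call. = FALSE)
  vapply(clones, function(cl) {
    n <- nchar(cl)
    mid <- n %/% 2
    halves <- c(substr(cl, 1, mid), substr(cl, mid + 1, n))
    d <- vapply(references, function(r) {
      m <- min(nchar(r), n)
      c(.pdist_str(substr(cl, 1, mid), substr(r, 1, mid)),
        .pdist_str(substr(cl, mid + 1, m), substr(r, mid + 1, m)))
    }, numeric(2))
    b1 <- which.min(d[1, ]); b2 <- which.min(d[2, ])
    if (b1 == b2) return(FALSE)
    (d[1, b2] - d[1, b1] > delta) && (d[2, b1] - d[2, b2] > delta)
  }, logical(1))
}

# p-distance between two unaligned-but-homologous strings (compared over
# the shorter length; no gap handling — clone/reference coordinates match
# because sequencing errors are substitutions).
.pdist_str <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0)
  ca <- seq_chars(substr(a, 1, n)); cb <- seq_chars(substr(b, 1, n))
  mean(ca != cb)
}
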