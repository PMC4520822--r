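# Synthetic WS/DGAT-like gene families and clone libraries with planted
# ground truth, for end-to-end validation of the survey pipeline.

#' Specification of a synthetic marker-gene family
#'
#' The layout alternates conserved anchor peptides with variable regions,
#' emulating the conserved-block architecture of the WS/DGAT family. The
#' default layout plants a forward primer anchor (RPLWEM), the HHxxxDG
#' active-site motif, the ND motif, and a reverse primer anchor (SNVPAG),
#' spaced so that the anchored product is 798 bp — the ~800 bp product
#' regime of a WS/DGAT degenerate survey. Anchors are never mutated;
#' variable-region residues are substituted i.i.d. per reference at
#' `divergence`.
#'
#' @param n_references number of reference gene variants (default 5)
#' @param layout list alternating anchor peptides (character) and variable
#'   region lengths (numeric); must contain at least two anchors and the
#'   HHxxxDG and ND motifs
#' @param divergence per-site substitution probability in variable regions
#'   (default 0.15)
#' @param usage codon usage table used to encode the proteins
#' @param seed integer seed
#' @return object of class `family_spec`
#' @export
family_spec <- function(n_references = 5,
                        layout = list(8, "RPLWEM", 70, "AHHSLVDGL", 70,
                                      "GVNDAL", 99, "SNVPAG", 10),
                        divergence = 0.15,
                        usage = codon_usage_uniform(),
                        seed = 42) {
  anchors <- unlist(layout[vapply(layout, is.character, logical(1))])
  if (length(anchors) < 2)
    stop("layout must contain at least two anchor peptides", call. = FALSE)
  full <- paste(anchors, collapse = "")
  if (length(find_motif(full, "HHxxxDG")) == 0 ||
      length(find_motif(full, "ND")) == 0)
    stop("layout anchors must include the HHxxxDG and ND motifs", call. = FALSE)
  stopifnot(divergence >= 0, divergence <= 1, n_references >= 1)
  structure(list(n_references = n_references, layout = layout,
                 divergence = divergence, usage = .validate_usage(usage),
                 seed = seed),
            class = "family_spec")
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a synthetic reference gene family
#'
#' Builds a base protein from the layout (random variable regions), then
#' derives each reference by substituting variable-region sites i.i.d. at
#' the spec's divergence. Anchor residues are identical across references
#' and are encoded with the modal codon of the usage table (conserved at
#' the nucleotide level, as primer-anchor blocks are in real families);
#' variable-region codons are sampled per reference with usage-table
#' weights. Deterministic under the spec's seed.
#'
#' @param spec a [family_spec()]
#' @return list: `proteins`, `cds` (named character vectors ref1..refN),
#'   `anchor_positions` (data.frame anchor, aa_start, aa_end),
#'   `spec`
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  base <- character(0)
  is_var <- logical(0)
  anchor_rows <- list()
  for (el in spec$layout) {
    if (is.character(el)) {
      anchor_rows[[length(anchor_rows) + 1]] <-
        data.frame(anchor = el, aa_start = length(base) + 1,
                   aa_end = length(base) + nchar(el),
                   stringsAsFactors = FALSE)
      base <- c(base, seq_chars(el))
      is_var <- c(is_var, rep(FALSE, nchar(el)))
    } else {
      base <- c(base, sample(.AA20, el, replace = TRUE))
      is_var <- c(is_var, rep(TRUE, el))
    }
  }
  L <- length(base)
  proteins <- character(spec$n_references)
  cds <- character(spec$n_references)
  anchor_codons <- vapply(base, function(aa) .modal_codon(spec$usage, aa),
                          character(1))
  for (r in seq_len(spec$n_references)) {
    prot <- base
    mut <- is_var & runif(L) < spec$divergence
    prot[mut] <- vapply(base[mut], function(aa)
      sample(setdiff(.AA20, aa), 1), character(1))
    codons <- character(L)
    for (i in seq_len(L)) {
      if (!is_var[i]) {
        codons[i] <- anchor_codons[i]
      } else {
        cand <- .codons_for(spec$usage, prot[i])
        codons[i] <- sample(cand$codon, 1, prob = cand$relative_frequency)
      }
    }
    proteins[r] <- paste(prot, collapse = "")
    cds[r] <- paste(codons, collapse = "")
  }
  names(proteins) <- names(cds) <- paste0("ref", seq_len(spec$n_references))
  list(proteins = proteins, cds = cds,
       anchor_positions = do.call(rbind, anchor_rows), spec = spec)
}

#' Specification of a synthetic clone library
#'
#' @param family result of [generate_family()]
#' @param forward,reverse the amplifying primer pair (IUPAC); defaults are
#'   the pair designed from the family's own anchors
#' @param n_clones library size (default 100)
#' @param error_rate per-site substitution (sequencing + polymerase) error
#'   (default 0.01)
#' @param chimera_rate fraction of clones that are midpoint fusions of two
#'   distinct references' amplicons (default 0.10)
#' @param offtarget_rate fraction of clones that are GC-matched shuffles of
#'   amplicon length, lacking the anchors (default 0.05)
#' @param label library label used in clone ids (default "LH"); clones are
#'   named `<label>-<n>l` following marker-gene library conventions
#' @param seed integer seed
#' @return object of class `library_spec`
#' @export
library_spec <- function(family, forward = NULL, reverse = NULL,
                         n_clones = 100, error_rate = 0.01,
                         chimera_rate = 0.10, offtarget_rate = 0.05,
                         label = "LH", seed = 42) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            chimera_rate >= 0, offtarget_rate >= 0,
            chimera_rate + offtarget_rate <= 1)
  if (is.null(forward) || is.null(reverse)) {
    # primers straight off the outermost planted anchors: the synthetic
    # analogue of targeting the family's canonical conserved blocks
    anch <- family$anchor_positions
    forward <- reverse_translate(anch$anchor[1], family$spec$usage)
    reverse <- revcomp(reverse_translate(anch$anchor[nrow(anch)],
                                         family$spec$usage))
  }
  structure(list(family = family, forward = forward, reverse = reverse,
                 n_clones = n_clones, error_rate = error_rate,
                 chimera_rate = chimera_rate, offtarget_rate = offtarget_rate,
                 label = label, seed = seed),
            class = "library_spec")
}

.mutate_nt <- function(s, rate) {
  if (rate == 0) return(s)
  ch <- seq_chars(s)
  hit <- runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}

#' Generate a synthetic clone library with planted truth
#'
#' Each clone is the amplicon of a randomly chosen reference with i.i.d.
#' substitution errors; with probability `chimera_rate` it is instead a
#' midpoint fusion of two distinct references' amplicons, and with
#' probability `offtarget_rate` a base-composition-matched shuffle of an
#' amplicon (so it passes the size filter but fails the motif screen).
#' Byte-identical outputs under the same spec and seed.
#'
#' @param spec a [library_spec()]
#' @return list: `clones` (named character vector), `truth` (data.frame id,
#'   source, source2, is_chimera, is_offtarget), `inserts` (reference
#'   insert sequences on trimmed coordinates), `forward`, `reverse`,
#'   `expected_bp`
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  fam <- spec$family
  amps <- lapply(fam$cds, function(tmpl) {
    a <- amplify(tmpl, spec$forward, spec$reverse)
    if (nrow(a) == 0) stop("family reference not amplifiable by the pair",
                           call. = FALSE)
    a$sequence[which.max(a$length)]
  })
  amps <- unlist(amps)
  expected_bp <- as.integer(round(mean(nchar(amps))))
  inserts <- vapply(amps, function(a)
    substr(a, nchar(spec$forward) + 1, nchar(a) - nchar(spec$reverse)),
    character(1))
  names(inserts) <- names(amps)
  set.seed(spec$seed)
  n <- spec$n_clones
  kind <- sample(c("chimera", "offtarget", "clean"), n, replace = TRUE,
                 prob = c(spec$chimera_rate, spec$offtarget_rate,
                          1 - spec$chimera_rate - spec$offtarget_rate))
  if (length(amps) < 2) kind[kind == "chimera"] <- "clean"
  clones <- character(n)
  truth <- data.frame(id = sprintf("%s-%dl", spec$label, seq_len(n)),
                      source = NA_character_, source2 = NA_character_,
                      is_chimera = FALSE, is_offtarget = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (kind[i] == "chimera") {
      pick <- sample(names(amps), 2)
      a1 <- amps[[pick[1]]]; a2 <- amps[[pick[2]]]
      mid <- nchar(a1) %/% 2
      fused <- paste0(substr(a1, 1, mid), substr(a2, mid + 1, nchar(a2)))
      clones[i] <- .mutate_nt(fused, spec$error_rate)
      truth$source[i] <- pick[1]; truth$source2[i] <- pick[2]
      truth$is_chimera[i] <- TRUE
    } else if (kind[i] == "offtarget") {
      src <- sample(names(amps), 1)
      a <- amps[[src]]
      interior <- seq_chars(substr(a, nchar(spec$forward) + 1,
                                   nchar(a) - nchar(spec$reverse)))
      shuffled <- paste(sample(interior), collapse = "")
      clones[i] <- paste0(substr(a, 1, nchar(spec$forward)), shuffled,
                          substr(a, nchar(a) - nchar(spec$reverse) + 1,
                                 nchar(a)))
      truth$is_offtarget[i] <- TRUE
    } else {
      src <- sample(names(amps), 1)
      clones[i] <- .mutate_nt(amps[[src]], spec$error_rate)
      truth$source[i] <- src
    }
  }
  names(clones) <- truth$id
  list(clones = clones, truth = truth, inserts = inserts,
       forward = spec$forward, reverse = spec$reverse,
       expected_bp = expected_bp)
}

#' Score pipeline outputs against planted truth
#'
#' @param results output of [run_survey()] (needs `clone_report` with id,
#'   type and flag columns)
#' @param truth truth data.frame from [generate_library()]
#' @return list: recovered_type_count, planted_type_count,
#'   type_count_error, chimera_precision, chimera_recall, offtarget_recall,
#'   type_purity (named vector), mean_type_purity
#' @export
score_against_truth <- function(results, truth) {
  rep <- results$clone_report
  if (!setequal(rep$id, truth$id))
    stop("clone ids of results and truth differ", call. = FALSE)
  rep <- rep[match(truth$id, rep$id), ]
  pred_chim <- if ("chimera_call" %in% names(rep))
    !is.na(rep$chimera_call) & rep$chimera_call else rep$flag == "chimera"
  true_chim <- truth$is_chimera
  tp <- sum(pred_chim & true_chim)
  chim_precision <- if (sum(pred_chim) > 0) tp / sum(pred_chim) else NA_real_
  chim_recall <- if (sum(true_chim) > 0) tp / sum(true_chim) else NA_real_
  # an off-target is recalled when any filter removed it before typing
  off_caught <- truth$is_offtarget & rep$flag != "ok"
  off_recall <- if (sum(truth$is_offtarget) > 0)
    sum(off_caught) / sum(truth$is_offtarget) else NA_real_
  typed <- !is.na(rep$type) & rep$flag == "ok" & !is.na(truth$source) &
    !truth$is_chimera
  purity <- if (any(typed)) {
    vapply(split(truth$source[typed], rep$type[typed]), function(src)
      max(table(src)) / length(src), numeric(1))
  } else numeric(0)
  planted <- length(unique(truth$source[!truth$is_chimera &
                                          !truth$is_offtarget &
                                          !is.na(truth$source)]))
  recovered <- length(unique(rep$type[!is.na(rep$type) & rep$flag == "ok"]))
  list(recovered_type_count = recovered,
       planted_type_count = planted,
       type_count_error = recovered - planted,
       chimera_precision = chim_precision,
       chimera_recall = chim_recall,
       offtarget_recall = off_recall,
       type_purity = purity,
       mean_type_purity = if (length(purity)) mean(purity) else NA_real_)
}
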