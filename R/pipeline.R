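# End-to-end survey orchestration: clone library in, sequence types and
# bootstrapped NJ tree out, with per-clone accounting at every stage.

#' Run the full clone-library survey
#'
#' Stages, in fixed order: size filter, primer trimming, RFLP pattern
#' grouping, representative selection, frame selection and translation,
#' conserved-motif screen, split-half chimera flag, distance matrix on the
#' representatives of clean patterns, sequence typing at the cutoff, and a
#' neighbour-joining tree of type representatives with bootstrap supports.
#' Clones removed at any stage keep a named flag (undersized, oversized,
#' trim_error, no_motif, chimera); clean clones inherit the sequence type
#' of their RFLP pattern's representative.
#'
#' @param clones named character vector of raw clone sequences (or a FASTA
#'   path)
#' @param forward,reverse amplification primer pair (IUPAC)
#' @param expected_bp expected amplicon size for the size filter
#' @param size_tolerance relative size window (default 0.15)
#' @param enzyme RFLP enzyme (default "HhaI")
#' @param references optional named character vector (or FASTA path) of
#'   trusted trimmed-insert sequences for the chimera screen; when absent,
#'   motif-passing representatives of multi-member patterns are used
#' @param cutoff sequence-type distance cutoff (default 0.01; scale it to
#'   the divergence structure of the data)
#' @param model distance model for typing and the tree (default
#'   "kimura_protein" on translations; "jukes_cantor" and "p" operate on
#'   the nucleotide inserts)
#' @param bootstrap_reps bootstrap replicates for the tree (default 1000)
#' @param chimera_delta margin for the chimera flag (default 0.05)
#' @param plw_in_primer passed to [screen_motifs()] (default TRUE: the
#'   survey primers cover the PLW element)
#' @param max_mismatch,three_prime_exact primer matching stringency
#' @param seed integer seed (bootstrap resampling)
#' @param out_dir optional directory; when given, writes clone_report.tsv,
#'   sequence_types.tsv, representatives.fasta, tree.nwk, summary.json and
#'   run_log.txt
#' @return list: clone_report (data.frame id, length, pattern, frame,
#'   strand, motifs, flag, type), types (typing table over representatives),
#'   representatives (named vector of typed representative inserts), tree
#'   (`phylo` with supports), summary (stage counts), log (character)
#' @export
run_survey <- function(clones, forward, reverse, expected_bp,
                       size_tolerance = 0.15, enzyme = "HhaI",
                       references = NULL, cutoff = 0.01,
                       model = "kimura_protein", bootstrap_reps = 1000,
                       chimera_delta = 0.05, plw_in_primer = TRUE,
                       max_mismatch = 2, three_prime_exact = 3, seed = 1,
                       out_dir = NULL) {
  if (is.character(clones) && length(clones) == 1 && file.exists(clones))
    clones <- read_fasta(clones)
  if (is.character(references) && length(references) == 1 &&
      file.exists(references))
    references <- read_fasta(references)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("survey of %d clones; expected product %d bp; enzyme %s; cutoff %g; model %s; seed %d",
      length(clones), expected_bp, if (is.character(enzyme)) enzyme else enzyme$name,
      cutoff, model, seed)

  rep_df <- data.frame(id = names(clones), length = nchar(clones),
                       pattern = NA_character_, frame = NA_integer_,
                       strand = NA_character_, hhxxxdg = NA, nd = NA,
                       chimera_call = NA, flag = "ok", type = NA_character_,
                       stringsAsFactors = FALSE)
  rownames(rep_df) <- rep_df$id

  # 1. size filter
  sf <- size_filter(clones, expected_bp, size_tolerance)
  for (k in seq_len(nrow(sf$discarded))) {
    rep_df[sf$discarded$id[k], "flag"] <- sf$discarded$flag[k]
    say("discard %s: %s (%d bp)", sf$discarded$id[k], sf$discarded$flag[k],
        sf$discarded$length[k])
  }
  kept <- sf$kept
  if (length(kept) == 0) stop("no clones after size filter", call. = FALSE)
  say("size filter: %d kept, %d discarded", length(kept), nrow(sf$discarded))

  # 2. primer trimming
  inserts <- vapply(kept, trim_primers, character(1), forward = forward,
                    reverse = reverse, max_mismatch = max_mismatch,
                    three_prime_exact = three_prime_exact)
  failed <- names(inserts)[is.na(inserts)]
  for (id in failed) {
    rep_df[id, "flag"] <- "trim_error"
    say("discard %s: trim_error (primers not located)", id)
  }
  inserts <- inserts[!is.na(inserts)]
  if (length(inserts) == 0) stop("no clones after primer trimming", call. = FALSE)
  say("primer trimming: %d kept, %d discarded", length(inserts), length(failed))

  # 3. RFLP grouping
  patterns <- group_by_pattern(inserts, enzyme)
  rep_df[patterns$id, "pattern"] <- patterns$pattern
  say("RFLP (%s): %d patterns over %d clones",
      if (is.character(enzyme)) enzyme else enzyme$name,
      length(unique(patterns$pattern)), nrow(patterns))

  # 4. frame selection, translation, motif screen (per clone)
  translations <- character(length(inserts))
  names(translations) <- names(inserts)
  for (id in names(inserts)) {
    bf <- best_frame(inserts[[id]])
    rep_df[id, "frame"] <- bf$frame
    rep_df[id, "strand"] <- bf$strand
    translations[[id]] <- bf$translation
    mot <- screen_motifs(bf$translation, plw_in_primer = plw_in_primer)
    rep_df[id, "hhxxxdg"] <- mot$status[mot$motif == "HHxxxDG"] == "present"
    rep_df[id, "nd"] <- mot$status[mot$motif == "ND"] == "present"
    if (!rep_df[id, "hhxxxdg"] || !rep_df[id, "nd"]) {
      rep_df[id, "flag"] <- "no_motif"
      say("discard %s: no_motif", id)
    }
  }
  clean_ids <- rep_df$id[rep_df$flag == "ok"]
  say("motif screen: %d kept, %d discarded", length(clean_ids),
      length(inserts) - length(clean_ids))

  # 5. chimera screen: the call is computed for every trimmed clone (so
  # truth scoring sees standard per-clone precision/recall); the exclusion
  # flag keeps stage priority, so a clone already failing the motif screen
  # stays flagged no_motif
  refs <- references
  if (is.null(refs)) {
    multi <- table(rep_df$pattern[rep_df$flag == "ok"])
    cand <- rep_df$id[rep_df$flag == "ok" &
                        rep_df$pattern %in% names(multi)[multi >= 2]]
    cand <- cand[cand %in% patterns$id[patterns$representative]]
    refs <- inserts[cand]
    say("chimera references: %d motif-passing multi-member representatives",
        length(refs))
  }
  if (length(refs) >= 2) {
    chim <- flag_chimeras(inserts, refs, delta = chimera_delta)
    rep_df[names(chim), "chimera_call"] <- unname(chim)
    for (id in intersect(names(chim)[chim], clean_ids)) {
      rep_df[id, "flag"] <- "chimera"
      say("discard %s: chimera", id)
    }
  } else {
    say("chimera screen skipped: fewer than 2 references")
  }
  clean_ids <- rep_df$id[rep_df$flag == "ok"]
  say("chimera screen: %d clean clones", length(clean_ids))
  if (length(clean_ids) == 0) stop("no clones after chimera screen", call. = FALSE)

  # 6. typing representatives: lowest-id clean member per pattern
  typing_reps <- vapply(split(clean_ids, rep_df[clean_ids, "pattern"]),
                        function(ids) sort(ids)[1], character(1))
  say("typing on %d pattern representatives", length(typing_reps))
  rep_seqs <- if (model == "kimura_protein") translations[typing_reps]
              else inserts[typing_reps]
  if (length(typing_reps) >= 3) {
    dm <- build_matrix(rep_seqs, model)
    types <- cluster_sequence_types(dm, cutoff)
  } else {
    types <- data.frame(id = unname(typing_reps),
                        type = paste0("ST", seq_along(typing_reps)),
                        representative = TRUE, stringsAsFactors = FALSE)
  }
  pat_type <- setNames(types$type, rep_df[types$id, "pattern"])
  rep_df[clean_ids, "type"] <- unname(pat_type[rep_df[clean_ids, "pattern"]])
  say("sequence types at cutoff %g: %d", cutoff, length(unique(types$type)))

  # 7. tree over type representatives
  type_reps <- types$id[types$representative]
  tree <- NULL
  if (length(type_reps) >= 4) {
    tree <- bootstrap_support(rep_seqs[type_reps], n_reps = bootstrap_reps,
                              model = model, seed = seed)
    say("NJ tree over %d type representatives, %d bootstrap replicates",
        length(type_reps), bootstrap_reps)
  } else {
    say("tree skipped: fewer than 4 type representatives")
  }

  summary <- list(
    input_clones = length(clones),
    after_size_filter = length(kept),
    after_trimming = length(inserts),
    rflp_patterns = length(unique(patterns$pattern)),
    motif_passing = sum(rep_df$flag %in% c("ok", "chimera")),
    chimeras_flagged = sum(rep_df$flag == "chimera"),
    clean_clones = length(clean_ids),
    sequence_types = length(unique(types$type)),
    cutoff = cutoff, model = model, seed = seed)

  out <- list(clone_report = rep_df, types = types,
              representatives = inserts[type_reps], tree = tree,
              summary = summary, log = log)
  if (!is.null(out_dir)) .write_survey(out, out_dir)
  out
}

.write_survey <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(out$clone_report, file.path(out_dir, "clone_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(out$types, file.path(out_dir, "sequence_types.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(out$representatives) > 0)
    write_fasta(out$representatives, file.path(out_dir, "representatives.fasta"))
  if (!is.null(out$tree))
    writeLines(to_newick(out$tree), file.path(out_dir, "tree.nwk"))
  jsonlite::write_json(out$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(out$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
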