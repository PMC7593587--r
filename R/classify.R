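# Classification of predicted proteins against the packaged pathway
# reference set, conservation assessment of the region following a
# repurposed codon, and the per-genome inventory/verdict.

#' Classify predicted proteins against the pathway reference set
#'
#' Each protein is aligned locally to every spec reference; a protein is
#' assigned to at most one spec — its top-scoring spec (ties broken by
#' identity, then spec order) — and a spec is called `present` when its
#' best assigned hit clears the spec's `min_identity` and `min_coverage`.
#' One top hit is retained per spec.
#'
#' @param proteins Named character vector of protein sequences (names are
#'   gene ids).
#' @param specs A [load_pathway_specs()] table.
#' @return A data.frame with one row per spec: `key`, `display_name`,
#'   `status` (`present`/`absent`), `best_identity_pct`,
#'   `best_coverage_pct`, `gene_id`, `query_only`.
#' @export
classify_pathway_genes <- function(proteins, specs = load_pathway_specs()) {
  n_p <- length(proteins)
  n_s <- nrow(specs)
  rows <- data.frame(key = specs$key, display_name = specs$display_name,
                     status = "absent", best_identity_pct = NA_real_,
                     best_coverage_pct = NA_real_, gene_id = NA_character_,
                     query_only = specs$query_only,
                     stringsAsFactors = FALSE)
  if (!n_p) return(rows)
  score <- matrix(-Inf, n_p, n_s)
  ident <- matrix(NA_real_, n_p, n_s)
  cover <- matrix(NA_real_, n_p, n_s)
  mat <- gce_substitution_matrix()
  aa_p <- Biostrings::AAStringSet(unname(proteins))
  for (j in seq_len(n_s)) {
    pa <- Biostrings::pairwiseAlignment(
      aa_p, Biostrings::AAString(specs$reference[j]),
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      type = "local")
    # local alignments have no end gaps, so identity over aligned columns
    # is nmatch / alignment length (C-level accessors; the string route is
    # far slower and equivalent)
    score[, j] <- Biostrings::score(pa)
    ident[, j] <- 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
    cover[, j] <- 100 *
      (IRanges::end(Biostrings::subject(pa)) -
         IRanges::start(Biostrings::subject(pa)) + 1L) /
      nchar(specs$reference[j])
  }
  # assign each protein to its top-scoring spec (ties: identity, spec order)
  assigned <- integer(n_p)
  for (i in seq_len(n_p)) {
    best <- which(score[i, ] == max(score[i, ]))
    if (length(best) > 1L)
      best <- best[order(-ident[i, best], best)][1L]
    assigned[i] <- best
  }
  for (j in seq_len(n_s)) {
    mine <- which(assigned == j)
    if (!length(mine)) next
    top <- mine[order(-score[mine, j], -ident[mine, j])][1L]
    rows$best_identity_pct[j] <- ident[top, j]
    rows$best_coverage_pct[j] <- cover[top, j]
    rows$gene_id[j] <- names(proteins)[top]
    if (ident[top, j] >= specs$min_identity[j] &&
        cover[top, j] >= specs$min_coverage[j])
      rows$status[j] <- "present"
  }
  rows
}

#' Conservation of the sequence following a repurposed codon
#'
#' Aligns the query segment starting at the residue after the recoded
#' codon (up to `window_aa` residues; fewer if the gene ends) against the
#' corresponding reference segment following the reference's recoded
#' residue. The event is called conserved when the global identity of the
#' window alignment reaches `threshold_pct`.
#'
#' @param event One row of [find_readthrough_candidates()] output (needs
#'   `protein`, `codon_index`, `inserted_residue`).
#' @param spec One row of [load_pathway_specs()] with `expects_residue`
#'   set; with several references the best one wins.
#' @param window_aa Window length in residues (default 50).
#' @param threshold_pct Identity threshold in percent (default 40).
#' @return A list: `window_aa` (residues actually compared),
#'   `aligned_identity_pct`, `reference_id`, `conserved`, `threshold_pct`,
#'   `degenerate` (TRUE when the gene ends at the recoded codon).
#' @export
assess_post_stop_conservation <- function(event, spec, window_aa = 50L,
                                          threshold_pct = 40) {
  if (is.na(spec$expects_residue))
    stop("spec '", spec$key, "' does not expect recoding", call. = FALSE)
  if (event$inserted_residue != spec$expects_residue)
    stop("event residue '", event$inserted_residue,
         "' does not match spec expectation '", spec$expects_residue, "'",
         call. = FALSE)
  q_from <- event$codon_index + 2L  # 1-based residue after the recoded site
  q_seg <- substr(event$protein, q_from,
                  min(nchar(event$protein), q_from + window_aa - 1L))
  r_from <- spec$recoded_index + 2L
  r_seg <- substr(spec$reference, r_from,
                  min(nchar(spec$reference), r_from + window_aa - 1L))
  if (!nzchar(q_seg) || !nzchar(r_seg))
    return(list(window_aa = 0L, aligned_identity_pct = 0,
                reference_id = spec$ref_id, conserved = FALSE,
                threshold_pct = threshold_pct, degenerate = TRUE))
  al <- align_proteins(q_seg, r_seg, mode = "global")
  list(window_aa = nchar(q_seg),
       aligned_identity_pct = al$identity_pct,
       reference_id = spec$ref_id,
       conserved = al$identity_pct >= threshold_pct,
       threshold_pct = threshold_pct, degenerate = FALSE)
}

# Components entering the completeness verdict, in reporting order.
#' @noRd
verdict_components <- function() {
  c("pylB", "pylC", "pylD", "pylS_N", "pylS_C", "pyl_tRNA", "mttB_recoding")
}

#' Assemble the per-genome pathway inventory and completeness verdict
#'
#' The verdict is `complete` iff pylB, pylC, pylD, pylS_N and pylS_C are
#' present, a Pyl-tRNA was located, and at least one conserved TAG
#' recoding event lies on the gene classified as the TMA methyltransferase
#' (mttB); `partial` when some but not all of these hold; `negative`
#' otherwise. Query-only specs (mtbB, mtmB-like) never enter the verdict;
#' a present mtmB-like gene without a conserved in-frame TAG is annotated
#' "no conserved in-frame TAG".
#'
#' @param genome_id Genome identifier.
#' @param rows Classification rows from [classify_pathway_genes()].
#' @param trna_hits [scan_trna()] hits for the genome.
#' @param recoding Data.frame of conserved-assessed recoding events with
#'   columns of [find_readthrough_candidates()] plus `spec_key`,
#'   `conserved`, `conservation_identity_pct`; may be empty.
#' @return A list of class `pathway_inventory`: `genome_id`, `rows`
#'   (classification plus recoding annotation and `note`), `trna`,
#'   `verdict`, `missing_components`.
#' @export
build_inventory <- function(genome_id, rows, trna_hits, recoding) {
  rows$recoded_codon <- NA_character_
  rows$recoded_codon_index <- NA_integer_
  rows$recoding_conserved <- NA
  rows$note <- NA_character_
  if (!is.null(recoding) && nrow(recoding)) {
    for (i in seq_len(nrow(recoding))) {
      j <- match(recoding$spec_key[i], rows$key)
      if (is.na(j)) next
      rows$recoded_codon[j] <- recoding$codon[i]
      rows$recoded_codon_index[j] <- recoding$codon_index[i]
      rows$recoding_conserved[j] <- recoding$conserved[i]
    }
  }
  # decoy annotation: present methyltransferase-like genes that lack a
  # conserved in-frame TAG
  decoys <- rows$key %in% c("mtmB_like", "mtbB") & rows$status == "present"
  no_tag <- is.na(rows$recoding_conserved) | !rows$recoding_conserved
  rows$note[decoys & no_tag] <- "no conserved in-frame TAG"

  pyl_trna <- !is.null(trna_hits) && nrow(trna_hits) > 0 &&
    any(trna_hits$kind == "pyl")
  mttb_ok <- FALSE
  if (!is.null(recoding) && nrow(recoding))
    mttb_ok <- any(recoding$spec_key == "mttB" & recoding$conserved &
                     recoding$inserted_residue == "O")
  have <- c(
    vapply(c("pylB", "pylC", "pylD", "pylS_N", "pylS_C"), function(k)
      rows$status[match(k, rows$key)] == "present", NA),
    pyl_tRNA = pyl_trna, mttB_recoding = mttb_ok)
  names(have) <- verdict_components()
  verdict <- if (all(have)) "complete" else if (any(have)) "partial"
  else "negative"
  structure(list(genome_id = genome_id, rows = rows, trna = trna_hits,
                 verdict = verdict,
                 missing_components = names(have)[!have]),
            class = "pathway_inventory")
}

#' @export
print.pathway_inventory <- function(x, ...) {
  cat("Pathway inventory for ", x$genome_id, "\n", sep = "")
  cat("  verdict: ", x$verdict, "\n", sep = "")
  if (length(x$missing_components))
    cat("  missing: ", paste(x$missing_components, collapse = ", "), "\n",
        sep = "")
  present <- x$rows$key[x$rows$status == "present"]
  cat("  present: ", paste(present, collapse = ", "), "\n", sep = "")
  invisible(x)
}
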