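# Translated homology screen of transcripts against the pathway reference
# set. Transcripts are six-frame translated readthrough-aware: TAG is read
# as pyrrolysine 'O' throughout; TGA is read as selenocysteine 'U' only
# when screening against a spec that expects TGA recoding, and treated as
# a stop otherwise (preventing spurious opal readthrough from inflating
# identity). Expression is called at a minimum percent amino-acid
# identity, default 98 (>= semantics).

#' Screen transcripts for expression of pathway proteins
#'
#' @param transcripts Named character vector of transcript DNA sequences
#'   (use [read_dna()] for FASTA/FASTQ input). Transcripts shorter than
#'   30 nt are skipped with a logged warning.
#' @param specs Reference set rows to screen against (default: the full
#'   packaged set), see [load_pathway_specs()].
#' @param threshold_pct Minimum percent amino-acid identity to call a
#'   transcript expressed evidence (default 98; a transcript at exactly
#'   the threshold passes).
#' @param min_report_len Minimum local-alignment length in residues for a
#'   row to be reported (default 30).
#' @return A data.frame: `transcript_id`, `spec_key`, `frame`,
#'   `aligned_len_aa`, `identity_pct`, `passes`, `covers_recoded_site`,
#'   `threshold_pct`.
#' @export
screen_transcripts <- function(transcripts, specs = load_pathway_specs(),
                               threshold_pct = 98, min_report_len = 30L) {
  stopifnot(length(transcripts) > 0)
  short <- nchar(transcripts) < 30L
  if (any(short)) {
    log_msg("WARN", "skipping ", sum(short),
            " transcript(s) shorter than 30 nt")
    transcripts <- transcripts[!short]
  }
  if (!length(transcripts)) return(empty_evidence())
  tab_pyl <- genetic_code("pyl_readthrough")
  tab_sec <- genetic_code("sec_readthrough")
  frag_cache <- list()
  fragments_for <- function(table) {
    key <- table$name
    if (!is.null(frag_cache[[key]])) return(frag_cache[[key]])
    fr <- lapply(names(transcripts), function(id) {
      f <- six_frame_translate(transcripts[[id]], table,
                               min_len = min_report_len)
      if (nrow(f)) f$transcript_id <- id
      f
    })
    fr <- do.call(rbind, fr)
    frag_cache[[key]] <<- fr
    fr
  }
  mat <- gce_substitution_matrix()
  rows <- list()
  for (j in seq_len(nrow(specs))) {
    table <- if (!is.na(specs$expects_residue[j]) &&
                 specs$expects_residue[j] == "U") tab_sec else tab_pyl
    fr <- fragments_for(table)
    if (is.null(fr) || !nrow(fr)) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(fr$peptide),
      Biostrings::AAString(specs$reference[j]),
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      type = "local")
    sc <- Biostrings::score(pa)
    aligned_len <- Biostrings::nchar(pa)
    ident <- 100 * Biostrings::nmatch(pa) / aligned_len
    b_start <- IRanges::start(Biostrings::subject(pa))
    b_end <- IRanges::end(Biostrings::subject(pa))
    for (id in unique(fr$transcript_id)) {
      mine <- which(fr$transcript_id == id)
      best <- mine[which.max(sc[mine])]
      if (aligned_len[best] < min_report_len) next
      covers <- if (is.na(specs$recoded_index[j])) NA else
        b_start[best] <= specs$recoded_index[j] + 1L &&
        b_end[best] >= specs$recoded_index[j] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = id, spec_key = specs$key[j],
        frame = fr$frame[best], aligned_len_aa = aligned_len[best],
        identity_pct = ident[best],
        passes = ident[best] >= threshold_pct,
        covers_recoded_site = covers, threshold_pct = threshold_pct,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_evidence())
  rownames(out) <- NULL
  out
}

#' @noRd
empty_evidence <- function() {
  data.frame(transcript_id = character(0), spec_key = character(0),
             frame = character(0), aligned_len_aa = integer(0),
             identity_pct = numeric(0), passes = logical(0),
             covers_recoded_site = logical(0), threshold_pct = numeric(0))
}

#' Per-spec expression summary
#'
#' @param evidence Output of [screen_transcripts()].
#' @return A data.frame per spec key: `n_transcripts` (reported rows),
#'   `n_passing`, `expressed` (any passing row), `best_identity_pct`.
#' @export
summarize_expression <- function(evidence) {
  if (!nrow(evidence))
    return(data.frame(spec_key = character(0), n_transcripts = integer(0),
                      n_passing = integer(0), expressed = logical(0),
                      best_identity_pct = numeric(0)))
  sp <- split(evidence, evidence$spec_key)
  out <- do.call(rbind, lapply(sp, function(e) data.frame(
    spec_key = e$spec_key[1L], n_transcripts = nrow(e),
    n_passing = sum(e$passes), expressed = any(e$passes),
    best_identity_pct = max(e$identity_pct))))
  rownames(out) <- NULL
  out
}
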