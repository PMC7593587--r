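# Readthrough extension: second prediction pass for genomes with the
# pyrrolysine biosynthesis cassette. First-pass genes terminated by the
# readthrough codon are extended through it to the next hard stop, and the
# consumed codon is reported as a candidate recoding event.

#' Enumerate candidate recoded genes by stop-codon readthrough
#'
#' For each first-pass gene whose terminator is the readthrough codon of
#' `rt_table` (TAG under `pyl_readthrough`, TGA under `sec_readthrough`),
#' re-translates the gene under `rt_table`, continuing through up to
#' `max_events` readthrough codons to the next hard stop. Each consumed
#' codon becomes one candidate event. Candidates whose genomic interval is
#' fully contained in another candidate on the same strand are dropped.
#' An extension that runs off the contig end is kept with `partial3 = TRUE`.
#'
#' @param contig The contig DNA string the first-pass calls came from.
#' @param first_pass Gene calls from [find_orfs()] (standard table).
#' @param rt_table A [genetic_code()] table with exactly one readthrough
#'   codon.
#' @param max_events Maximum readthrough codons consumed per gene
#'   (default 1).
#' @return A data.frame with one row per event: the extended gene call
#'   columns (as [find_orfs()]) plus `codon`, `codon_index` (0-based codon
#'   position of the consumed stop within the extended gene),
#'   `inserted_residue`, `upstream_gene`, `downstream_gene`.
#' @export
find_readthrough_candidates <- function(contig, first_pass,
                                        rt_table = genetic_code("pyl_readthrough"),
                                        max_events = 1L) {
  stopifnot(max_events >= 1L)
  if (length(rt_table$readthrough) != 1L)
    stop("rt_table must have exactly one readthrough codon", call. = FALSE)
  contig <- clean_dna(contig)
  L <- nchar(contig)
  rt_codon <- names(rt_table$readthrough)
  rt_res <- unname(rt_table$readthrough)
  cand <- first_pass[!is.na(first_pass$terminator) &
                       first_pass$terminator == rt_codon, , drop = FALSE]
  if (!nrow(cand)) return(empty_recoding_events())
  rc <- reverse_complement(contig)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    g <- cand[i, ]
    sseq <- if (g$strand == "+") contig else rc
    loc_start <- if (g$strand == "+") g$start else L - g$end
    ext <- extend_through_stops(sseq, loc_start, rt_table, rt_codon, max_events)
    if (g$strand == "+") {
      g_start <- loc_start; g_end <- loc_start + ext$len_nt
    } else {
      g_start <- L - (loc_start + ext$len_nt); g_end <- L - loc_start
    }
    down <- match_downstream(first_pass, g, g_start, g_end)
    for (ci in ext$consumed) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = paste0(g$gene_id, "_rt"), contig_id = g$contig_id,
        start = g_start, end = g_end, strand = g$strand, frame = g$frame,
        table_name = rt_table$name, protein = ext$protein,
        terminator = ext$terminator, partial5 = FALSE,
        partial3 = ext$partial3,
        codon = rt_codon, codon_index = ci, inserted_residue = rt_res,
        upstream_gene = g$gene_id, downstream_gene = down)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  drop_contained(out)
}

#' @noRd
empty_recoding_events <- function() {
  cbind(empty_gene_calls(),
        data.frame(codon = character(0), codon_index = integer(0),
                   inserted_residue = character(0),
                   upstream_gene = character(0),
                   downstream_gene = character(0)))
}

# Translate from strand-local 0-based `loc_start` under the readthrough
# table; stop at the first hard stop, at the (max_events+1)-th readthrough
# codon, or at the contig edge. Returns protein, consumed codon indices
# (0-based within the extended gene), nt length (incl. terminator), flags.
#' @noRd
extend_through_stops <- function(sseq, loc_start, rt_table, rt_codon,
                                 max_events, chunk_codons = 512L) {
  nc_total <- (nchar(sseq) - loc_start) %/% 3L
  res <- character(0)
  codons <- character(0)
  consumed <- integer(0)
  term <- NA_character_
  end_codon <- nc_total
  partial3 <- TRUE
  done <- 0L
  while (done < nc_total) {
    take <- min(chunk_codons, nc_total - done)
    from <- loc_start + 3L * done + 1L
    cst <- seq.int(from, by = 3L, length.out = take)
    cc <- substring(sseq, cst, cst + 2L)
    rr <- unname(rt_table$codon_map[cc])
    rr[is.na(rr)] <- "X"
    stop_here <- FALSE
    interesting <- which(rr == "*" | cc == rt_codon)
    for (jj in interesting) {
      j <- done + jj
      if (rr[jj] == "*") {
        term <- cc[jj]; end_codon <- j - 1L; partial3 <- FALSE
        stop_here <- TRUE; take <- jj; break
      }
      if (length(consumed) >= max_events) {
        # budget exhausted: this readthrough codon terminates the gene
        term <- cc[jj]; end_codon <- j - 1L; partial3 <- FALSE
        stop_here <- TRUE; take <- jj; break
      }
      consumed <- c(consumed, j - 1L)
    }
    res <- c(res, rr[seq_len(take)])
    codons <- c(codons, cc[seq_len(take)])
    done <- done + take
    if (stop_here) break
  }
  protein <- paste(res[seq_len(end_codon)], collapse = "")
  len_nt <- 3L * (end_codon + (!partial3))
  list(protein = protein, consumed = consumed, terminator = term,
       len_nt = len_nt, partial3 = partial3)
}

# First-pass gene on the same strand/frame that shares the extended gene's
# terminator (i.e. the downstream call fused by readthrough), if any.
#' @noRd
match_downstream <- function(first_pass, g, g_start, g_end) {
  same <- first_pass$strand == g$strand & first_pass$gene_id != g$gene_id
  hit <- if (g$strand == "+") same & first_pass$end == g_end &
    first_pass$start > g$start
  else same & first_pass$start == g_start & first_pass$end < g$end
  if (any(hit)) first_pass$gene_id[which(hit)[1L]] else NA_character_
}

#' @noRd
drop_contained <- function(ev) {
  if (!nrow(ev)) return(ev)
  keep <- rep(TRUE, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    others <- which(ev$strand == ev$strand[i] & seq_len(nrow(ev)) != i)
    for (j in others) {
      contains <- ev$start[j] <= ev$start[i] && ev$end[j] >= ev$end[i] &&
        (ev$end[j] - ev$start[j]) > (ev$end[i] - ev$start[i])
      if (contains) { keep[i] <- FALSE; break }
    }
  }
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read the codon at a recoding event's genomic position
#'
#' Strand-aware re-read of the consumed codon directly from the contig;
#' used to sanity-check reported coordinates.
#'
#' @param event One row of [find_readthrough_candidates()] output.
#' @param contig The contig DNA string.
#' @return The 3-mer at the event's codon position, as read on the coding
#'   strand.
#' @export
read_event_codon <- function(event, contig) {
  contig <- clean_dna(contig)
  if (event$strand == "+") {
    p <- event$start + 3L * event$codon_index
    substr(contig, p + 1L, p + 3L)
  } else {
    p <- event$end - 3L * (event$codon_index + 1L)
    reverse_complement(substr(contig, p + 1L, p + 3L))
  }
}
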