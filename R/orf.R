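# Deterministic ORF scanner. Stand-in for a statistical gene finder: all
# maximal start-to-stop ORFs on both strands, longest ORF per (strand,
# frame, terminator). Coordinates are 0-based half-open on the forward
# strand throughout; the GFF3 writer converts to 1-based closed.

#' Find open reading frames
#'
#' Scans both strands of a contig for maximal ORFs: each ORF begins at a
#' start codon of `table`, ends at the first in-frame terminator (the stop
#' codon is included in the coordinates) or at the contig edge (3'-partial,
#' stop not included), and has at least `min_aa` residues. Within a
#' (strand, frame, terminator) group only the longest ORF is kept, i.e. the
#' earliest start after the previous in-frame stop.
#'
#' @param contig A single DNA string.
#' @param contig_id Identifier recorded in the calls (default "contig").
#' @param table A [genetic_code()] table; its readthrough codons do not
#'   terminate ORFs.
#' @param min_aa Minimum protein length in residues (default 50).
#' @return A data.frame of gene calls: `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open, forward strand), `strand`, `frame` (0-2,
#'   strand-local), `table_name`, `protein`, `terminator` (stop codon or
#'   `NA` for 3'-partials), `partial5`, `partial3`.
#' @examples
#' find_orfs("ATGAAATAA", table = genetic_code("bact11"), min_aa = 1)
#' @export
find_orfs <- function(contig, contig_id = "contig",
                      table = genetic_code("bact11"), min_aa = 50L) {
  stopifnot(min_aa >= 1L)
  contig <- clean_dna(contig)
  L <- nchar(contig)
  calls <- list()
  if (L >= 3L * (min_aa + 1L)) {
    rc <- reverse_complement(contig)
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") contig else rc
      for (off in 0:2) {
        calls[[paste0(strand, off)]] <-
          scan_frame(sseq, off, strand, L, table, min_aa, contig_id)
      }
    }
  }
  out <- do.call(rbind, calls)
  if (is.null(out) || !nrow(out)) return(empty_gene_calls())
  out <- out[order(out$start, out$end, out$strand), ]
  out$gene_id <- sprintf("%s_orf%03d", out$contig_id, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, gene_call_cols()]
}

#' @noRd
gene_call_cols <- function() {
  c("gene_id", "contig_id", "start", "end", "strand", "frame", "table_name",
    "protein", "terminator", "partial5", "partial3")
}

#' @noRd
empty_gene_calls <- function() {
  data.frame(gene_id = character(0), contig_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             frame = integer(0), table_name = character(0),
             protein = character(0), terminator = character(0),
             partial5 = logical(0), partial3 = logical(0))
}

# One strand-local frame. `sseq` is the strand sequence (revcomp for '-'),
# `off` the 0-based frame offset. Strand-local half-open [a, b) maps to
# forward coordinates as-is for '+' and [L - b, L - a) for '-'.
#' @noRd
scan_frame <- function(sseq, off, strand, L, table, min_aa, contig_id) {
  sub <- substr(sseq, off + 1L, nchar(sseq))
  nc <- nchar(sub) %/% 3L
  if (nc < min_aa + 1L) return(NULL)
  cstart <- seq.int(1L, by = 3L, length.out = nc)
  codons <- substring(sub, cstart, cstart + 2L)
  is_stop <- codons %in% table$stops
  is_start <- codons %in% table$starts
  stop_idx <- which(is_stop)
  start_idx <- which(is_start)
  if (!length(start_idx)) return(NULL)
  res <- NULL  # lazily translated per ORF below
  bounds <- c(0L, stop_idx, if (!length(stop_idx) || stop_idx[length(stop_idx)] < nc) nc + 1L)
  rows <- list()
  for (b in seq_len(length(bounds) - 1L)) {
    prev_stop <- bounds[b]
    term <- bounds[b + 1L]          # codon index of terminator, or nc+1 edge
    partial3 <- term > nc
    first_start <- start_idx[start_idx > prev_stop & start_idx < term]
    if (!length(first_start)) next
    a <- first_start[1L]
    naa <- term - a                  # residues incl. start codon residue
    if (naa < min_aa) next
    loc_start0 <- off + 3L * (a - 1L)              # strand-local, 0-based
    loc_end0 <- off + 3L * (if (partial3) term - 1L else term)
    prot <- paste(codon_residues(substr(sseq, loc_start0 + 1L,
                                        loc_start0 + 3L * naa), table),
                  collapse = "")
    if (strand == "+") {
      g_start <- loc_start0; g_end <- loc_end0
    } else {
      g_start <- L - loc_end0; g_end <- L - loc_start0
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = NA_character_, contig_id = contig_id,
      start = g_start, end = g_end, strand = strand, frame = off,
      table_name = table$name, protein = prot,
      terminator = if (partial3) NA_character_ else codons[term],
      partial5 = FALSE, partial3 = partial3)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Decide whether the TAG-readthrough prediction pass applies
#'
#' The readthrough pass is run only for genomes in which the pyrrolysine
#' biosynthesis enzymes were identified: pylB, pylC and pylD must all be
#' present in the inventory.
#'
#' @param inventory A pathway inventory (see [classify_pathway_genes()]),
#'   or its `rows` data.frame.
#' @return `TRUE` iff pylB, pylC and pylD are all present.
#' @export
requires_readthrough_pass <- function(inventory) {
  rows <- if (is.data.frame(inventory)) inventory else inventory$rows
  if (is.null(rows) || !nrow(rows)) return(FALSE)
  need <- c("pylB", "pylC", "pylD")
  all(need %in% rows$key[rows$status == "present"])
}
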