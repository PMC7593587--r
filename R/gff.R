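# GFF3 output for gene calls, recoding events and RNA elements. Internal
# coordinates are 0-based half-open; GRanges/GFF3 are 1-based closed.

#' Export gene calls (and optional recoding events) as GFF3
#'
#' @param calls Gene calls from [find_orfs()] or
#'   [find_readthrough_candidates()]; recoding columns (`codon`,
#'   `codon_index`, `inserted_residue`), when present, are written as GFF3
#'   attributes.
#' @param path Output path.
#' @param type Feature type (default `"CDS"`).
#' @return Invisibly, the path.
#' @export
write_gff3 <- function(calls, path, type = "CDS") {
  if (!nrow(calls)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = calls$contig_id,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end),
    strand = calls$strand)
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <- calls$gene_id
  S4Vectors::mcols(gr)$partial <-
    ifelse(calls$partial3, "3prime", NA_character_)
  if ("codon" %in% names(calls)) {
    S4Vectors::mcols(gr)$recoded_codon <- calls$codon
    S4Vectors::mcols(gr)$recoded_codon_index <- calls$codon_index
    S4Vectors::mcols(gr)$inserted_residue <- calls$inserted_residue
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export tRNA hits as GFF3
#'
#' @param hits [scan_trna()] output.
#' @param path Output path.
#' @export
write_trna_gff3 <- function(hits, path) {
  if (!nrow(hits)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = hits$contig_id,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand)
  S4Vectors::mcols(gr)$type <- "tRNA"
  S4Vectors::mcols(gr)$anticodon <- hits$anticodon
  S4Vectors::mcols(gr)$anticodon_rna <- hits$anticodon_rna
  S4Vectors::mcols(gr)$kind <- hits$kind
  S4Vectors::mcols(gr)$score2 <- hits$score
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
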