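# Bacterial SECIS-like elements: a stem-loop immediately downstream of an
# in-frame TGA. The full thermodynamic model of dedicated SECIS finders is
# replaced by paired-base maximisation with G-U wobble: the best hairpin
# is the longest perfectly paired stem (ties: smaller offset, then smaller
# loop) whose stem starts within `max_offset` nt of the TGA 3' end and
# whose loop is 3-12 nt.

#' Scan for SECIS-like hairpins downstream of in-frame TGA codons
#'
#' @param gene A gene-call row (from [find_readthrough_candidates()] under
#'   the `sec_readthrough` table) containing at least one in-frame TGA;
#'   its `protein` must contain `U`, or an error is raised.
#' @param contig The contig DNA string.
#' @param min_stem Minimum stem length in bp (default 7).
#' @param max_offset Maximum distance from the TGA 3' end to the stem
#'   start, in nt (default 15).
#' @param max_stem Largest stem length searched (default 14).
#' @return A data.frame with one row per in-frame TGA that has a
#'   qualifying hairpin: `contig_id`, `uga_codon_pos` (0-based genomic
#'   position of the TGA, forward strand), `codon_index`, `offset_nt`,
#'   `stem_len`, `loop_len`, `score` (paired bases, equals `stem_len`).
#' @export
scan_secis <- function(gene, contig, min_stem = 7L, max_offset = 15L,
                       max_stem = 14L) {
  contig <- clean_dna(contig)
  uga_idx <- which(chars(gene$protein) == "U") - 1L  # 0-based codon indices
  if (!length(uga_idx))
    stop("gene has no in-frame TGA under readthrough translation",
         call. = FALSE)
  L <- nchar(contig)
  sseq <- if (gene$strand == "+") contig else reverse_complement(contig)
  loc_start <- if (gene$strand == "+") gene$start else L - gene$end
  out <- list()
  for (ci in uga_idx) {
    tga_end <- loc_start + 3L * (ci + 1L)  # strand-local 0-based, exclusive
    region <- substr(sseq, tga_end + 1L,
                     min(nchar(sseq), tga_end + max_offset + 2L * max_stem + 12L))
    best <- best_hairpin(region, min_stem, max_offset, max_stem)
    if (is.null(best)) next
    tga_start_local <- tga_end - 3L
    uga_pos <- if (gene$strand == "+") tga_start_local
    else L - tga_start_local - 3L
    out[[length(out) + 1L]] <- data.frame(
      contig_id = gene$contig_id, uga_codon_pos = uga_pos,
      codon_index = ci, offset_nt = best$offset, stem_len = best$stem,
      loop_len = best$loop, score = best$stem)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(contig_id = character(0), uga_codon_pos = integer(0),
                      codon_index = integer(0), offset_nt = integer(0),
                      stem_len = integer(0), loop_len = integer(0),
                      score = integer(0)))
  rownames(res) <- NULL
  res
}

# Exhaustive enumeration of (offset, stem, loop); perfect pairing with G-T
# wobble required over the whole stem. Returns NULL when nothing reaches
# min_stem.
#' @noRd
best_hairpin <- function(region, min_stem, max_offset, max_stem) {
  cs <- chars(region)
  n <- length(cs)
  pm <- pair_ok_matrix()
  best <- NULL
  for (s in seq.int(max_stem, min_stem)) {
    for (off in 0:max_offset) {
      for (lp in 3:12) {
        last <- off + 2L * s + lp
        if (last > n) next
        i <- off + seq_len(s)                # 5' stem positions (1-based)
        j <- off + s + lp + (s:1)            # paired 3' stem positions
        if (all(pm[cbind(cs[i], cs[j])])) {
          cand <- list(offset = off, stem = s, loop = lp)
          if (is.null(best) || cand$stem > best$stem ||
              (cand$stem == best$stem &&
                 (cand$offset < best$offset ||
                    (cand$offset == best$offset && cand$loop < best$loop))))
            best <- cand
        }
      }
    }
    if (!is.null(best)) break  # s decreases, so the first s with a hit wins
  }
  best
}
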