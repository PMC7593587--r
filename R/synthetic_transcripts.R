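# Simulated transcripts: back-translated windows of implanted pathway
# proteins at controlled amino-acid divergence, on random strands and
# frames, with everything recorded in the manifest. Emulates assembled
# metatranscriptome contigs; no read-level error model.

#' Simulate transcripts from a synthetic genome's implants
#'
#' For each selected implant and each divergence level, emits `per_gene`
#' transcripts: the implant's reference protein is mutated to the level,
#' a random window is taken, back-translated with uniform synonymous
#' codons (recoded sites to TAG/TGA), padded to a random frame and
#' possibly reverse-complemented. Frame and divergence are recorded in
#' the manifest.
#'
#' @param manifest Manifest from [generate_genome()] (needs >= 1 implant).
#' @param per_gene Transcripts per implant per divergence level.
#' @param divergence_levels Amino-acid divergence percentages.
#' @param seed Integer seed.
#' @param window_aa Window length in residues (default 100; shorter
#'   proteins are used whole).
#' @param spec_keys Implants to transcribe; defaults to the pyrrolysine
#'   machinery and the TMA methyltransferase.
#' @param specs Reference set.
#' @return A list: `transcripts` (named character vector) and `manifest`
#'   with the `transcripts` table filled in (`transcript_id`, `spec_key`,
#'   `frame` in `+1..+3`/`-1..-3`, `aa_divergence_pct`, `window_start`
#'   (0-based residue), `window_len`, `covers_recoded_site`).
#' @export
simulate_transcripts <- function(manifest, per_gene = 10L,
                                 divergence_levels = 0,
                                 seed = 1L, window_aa = 100L,
                                 spec_keys = c("pylB", "pylC", "pylD",
                                               "pylS_N", "pylS_C", "mttB"),
                                 specs = load_pathway_specs()) {
  im <- manifest$implants
  if (is.null(im) || !nrow(im))
    stop("manifest has no implants", call. = FALSE)
  use <- im$spec_key[im$spec_key %in% spec_keys]
  if (!length(use))
    stop("no implants match spec_keys", call. = FALSE)
  with_seed(seed, {
    seqs <- character(0)
    rows <- list()
    n <- 0L
    for (key in use) {
      j <- match(key, specs$key)
      base_prot <- specs$reference[j]
      rec_idx <- specs$recoded_index[j]  # 0-based or NA
      for (d in divergence_levels) {
        for (r in seq_len(per_gene)) {
          prot <- mutate_protein(base_prot, d)
          plen <- nchar(prot)
          wlen <- min(window_aa, plen)
          wstart <- if (plen > wlen) sample.int(plen - wlen + 1L, 1L) - 1L
          else 0L
          window <- substr(prot, wstart + 1L, wstart + wlen)
          covers <- !is.na(rec_idx) && rec_idx >= wstart &&
            rec_idx < wstart + wlen
          cds <- back_translate(window)
          f <- sample.int(3L, 1L)
          pad5 <- random_dna(f - 1L, 0.5)
          pad3 <- random_dna(sample.int(3L, 1L) - 1L, 0.5)
          t_seq <- paste0(pad5, cds, pad3)
          strand <- sample(c("+", "-"), 1L)
          if (strand == "-") t_seq <- reverse_complement(t_seq)
          n <- n + 1L
          id <- sprintf("tx_%s_d%g_%03d", key, d, n)
          seqs[id] <- t_seq
          rows[[n]] <- data.frame(
            transcript_id = id, spec_key = key,
            frame = paste0(strand, f), aa_divergence_pct = d,
            window_start = wstart, window_len = wlen,
            covers_recoded_site = covers, stringsAsFactors = FALSE)
        }
      }
    }
    manifest$transcripts <- do.call(rbind, rows)
    manifest <- normalize_manifest(manifest)
    list(transcripts = seqs, manifest = manifest)
  })
}

#' Materialize the three fixture presets under a directory
#'
#' Writes, for each preset (`pyl_complete`, `pyl_no_trna`, `negative`), a
#' genome FASTA and its manifest JSON; for `pyl_complete`, also a
#' transcripts FASTA simulated at 0% divergence.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the directory.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (preset in c("pyl_complete", "pyl_no_trna", "negative")) {
    g <- generate_genome(seed = seed, implant_plan = preset)
    write_fasta(g$genome, file.path(dir, paste0(preset, ".fna")))
    write_manifest(g$manifest,
                   file.path(dir, paste0(preset, ".manifest.json")))
    if (preset == "pyl_complete") {
      tx <- simulate_transcripts(g$manifest, per_gene = 5L,
                                 divergence_levels = 0, seed = seed)
      write_fasta(tx$transcripts, file.path(dir, "transcripts_d0.fna"))
      write_manifest(tx$manifest,
                     file.path(dir, "pyl_complete.with_tx.manifest.json"))
    }
  }
  invisible(dir)
}
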