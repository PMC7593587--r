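# Synthetic genomes with ground truth. Implants are taken from the
# packaged reference set (proteins back-translated with uniform synonymous
# codon choice; recoded sites back-translated to TAG/TGA), flanked by a
# stop-codon insulator that terminates reading frames in all six frames so
# first-pass gene calls start exactly at the implant's start codon. All
# randomness flows from one explicit seed; outputs are byte-identical
# across runs.

# Stops in all three frames and (being its own reverse complement) on both
# strands.
INSULATOR <- "TTAATTAATTAA"

#' Back-translate a protein with uniform synonymous codon choice
#'
#' Recoded residues are back-translated to their repurposed codon
#' (`O` -> TAG, `U` -> TGA). Draws from the current RNG stream unless
#' `seed` is given.
#'
#' @param protein Protein string (canonical residues plus O/U).
#' @param table Codon table supplying the synonym sets (default bact11).
#' @param seed Optional seed.
#' @return A DNA string of length `3 * nchar(protein)` (no terminator).
#' @export
back_translate <- function(protein, table = genetic_code("bact11"),
                           seed = NULL) {
  with_seed(seed, {
    syn <- split(names(table$codon_map),
                 unname(table$codon_map))
    syn[["O"]] <- "TAG"
    syn[["U"]] <- "TGA"
    syn[["*"]] <- NULL
    res <- chars(protein)
    bad <- setdiff(unique(res), names(syn))
    if (length(bad))
      stop("cannot back-translate residue(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    paste(vapply(res, function(r) {
      s <- syn[[r]]
      if (length(s) == 1L) s else sample(s, 1L)
    }, "", USE.NAMES = FALSE), collapse = "")
  })
}

#' Mutate a protein to a target amino-acid divergence
#'
#' Each site is independently substituted with probability
#' `aa_divergence_pct / 100` by a uniformly chosen different canonical
#' residue. Recoded residues (O/U) are never mutated.
#'
#' @param protein Protein string.
#' @param aa_divergence_pct Percent divergence in `[0, 100]`.
#' @param seed Optional seed (draws from the current stream otherwise).
#' @return The mutated protein string.
#' @export
mutate_protein <- function(protein, aa_divergence_pct, seed = NULL) {
  stopifnot(aa_divergence_pct >= 0, aa_divergence_pct <= 100)
  if (aa_divergence_pct == 0) return(protein)
  with_seed(seed, {
    aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
              "L","K","M","F","P","S","T","W","Y","V")
    res <- chars(protein)
    mutable <- !(res %in% c("O", "U"))
    hit <- stats::runif(length(res)) < aa_divergence_pct / 100 & mutable
    if (any(hit))
      res[hit] <- vapply(res[hit], function(r)
        sample(setdiff(aa20, r), 1L), "")
    paste(res, collapse = "")
  })
}

#' @noRd
preset_plan <- function(preset) {
  full <- c("pylB", "pylC", "pylD", "pylS_N", "pylS_C", "pyl_tRNA",
            "mttB", "ramA", "mttC", "cutC", "cutD",
            "selA", "selB", "selD", "sec_tRNA", "grdA_like",
            "bcct", "mtmB_like")
  switch(preset,
         pyl_complete = full,
         pyl_no_trna = setdiff(full, "pyl_tRNA"),
         negative = c("mtmB_like", "bcct"),
         stop("unknown preset: ", preset, call. = FALSE))
}

#' Generate a synthetic genome with a ground-truth manifest
#'
#' Emits one contig: i.i.d. background at the target GC fraction with the
#' planned implants placed non-overlapping on random strands with at least
#' `spacing` nt between blocks. Plan presets: `"pyl_complete"` (the full
#' Pyl/Sec/TMA pathway incl. tRNAs, the recoded mttB and grdA-like genes,
#' and the mtmB-like decoy), `"pyl_no_trna"` (same minus the Pyl tRNA) and
#' `"negative"` (decoys only).
#'
#' @param length_nt Genome length (default 60000).
#' @param gc_fraction Background GC fraction in (0, 1).
#' @param seed Integer seed; all randomness derives from it.
#' @param implant_plan A preset name or a character vector of spec keys
#'   (plus `"pyl_tRNA"`/`"sec_tRNA"`).
#' @param divergence_pct Amino-acid divergence applied to implanted
#'   proteins (default 0; the grdA-like implant is always placed
#'   verbatim because its SECIS hairpin is part of the designed CDS).
#' @param genome_id Contig/genome identifier.
#' @param spacing Minimum nt between implant blocks (default 100).
#' @param specs Reference set, see [load_pathway_specs()].
#' @return A list: `genome` (named character, one contig), `manifest`
#'   (class `gce_manifest`).
#' @examples
#' g <- generate_genome(length_nt = 30000, seed = 1, implant_plan = "negative")
#' g$manifest$implants$spec_key
#' @export
generate_genome <- function(length_nt = 60000L, gc_fraction = 0.5,
                            seed = 1L, implant_plan = "pyl_complete",
                            divergence_pct = 0, genome_id = NULL,
                            spacing = 100L, specs = load_pathway_specs()) {
  stopifnot(gc_fraction > 0, gc_fraction < 1)
  plan <- if (length(implant_plan) == 1L &&
              implant_plan %in% c("pyl_complete", "pyl_no_trna", "negative"))
    preset_plan(implant_plan) else implant_plan
  if (is.null(genome_id))
    genome_id <- paste0("synthetic_",
                        if (length(implant_plan) == 1L) implant_plan
                        else "custom", "_s", seed)
  with_seed(seed, {
    blocks <- lapply(plan, build_implant_block, specs = specs,
                     divergence_pct = divergence_pct)
    total_block <- sum(vapply(blocks, function(b) nchar(b$seq), 0L))
    k <- length(blocks)
    min_len <- total_block + (k + 1L) * spacing
    if (length_nt < min_len)
      stop("length_nt too small: need at least ", min_len, " nt for ",
           k, " implants", call. = FALSE)
    blocks <- blocks[sample.int(k)]
    extra <- length_nt - min_len
    gaps <- spacing + as.vector(stats::rmultinom(1L, extra,
                                                 rep(1, k + 1L)))
    pieces <- character(2L * k + 1L)
    implants <- list()
    pos <- 0L
    for (i in seq_len(k)) {
      pieces[2L * i - 1L] <- random_dna(gaps[i], gc_fraction)
      pos <- pos + gaps[i]
      b <- blocks[[i]]
      strand <- sample(c("+", "-"), 1L)
      emitted <- if (strand == "+") b$seq else reverse_complement(b$seq)
      blen <- nchar(b$seq)
      if (strand == "+") {
        f_start <- pos + b$payload_off
      } else {
        f_start <- pos + blen - (b$payload_off + b$payload_len)
      }
      implants[[i]] <- data.frame(
        spec_key = b$key, contig_id = genome_id,
        start = f_start, end = f_start + b$payload_len, strand = strand,
        recoded_codon_index = b$recoded_codon_index,
        divergence_pct_applied = b$divergence, stringsAsFactors = FALSE)
      pieces[2L * i] <- emitted
      pos <- pos + blen
    }
    pieces[2L * k + 1L] <- random_dna(gaps[k + 1L], gc_fraction)
    genome <- setNames(paste(pieces, collapse = ""), genome_id)
    manifest <- new_manifest(seed = seed, genome_id = genome_id,
                             length_nt = length_nt,
                             gc_fraction = gc_fraction,
                             implants = do.call(rbind, implants))
    list(genome = genome, manifest = manifest)
  })
}

#' @noRd
random_dna <- function(n, gc) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# One implant block: insulated CDS, packaged tRNA, or designed
# selenoprotein CDS. payload_off/payload_len locate the gene (or tRNA)
# within the block on the block's own strand.
#' @noRd
build_implant_block <- function(key, specs, divergence_pct) {
  if (key %in% c("pyl_tRNA", "sec_tRNA")) {
    seq <- unname(read_dna(reference_file(
      if (key == "pyl_tRNA") "trna_pyl" else "trna_sec"))[1L])
    return(list(key = key, seq = seq, payload_off = 0L,
                payload_len = nchar(seq),
                recoded_codon_index = NA_integer_, divergence = 0))
  }
  j <- match(key, specs$key)
  if (is.na(j)) stop("unknown implant key: ", key, call. = FALSE)
  if (key == "grdA_like") {
    cds <- unname(read_dna(reference_file("grdA_cds"))[1L])
    div <- 0
  } else {
    prot <- specs$reference[j]
    div <- divergence_pct
    if (div > 0) prot <- mutate_protein(prot, div)
    cds <- paste0(back_translate(prot), "TAA")
  }
  seq <- paste0(INSULATOR, cds, INSULATOR)
  list(key = key, seq = seq, payload_off = nchar(INSULATOR),
       payload_len = nchar(cds),
       recoded_codon_index =
         if (is.na(specs$recoded_index[j])) NA_integer_
         else as.integer(specs$recoded_index[j]),
       divergence = div)
}
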