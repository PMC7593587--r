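# Builds the packaged synthetic reference set under inst/extdata/reference/:
#   pathway_proteins.faa       synthetic stand-in proteins, one per pathway key
#   pathway_specs.tsv          per-key thresholds and recoding expectations
#   trna_pyl_synthetic.fa      cloverleaf Pyl-tRNA gene (CTA anticodon)
#   trna_sec_synthetic.fa      cloverleaf Sec-tRNA gene (TCA anticodon, long arm)
#   grdA_like_cds_synthetic.fa designed selenoprotein CDS with an 8-bp SECIS
#                              hairpin 2 nt after the in-frame TGA
# Deterministic (fixed seeds); run from the repository root.

pkgload::load_all(".", quiet = TRUE)

set.seed(413001)
AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
# rough prokaryotic composition, enough to look protein-like
AAFREQ <- c(8.9, 5.6, 3.9, 5.4, 1.0, 3.9, 6.2, 7.8, 2.1, 6.0,
            10.2, 4.8, 2.4, 3.9, 4.4, 6.0, 5.4, 1.3, 2.9, 7.0)

rand_protein <- function(len, recoded = NULL, residue = NULL) {
  p <- sample(AA20, len, replace = TRUE, prob = AAFREQ)
  p[1] <- "M"
  if (!is.null(recoded)) p[recoded + 1] <- residue  # 0-based index
  paste(p, collapse = "")
}

spec_def <- data.frame(
  key = c("pylB", "pylC", "pylD", "pylS_N", "pylS_C", "mttB", "ramA",
          "mttC", "cutC", "cutD", "grdA_like", "selA", "selB", "selD",
          "bcct", "mtbB", "mtmB_like"),
  display_name = c(
    "3-methylornithine synthase (PylB)",
    "3-methylornithine-L-lysine ligase (PylC)",
    "3-methylornithyl-N6-L-lysine dehydrogenase (PylD)",
    "pyrrolysyl-tRNA synthetase, N-terminal gene (PylSn)",
    "pyrrolysyl-tRNA synthetase, C-terminal gene (PylSc)",
    "trimethylamine methyltransferase (MttB, Pyl-containing)",
    "methylamine methyltransferase corrinoid reductive activase (RamA)",
    "TMA methyltransferase cognate corrinoid protein (MttC)",
    "choline trimethylamine lyase (CutC)",
    "choline trimethylamine lyase activating enzyme (CutD)",
    "glycine betaine reductase selenoprotein (GrdA-like, Sec-containing)",
    "L-seryl-tRNA(Sec) selenium transferase (SelA)",
    "selenocysteine-specific elongation factor (SelB)",
    "selenide, water dikinase (SelD)",
    "betaine/carnitine/choline transporter (BCCT family)",
    "dimethylamine methyltransferase (MtbB; absence query)",
    "monomethylamine methyltransferase-like (MtmB-like decoy, no TAG)"),
  len = c(350, 380, 250, 110, 280, 450, 450,
          220, 500, 300, 160, 400, 400, 340,
          480, 460, 460),
  expects_codon = c(NA, NA, NA, NA, NA, "TAG", NA, NA, NA, NA, "TGA",
                    NA, NA, NA, NA, NA, NA),
  expects_residue = c(NA, NA, NA, NA, NA, "O", NA, NA, NA, NA, "U",
                      NA, NA, NA, NA, NA, NA),
  recoded_index = c(NA, NA, NA, NA, NA, 200, NA, NA, NA, NA, 80,
                    NA, NA, NA, NA, NA, NA),
  verdict_component = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                        FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                        FALSE, FALSE),
  query_only = c(rep(FALSE, 15), TRUE, TRUE),
  stringsAsFactors = FALSE)
spec_def$min_identity <- 35
spec_def$min_coverage <- 70
spec_def$ref_id <- paste0("ref_", spec_def$key, "_synthetic")

proteins <- character(nrow(spec_def))
names(proteins) <- spec_def$ref_id
for (i in seq_len(nrow(spec_def))) {
  if (spec_def$key[i] == "grdA_like") next  # derived from designed CDS below
  proteins[i] <- rand_protein(spec_def$len[i],
                              recoded = spec_def$recoded_index[i],
                              residue = spec_def$expects_residue[i])
}

# --- grdA-like designed CDS: U at codon index 80, 8-bp hairpin 2 nt after
# the TGA, no other in-frame stop, hairpin uniquely maximal in the search
# window ---------------------------------------------------------------
tab_sec <- genetic_code("sec_readthrough")
design_grdA <- function(sub_seed) {
  set.seed(413100 + sub_seed)
  prot <- rand_protein(160, recoded = 80, residue = "U")
  cds <- paste0(back_translate(prot), "TAA")
  v <- strsplit(cds, "")[[1]]
  stopifnot(paste(v[241:243], collapse = "") == "TGA")
  stem <- sample(c("A","C","G","T"), 8, replace = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v[244:245] <- c("C", "A")                      # offset 2
  v[246:253] <- stem
  v[254:257] <- sample(c("A","C","G","T"), 4, replace = TRUE)
  v[258:265] <- rev(unname(comp[stem]))
  cds <- paste(v, collapse = "")
  # reject designs with stray stops or a non-unique / shifted best hairpin
  p <- tryCatch(translate(cds, tab_sec, "trailing_star"),
                warning = function(w) "")
  if (nchar(p) != 161 || substr(p, 161, 161) != "*") return(NULL)
  if (sum(strsplit(p, "")[[1]] == "U") != 1) return(NULL)
  region <- substr(cds, 244, 244 + 15 + 2 * 14 + 12)
  best <- gcescan:::best_hairpin(region, min_stem = 7, max_offset = 15,
                                 max_stem = 14)
  if (is.null(best) || best$stem != 8 || best$offset != 2 ||
      best$loop != 4) return(NULL)
  list(cds = cds, protein = sub("\\*$", "", p))
}
grdA <- NULL
for (s in 1:50) { grdA <- design_grdA(s); if (!is.null(grdA)) break }
stopifnot(!is.null(grdA))
cat("grdA design accepted at sub-seed", s, "\n")
proteins["ref_grdA_like_synthetic"] <- grdA$protein

outdir <- file.path("inst", "extdata", "reference")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
write_fasta(proteins, file.path(outdir, "pathway_proteins.faa"))
write.table(spec_def[, c("key", "display_name", "ref_id", "min_identity",
                         "min_coverage", "expects_codon", "expects_residue",
                         "recoded_index", "verdict_component",
                         "query_only")],
            file.path(outdir, "pathway_specs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_fasta(c(grdA_like_cds_synthetic = grdA$cds),
            file.path(outdir, "grdA_like_cds_synthetic.fa"))

# --- synthetic tRNA genes ----------------------------------------------
pyl <- synthetic_trna("CTA", seed = 413201)
sec <- synthetic_trna("TCA", seed = 413202)
write_fasta(c(trna_pyl_synthetic = pyl),
            file.path(outdir, "trna_pyl_synthetic.fa"))
write_fasta(c(trna_sec_synthetic = sec),
            file.path(outdir, "trna_sec_synthetic.fa"))

# sanity: the scanner must see both tRNAs with the right kind
h1 <- scan_trna(pyl); h2 <- scan_trna(sec)
stopifnot(nrow(h1) == 1, h1$kind == "pyl", h1$anticodon == "CTA",
          nrow(h2) == 1, h2$kind == "sec", h2$anticodon == "TCA",
          h2$variable_arm_len >= 10)
cat("reference set written to", outdir, "\n")
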