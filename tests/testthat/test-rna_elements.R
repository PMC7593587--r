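pyl_trna <- unname(read_dna(reference_file("trna_pyl"))[1])
sec_trna <- unname(read_dna(reference_file("trna_sec"))[1])

test_that("the packaged Pyl-tRNA is found on either strand", {
  set.seed(23)
  flank5 <- random_dna_str(400)
  flank3 <- random_dna_str(400)
  contig <- paste0(flank5, pyl_trna, flank3)
  hits <- scan_trna(contig)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$kind, "pyl")
  expect_equal(hits$anticodon, "CTA")
  expect_equal(hits$anticodon_rna, "CUA")
  expect_equal(hits$start, 400)
  expect_equal(hits$end, 400 + nchar(pyl_trna))
  expect_equal(hits$strand, "+")
  rc_hits <- scan_trna(reverse_complement(contig))
  expect_equal(nrow(rc_hits), 1)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$anticodon, "CTA")
  expect_equal(rc_hits$kind, "pyl")
})

test_that("Sec and Pyl tRNAs are never confused", {
  contig <- paste0(pyl_trna, strrep("A", 150), sec_trna)
  hits <- scan_trna(contig)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$kind, c("pyl", "sec"))
  sec_hit <- hits[hits$kind == "sec", ]
  expect_equal(sec_hit$anticodon, "TCA")
  expect_gte(sec_hit$variable_arm_len, 10)
  pyl_hit <- hits[hits$kind == "pyl", ]
  expect_lt(pyl_hit$variable_arm_len, 10)
  # total length within the cloverleaf model's bounds
  expect_true(all(hits$end - hits$start >= 70 &
                    hits$end - hits$start <= 120))
})

test_that("scan results are deterministic", {
  set.seed(29)
  contig <- paste0(random_dna_str(1000), pyl_trna, random_dna_str(1000))
  expect_identical(scan_trna(contig), scan_trna(contig))
})

test_that("random-sequence hits match the exhaustive all-window oracle", {
  set.seed(21)
  contig <- random_dna_str(10000)
  got <- scan_trna(contig)
  raw <- oracle_trna_raw(contig, c("CTA", "TCA"))
  # default stringency is calibrated for zero hits on random sequence
  expect_equal(nrow(got), 0)
  expect_equal(nrow(raw), 0)
})

test_that("implanted tRNA agrees with the oracle's best window", {
  set.seed(25)
  contig <- paste0(random_dna_str(300), sec_trna, random_dna_str(300))
  got <- scan_trna(contig)
  raw <- oracle_trna_raw(contig, c("CTA", "TCA"))
  expect_gte(nrow(raw), 1)
  best <- raw[which.max(raw$score), ]
  expect_equal(nrow(got), 1)
  expect_equal(got$start, best$start)
  expect_equal(got$end, best$end)
  expect_equal(got$score, best$score)
  # every reported hit exists in the oracle's raw enumeration
  expect_true(all(paste(got$start, got$end, got$strand) %in%
                    paste(raw$start, raw$end, raw$strand)))
})

test_that("overlap collapse leaves no pair overlapping >50% of the shorter", {
  set.seed(27)
  # tandem copies force overlapping candidate windows
  contig <- paste0(random_dna_str(100), pyl_trna, pyl_trna,
                   random_dna_str(100))
  hits <- scan_trna(contig)
  expect_gte(nrow(hits), 1)
  if (nrow(hits) > 1) {
    for (i in 1:(nrow(hits) - 1)) for (j in (i + 1):nrow(hits)) {
      ov <- min(hits$end[i], hits$end[j]) -
        max(hits$start[i], hits$start[j])
      shorter <- min(hits$end[i] - hits$start[i],
                     hits$end[j] - hits$start[j])
      expect_lte(ov, 0.5 * shorter)
    }
  }
})

test_that("synthetic tRNA construction honours anticodon and arm lengths", {
  t1 <- synthetic_trna("CTA", d_loop_len = 6, var_arm_len = 8, seed = 5)
  expect_equal(nchar(t1), 60 + 6 + 8)
  h <- scan_trna(t1)
  expect_equal(nrow(h), 1)
  expect_equal(h$anticodon, "CTA")
  expect_equal(h$d_loop_len, 6)
  expect_equal(h$variable_arm_len, 8)
  expect_equal(h$score, 21)
})

# ---- SECIS ------------------------------------------------------------

make_sec_gene <- function(offset_nt = 2, stem = 8, loop = 4,
                          n_up = 20, n_down = 12, seed = 99) {
  set.seed(seed)
  excl <- c("TAA", "TAG", "TGA", "ATG", "GTG", "TTG")
  up <- random_cds(n_up, exclude = excl)
  stem1 <- c("G", "C", "A", "T", "G", "G", "C", "A")[seq_len(stem)]
  hp <- paste0(strrep("C", offset_nt), paste(stem1, collapse = ""),
               random_cds(1), # 3-nt loop filler (loop arg used below)
               paste(rev(chartr("ACGT", "TGCA", stem1)), collapse = ""))
  # rebuild precisely: offset + stem + loop + revcomp(stem)
  loop_seq <- substr("ATCCATGCATGC", 1, loop)
  hp <- paste0(strrep("C", offset_nt), paste(stem1, collapse = ""),
               loop_seq,
               paste(rev(strsplit(chartr("ACGT", "TGCA",
                                         paste(stem1, collapse = "")),
                                  "")[[1]]), collapse = ""))
  pad <- (3 - (nchar(hp) %% 3)) %% 3
  down <- paste0(hp, strrep("C", pad), random_cds(n_down, exclude = excl))
  cds <- paste0("ATG", up, "TGA", down, "TAA")
  contig <- paste0("TTAATTAATTAA", cds, "TTAATTAATTAA")
  fp <- find_orfs(contig, table = genetic_code("bact11"), min_aa = 5)
  ev <- find_readthrough_candidates(contig, fp,
                                    genetic_code("sec_readthrough"))
  list(contig = contig, gene = ev[which.max(nchar(ev$protein)), ])
}

test_that("an implanted hairpin is reported with its exact geometry", {
  x <- make_sec_gene(offset_nt = 2, stem = 8, loop = 4)
  expect_equal(substr(x$gene$protein, 22, 22), "U")
  hits <- scan_secis(x$gene, x$contig, min_stem = 7, max_offset = 15)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$stem_len, 8)
  expect_equal(hits$offset_nt, 2)
  expect_equal(hits$loop_len, 4)
  expect_equal(hits$score, 8)
  # the reported TGA position re-reads as TGA on the coding strand
  expect_equal(substr(x$contig, hits$uga_codon_pos + 1,
                      hits$uga_codon_pos + 3), "TGA")
})

test_that("a hairpin beyond max_offset is not reported", {
  x <- make_sec_gene(offset_nt = 9, stem = 8, loop = 4)
  hits <- scan_secis(x$gene, x$contig, min_stem = 7, max_offset = 5)
  expect_equal(nrow(hits), 0)
})

test_that("best hairpin equals the exhaustive pairing-maximisation oracle", {
  set.seed(17)
  tab_b <- genetic_code("bact11")
  for (rep in 1:10) {
    region <- random_dna_str(60)
    got <- gcescan:::best_hairpin(region, min_stem = 4, max_offset = 15,
                                  max_stem = 14)
    want <- oracle_best_hairpin(region, min_stem = 4, max_offset = 15)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$stem, want$stem)
      expect_equal(got$offset, want$offset)
      expect_equal(got$loop, want$loop)
    }
  }
})

test_that("a gene without in-frame TGA is a precondition error", {
  gene <- data.frame(contig_id = "c", start = 0, end = 9, strand = "+",
                     protein = "MKV")
  expect_error(scan_secis(gene, "ATGAAAGTTTAA"), "no in-frame TGA")
})
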