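tab_b <- genetic_code("bact11")
tab_p <- genetic_code("pyl_readthrough")

test_that("a minimal ORF is called with exact coordinates on both strands", {
  calls <- find_orfs("ATGAAATAA", table = tab_b, min_aa = 1)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 0)
  expect_equal(calls$end, 9)
  expect_equal(calls$strand, "+")
  expect_equal(calls$protein, "MK")
  expect_equal(calls$terminator, "TAA")
  rc <- find_orfs(reverse_complement("ATGAAATAA"), table = tab_b, min_aa = 1)
  expect_equal(nrow(rc), 1)
  expect_equal(rc$strand, "-")
  expect_equal(rc$protein, "MK")
  expect_equal(c(rc$start, rc$end), c(0, 9))
})

test_that("contig too short for min_aa yields an empty call set", {
  expect_equal(nrow(find_orfs("ATGAAATAA", table = tab_b, min_aa = 5)), 0)
})

test_that("ORF calls equal the exhaustive brute-force scan", {
  set.seed(7)
  for (rep in 1:3) {
    contig <- random_dna_str(2000)
    got <- find_orfs(contig, table = tab_b, min_aa = 20)
    want <- oracle_orfs(contig, tab_b, min_aa = 20)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$strand, want$strand)
    expect_equal(got$protein, want$protein)
    expect_equal(got$partial3, want$partial3)
  }
})

test_that("readthrough pass gate requires pylB, pylC and pylD together", {
  inv <- data.frame(key = c("pylB", "pylC", "pylD"),
                    status = c("present", "present", "present"))
  expect_true(requires_readthrough_pass(inv))
  inv$status[1] <- "absent"
  expect_false(requires_readthrough_pass(inv))
  expect_false(requires_readthrough_pass(inv[0, ]))
})

test_that("amber-terminated gene is extended through TAG to the next stop", {
  set.seed(15)
  up <- random_cds(10, exclude = c("TAA", "TAG", "TGA", "ATG", "GTG", "TTG"))
  down <- random_cds(9, exclude = c("TAA", "TAG", "TGA", "ATG", "GTG", "TTG"))
  cds <- paste0("ATG", up, "TAG", down, "TAA")
  contig <- paste0("TTAATTAATTAA", cds, "TTAATTAATTAA")
  fp <- find_orfs(contig, table = tab_b, min_aa = 5)
  ev <- find_readthrough_candidates(contig, fp, tab_p)
  expect_equal(nrow(ev), 1)
  expect_equal(nchar(ev$protein), 21)  # M + 10 + O + 9
  expect_equal(ev$codon_index, 11)
  expect_equal(substr(ev$protein, 12, 12), "O")
  expect_equal(ev$inserted_residue, "O")
  expect_equal(ev$terminator, "TAA")
  # fusion conservation: extended = upstream + O + downstream translation
  up_gene <- fp[!is.na(fp$terminator) & fp$terminator == "TAG", ]
  expect_identical(ev$protein,
                   paste0(up_gene$protein, "O",
                          translate(paste0(down, "TAA"), tab_b)))
  # coordinate sanity: codon re-read at the event position is TAG
  expect_identical(read_event_codon(ev, contig), "TAG")
})

test_that("readthrough events carry exact coordinates on the minus strand", {
  set.seed(16)
  up <- random_cds(12, exclude = c("TAA", "TAG", "TGA", "ATG", "GTG", "TTG"))
  down <- random_cds(7, exclude = c("TAA", "TAG", "TGA", "ATG", "GTG", "TTG"))
  cds <- paste0("ATG", up, "TAG", down, "TAA")
  contig <- reverse_complement(
    paste0("TTAATTAATTAA", cds, "TTAATTAATTAA"))
  fp <- find_orfs(contig, table = tab_b, min_aa = 5)
  ev <- find_readthrough_candidates(contig, fp, tab_p)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$strand, "-")
  expect_equal(ev$codon_index, 13)
  expect_identical(read_event_codon(ev, contig), "TAG")
})

test_that("genes ending in TAA/TGA yield no amber candidates", {
  set.seed(17)
  contig <- paste0("TTAATTAATTAA", "ATG", random_cds(30), "TAA",
                   "TTAATTAATTAA", "ATG", random_cds(25), "TGA",
                   "TTAATTAATTAA")
  fp <- find_orfs(contig, table = tab_b, min_aa = 10)
  expect_gte(nrow(fp), 2)
  ev <- find_readthrough_candidates(contig, fp, tab_p)
  expect_equal(nrow(ev), 0)
})

test_that("max_events bounds consecutive amber readthroughs", {
  set.seed(18)
  a <- random_cds(10, exclude = c("TAA", "TAG", "TGA", "ATG", "GTG", "TTG"))
  b <- random_cds(10, exclude = c("TAA", "TAG", "TGA", "ATG", "GTG", "TTG"))
  c3 <- random_cds(10, exclude = c("TAA", "TAG", "TGA", "ATG", "GTG", "TTG"))
  cds <- paste0("ATG", a, "TAG", b, "TAG", c3, "TAA")
  contig <- paste0("TTAATTAATTAA", cds, "TTAATTAATTAA")
  fp <- find_orfs(contig, table = tab_b, min_aa = 5)
  main <- fp$gene_id[fp$start == 12 & fp$strand == "+"]  # the implanted CDS
  ev1 <- find_readthrough_candidates(contig, fp, tab_p, max_events = 1)
  ev1 <- ev1[ev1$upstream_gene == main, ]
  expect_equal(nrow(ev1), 1)
  expect_equal(nchar(ev1$protein), 22)     # stops at the second TAG
  expect_equal(ev1$terminator, "TAG")
  ev2 <- find_readthrough_candidates(contig, fp, tab_p, max_events = 2)
  ev2 <- ev2[ev2$upstream_gene == main, ]
  expect_equal(nrow(ev2), 2)               # one row per consumed codon
  expect_equal(sort(ev2$codon_index), c(11, 22))
  expect_equal(unique(nchar(ev2$protein)), 33)
})

test_that("extension off the contig end is kept as a 3'-partial", {
  set.seed(19)
  up <- random_cds(8, exclude = c("TAA", "TAG", "TGA", "ATG", "GTG", "TTG"))
  down <- random_cds(5, exclude = c("TAA", "TAG", "TGA", "ATG", "GTG", "TTG"))
  contig <- paste0("ATG", up, "TAG", down)  # no hard stop, no insulator
  fp <- find_orfs(contig, table = tab_b, min_aa = 5)
  ev <- find_readthrough_candidates(contig, fp, tab_p)
  expect_equal(nrow(ev), 1)
  expect_true(ev$partial3)
  expect_true(is.na(ev$terminator))
  expect_equal(nchar(ev$protein), 15)  # M + 8 + O + 5
})

test_that("implanted recoded gene is recovered at the manifest codon index", {
  g <- generate_genome(seed = 42, implant_plan = "pyl_complete")
  contig <- unname(g$genome)
  man <- g$manifest$implants
  fp <- find_orfs(contig, contig_id = g$manifest$genome_id, table = tab_b)
  ev <- find_readthrough_candidates(contig, fp, tab_p)
  mttb <- man[man$spec_key == "mttB", ]
  hit <- ev[ev$start == mttb$start & ev$end == mttb$end, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$codon_index, mttb$recoded_codon_index)
  expect_equal(hit$strand, mttb$strand)
  expect_identical(read_event_codon(hit, contig), "TAG")
})
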