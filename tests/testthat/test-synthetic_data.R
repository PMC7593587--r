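test_that("genome generation is byte-identical under a fixed seed", {
  g1 <- generate_genome(seed = 5, implant_plan = "negative",
                        length_nt = 20000)
  g2 <- generate_genome(seed = 5, implant_plan = "negative",
                        length_nt = 20000)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$manifest$implants, g2$manifest$implants)
  g3 <- generate_genome(seed = 6, implant_plan = "negative",
                        length_nt = 20000)
  expect_false(identical(g1$genome, g3$genome))
})

test_that("background GC is within the binomial tolerance of the target", {
  g <- generate_genome(seed = 1, implant_plan = "negative",
                       length_nt = 100000, gc_fraction = 0.5)
  s <- unname(g$genome)
  # mask implants so only background is measured
  for (i in seq_len(nrow(g$manifest$implants))) {
    im <- g$manifest$implants[i, ]
    substr(s, im$start + 1, im$end) <- strrep(".", im$end - im$start)
  }
  v <- strsplit(s, "")[[1]]
  v <- v[v != "."]
  gc <- mean(v %in% c("G", "C"))
  # binomial bound: 0.5 +- 4 * sqrt(0.25/n) is far inside +-2 points
  expect_lt(abs(gc - 0.5), 0.02)
  expect_gt(length(v), 90000)
})

test_that("implant coordinates address exactly the implanted payloads", {
  g <- generate_genome(seed = 42, implant_plan = "pyl_complete")
  specs <- load_pathway_specs()
  contig <- unname(g$genome)
  im <- g$manifest$implants
  tab_b <- genetic_code("bact11")
  tab_p <- genetic_code("pyl_readthrough")
  tab_s <- genetic_code("sec_readthrough")
  for (i in seq_len(nrow(im))) {
    r <- im[i, ]
    payload <- substr(contig, r$start + 1, r$end)
    if (r$strand == "-") payload <- reverse_complement(payload)
    if (r$spec_key %in% c("pyl_tRNA", "sec_tRNA")) {
      ref <- read_dna(reference_file(
        if (r$spec_key == "pyl_tRNA") "trna_pyl" else "trna_sec"))[[1]]
      expect_identical(payload, ref)
    } else {
      tab <- if (r$spec_key == "mttB") tab_p
      else if (r$spec_key == "grdA_like") tab_s else tab_b
      prot <- translate(payload, tab)
      ref <- specs$reference[specs$key == r$spec_key]
      expect_identical(prot, ref)
      if (!is.na(r$recoded_codon_index))
        expect_identical(substr(prot, r$recoded_codon_index + 1,
                                r$recoded_codon_index + 1),
                         specs$expects_residue[specs$key == r$spec_key])
    }
  }
})

test_that("presets include and exclude the right implants", {
  g_full <- generate_genome(seed = 2, implant_plan = "pyl_complete")
  g_not <- generate_genome(seed = 2, implant_plan = "pyl_no_trna")
  g_neg <- generate_genome(seed = 2, implant_plan = "negative",
                           length_nt = 20000)
  expect_true("pyl_tRNA" %in% g_full$manifest$implants$spec_key)
  expect_false("pyl_tRNA" %in% g_not$manifest$implants$spec_key)
  expect_setequal(setdiff(g_full$manifest$implants$spec_key,
                          g_not$manifest$implants$spec_key), "pyl_tRNA")
  expect_setequal(g_neg$manifest$implants$spec_key, c("mtmB_like", "bcct"))
  # mtbB (the absence query) is implanted nowhere
  expect_false("mtbB" %in% g_full$manifest$implants$spec_key)
})

test_that("too-short genomes fail with the required minimum in the message", {
  expect_error(generate_genome(seed = 1, length_nt = 5000,
                               implant_plan = "pyl_complete"),
               "need at least [0-9]+ nt")
})

test_that("mutate_protein matches its binomial model", {
  p <- random_protein(100)
  expect_identical(mutate_protein(p, 0, seed = 1), p)
  m100 <- mutate_protein(p, 100, seed = 1)
  expect_equal(sum(strsplit(p, "")[[1]] == strsplit(m100, "")[[1]]), 0)
  # recoded residues are never touched
  po <- paste0(substr(p, 1, 50), "O", substr(p, 52, 100))
  expect_equal(substr(mutate_protein(po, 100, seed = 2), 51, 51), "O")
  # mean substituted-site count within 4 SD of Binomial(n, 0.05)
  set.seed(2)
  n <- nchar(p)
  counts <- replicate(400, {
    m <- mutate_protein(p, 5)
    sum(strsplit(p, "")[[1]] != strsplit(m, "")[[1]])
  })
  expect_lt(abs(mean(counts) - n * 0.05),
            4 * sqrt(n * 0.05 * 0.95 / 400))
})

test_that("manifests round-trip through JSON", {
  g <- generate_genome(seed = 3, implant_plan = "pyl_no_trna")
  tx <- simulate_transcripts(g$manifest, per_gene = 2,
                             divergence_levels = c(0, 5), seed = 4)
  tf <- tempfile(fileext = ".json")
  write_manifest(tx$manifest, tf)
  back <- read_manifest(tf)
  expect_equal(back$seed, tx$manifest$seed)
  expect_equal(back$genome_id, tx$manifest$genome_id)
  expect_equal(back$background, tx$manifest$background)
  expect_equal(back$implants, tx$manifest$implants)
  expect_equal(back$transcripts, tx$manifest$transcripts)
})

test_that("transcript simulation is deterministic and well-formed", {
  g <- generate_genome(seed = 3, implant_plan = "pyl_complete")
  t1 <- simulate_transcripts(g$manifest, per_gene = 3,
                             divergence_levels = 0, seed = 9)
  t2 <- simulate_transcripts(g$manifest, per_gene = 3,
                             divergence_levels = 0, seed = 9)
  expect_identical(t1$transcripts, t2$transcripts)
  man <- t1$manifest$transcripts
  expect_equal(nrow(man), 3 * 6)  # six default spec keys
  expect_true(all(man$frame %in% c("+1", "+2", "+3", "-1", "-2", "-3")))
  expect_true(all(nchar(t1$transcripts) >= 3 * man$window_len))
})

test_that("fixture materialisation writes the three presets", {
  d <- file.path(tempdir(), "fixtures_test")
  generate_fixtures(d, seed = 2)
  expect_true(all(file.exists(file.path(d, c(
    "pyl_complete.fna", "pyl_complete.manifest.json",
    "pyl_no_trna.fna", "pyl_no_trna.manifest.json",
    "negative.fna", "negative.manifest.json", "transcripts_d0.fna")))))
  m <- read_manifest(file.path(d, "pyl_no_trna.manifest.json"))
  expect_false("pyl_tRNA" %in% m$implants$spec_key)
  unlink(d, recursive = TRUE)
})
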