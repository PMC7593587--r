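specs <- load_pathway_specs()

test_that("identity and coverage follow their definitions", {
  set.seed(1)
  a <- random_protein(100)
  al <- align_proteins(a, a, mode = "global")
  expect_equal(al$identity_pct, 100)
  expect_equal(al$coverage_pct, 100)
  # one substitution in 100 -> 99.0
  b <- a
  pos <- 50
  substr(b, pos, pos) <- if (substr(a, pos, pos) == "A") "R" else "A"
  expect_equal(align_proteins(a, b, mode = "global")$identity_pct, 99.0)
  expect_error(align_proteins("", "MKV"), "empty")
})

test_that("O and U self-match positively and cross-mismatch", {
  m <- gce_substitution_matrix()
  expect_gt(m["O", "O"], 0)
  expect_gt(m["U", "U"], 0)
  expect_lt(m["O", "K"], 0)
  expect_lt(m["U", "C"], 0)
  expect_lt(m["O", "U"], 0)
  al <- align_proteins("MKOVL", "MKOVL")
  expect_equal(al$identity_pct, 100)
})

test_that("alignment scores equal the plain-recursion DP oracle", {
  set.seed(5)
  for (i in 1:30) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    expect_equal(align_proteins(a, b, mode = "global")$score,
                 oracle_align_score(a, b, "global"))
    expect_equal(align_proteins(a, b, mode = "local")$score,
                 oracle_align_score(a, b, "local"))
  }
})

test_that("global identity is symmetric", {
  set.seed(6)
  for (i in 1:50) {
    a <- random_protein(sample(20:60, 1))
    b <- random_protein(sample(20:60, 1))
    expect_equal(align_proteins(a, b, mode = "global")$identity_pct,
                 align_proteins(b, a, mode = "global")$identity_pct)
  }
})

test_that("an exact reference copy classifies present at identity 100", {
  prot <- c(gene1 = specs$reference[specs$key == "pylB"])
  rows <- classify_pathway_genes(prot, specs)
  r <- rows[rows$key == "pylB", ]
  expect_equal(r$status, "present")
  expect_equal(r$best_identity_pct, 100)
  expect_equal(r$best_coverage_pct, 100)
  expect_equal(r$gene_id, "gene1")
  expect_true(all(rows$status[rows$key != "pylB"] == "absent"))
})

test_that("a random protein clears no spec threshold", {
  set.seed(9)
  prot <- c(rnd = random_protein(300))
  rows <- classify_pathway_genes(prot, specs)
  expect_true(all(rows$status == "absent"))
  # exhaustive check: every spec alignment is below its identity threshold
  # at the required coverage
  for (j in seq_len(nrow(specs))) {
    al <- align_proteins(prot[[1]], specs$reference[j], mode = "local")
    cov <- 100 * (al$b_end - al$b_start + 1) / nchar(specs$reference[j])
    expect_true(al$identity_pct < specs$min_identity[j] ||
                  cov < specs$min_coverage[j])
  }
})

test_that("pylB/C/D-only proteome gates the second pass, verdict partial", {
  prot <- setNames(specs$reference[match(c("pylB", "pylC", "pylD"),
                                         specs$key)],
                   c("g1", "g2", "g3"))
  rows <- classify_pathway_genes(prot, specs)
  expect_true(requires_readthrough_pass(rows))
  inv <- build_inventory("test", rows, trna_hits = NULL, recoding = NULL)
  expect_equal(inv$verdict, "partial")
  expect_true(all(c("pylS_N", "pylS_C", "pyl_tRNA", "mttB_recoding") %in%
                    inv$missing_components))
})

test_that("lowering min_identity never flips a spec present -> absent", {
  set.seed(12)
  prot <- setNames(
    c(mutate_protein(specs$reference[specs$key == "pylD"], 30),
      random_protein(200)),
    c("borderline", "noise"))
  present_at <- function(th) {
    s <- specs
    s$min_identity <- th
    r <- classify_pathway_genes(prot, s)
    r$key[r$status == "present"]
  }
  prev <- present_at(80)
  for (th in c(60, 40, 20, 5)) {
    cur <- present_at(th)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("post-stop conservation scores the downstream window", {
  spec <- specs[specs$key == "mttB", ]
  ref <- spec$reference
  idx <- spec$recoded_index
  # query identical to the reference -> 100, conserved
  event <- data.frame(protein = ref, codon_index = idx,
                      inserted_residue = "O")
  rep1 <- assess_post_stop_conservation(event, spec)
  expect_equal(rep1$aligned_identity_pct, 100)
  expect_true(rep1$conserved)
  expect_equal(rep1$window_aa, 50)
  # random downstream -> near the random baseline, not conserved at 40%
  set.seed(13)
  scrambled <- paste0(substr(ref, 1, idx + 1), random_protein(50))
  event2 <- data.frame(protein = scrambled, codon_index = idx,
                       inserted_residue = "O")
  rep2 <- assess_post_stop_conservation(event2, spec)
  oracle <- align_proteins(substr(scrambled, idx + 2, idx + 51),
                           substr(ref, idx + 2, idx + 51),
                           mode = "global")
  expect_equal(rep2$aligned_identity_pct, oracle$identity_pct)
  expect_false(rep2$conserved)
  # window truncated by a short gene: identity over available residues only
  short <- substr(ref, 1, idx + 11)  # 10 residues after the recoded site
  event3 <- data.frame(protein = short, codon_index = idx,
                       inserted_residue = "O")
  rep3 <- assess_post_stop_conservation(event3, spec)
  expect_equal(rep3$window_aa, 10)
  expect_equal(rep3$aligned_identity_pct, 100)
  # degenerate: gene ends at the recoded codon
  event4 <- data.frame(protein = substr(ref, 1, idx + 1),
                       codon_index = idx, inserted_residue = "O")
  rep4 <- assess_post_stop_conservation(event4, spec)
  expect_true(rep4$degenerate)
  expect_false(rep4$conserved)
  expect_equal(rep4$window_aa, 0)
  # residue mismatch is an error
  event5 <- data.frame(protein = ref, codon_index = idx,
                       inserted_residue = "U")
  expect_error(assess_post_stop_conservation(event5, spec), "match")
})

test_that("mtmB-like decoy reports present-but-unrecoded", {
  prot <- c(decoy = specs$reference[specs$key == "mtmB_like"])
  rows <- classify_pathway_genes(prot, specs)
  inv <- build_inventory("test", rows, trna_hits = NULL, recoding = NULL)
  r <- inv$rows[inv$rows$key == "mtmB_like", ]
  expect_equal(r$status, "present")
  expect_equal(r$note, "no conserved in-frame TAG")
  expect_equal(inv$verdict, "negative")
})

test_that("full cassette minus tRNA reproduces the partial verdict pattern", {
  keys <- c("pylB", "pylC", "pylD", "pylS_N", "pylS_C")
  prot <- setNames(specs$reference[match(keys, specs$key)], keys)
  rows <- classify_pathway_genes(prot, specs)
  mttb <- specs[specs$key == "mttB", ]
  recoding <- data.frame(spec_key = "mttB", codon = "TAG",
                         codon_index = mttb$recoded_index,
                         inserted_residue = "O", conserved = TRUE)
  inv <- build_inventory("test", rows, trna_hits = NULL,
                         recoding = recoding)
  expect_equal(inv$verdict, "partial")
  expect_equal(inv$missing_components, "pyl_tRNA")
})
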