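# Independent brute-force oracles. Deliberately naive: plain loops and
# explicit enumeration, sharing no code path with the package internals
# they check.

# --- affine-gap DP, plain matrix recursion -----------------------------
# Gap of length L costs open + L * ext (first gap residue open + ext).
oracle_align_score <- function(a, b, mode = "global",
                               open = 11, ext = 1,
                               mat = gce_substitution_matrix()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # a-residue aligned to gap
  Y <- matrix(NEG, n + 1, m + 1)  # b-residue aligned to gap
  M[1, 1] <- 0
  if (mode == "global") {
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  best_local <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      diag_best <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- s + diag_best
      if (mode == "local") {
        M[i + 1, j + 1] <- max(M[i + 1, j + 1], s)  # restart at this pair
        if (M[i + 1, j + 1] < 0) M[i + 1, j + 1] <- NEG
        best_local <- max(best_local, M[i + 1, j + 1])
      }
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  if (mode == "global") max(M[n + 1, m + 1], X[n + 1, m + 1],
                            Y[n + 1, m + 1])
  else best_local
}

# --- exhaustive ORF scan ------------------------------------------------
# Every start-codon position on both strands is walked to its terminator;
# within a (strand, frame, terminator) group the longest ORF survives.
oracle_orfs <- function(contig, table, min_aa) {
  L <- nchar(contig)
  revcomp <- function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  out <- list()
  for (strand in c("+", "-")) {
    sseq <- if (strand == "+") contig else revcomp(contig)
    for (p in seq_len(L - 2)) {
      codon <- substr(sseq, p, p + 2)
      if (!(codon %in% table$starts)) next
      q <- p
      prot <- character(0)
      terminator <- NA_character_
      term_pos <- NA_integer_
      while (q + 2 <= L) {
        cd <- substr(sseq, q, q + 2)
        if (cd %in% table$stops) { terminator <- cd; term_pos <- q; break }
        prot <- c(prot, if (grepl("N", cd)) "X" else table$codon_map[[cd]])
        q <- q + 3
      }
      if (length(prot) < min_aa) next
      loc_start <- p - 1L
      loc_end <- if (is.na(term_pos)) q - 1L else term_pos + 2L
      if (strand == "+") { g1 <- loc_start; g2 <- loc_end }
      else { g1 <- L - loc_end; g2 <- L - loc_start }
      out[[length(out) + 1L]] <- data.frame(
        start = g1, end = g2, strand = strand,
        frame = (p - 1L) %% 3L,
        terminator = terminator, term_key =
          paste(strand, (p - 1L) %% 3L,
                if (is.na(term_pos)) "edge" else term_pos),
        protein = paste(prot, collapse = ""),
        partial3 = is.na(terminator), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0)))
  df <- do.call(rbind, out)
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$term_key), function(ix)
    ix[which.max(nchar(df$protein[ix]))]))
  df <- df[sort(keep), c("start", "end", "strand", "frame", "protein",
                         "terminator", "partial3")]
  df <- df[order(df$start, df$end, df$strand), ]
  rownames(df) <- NULL
  df
}

# --- per-offset six-frame translation ----------------------------------
oracle_six_frame_fragments <- function(s, table, min_len = 1L) {
  revcomp <- function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  frags <- character(0)
  for (strand in c("+", "-")) {
    sseq <- if (strand == "+") s else revcomp(s)
    for (off in 0:2) {
      cur <- character(0)
      q <- off + 1L
      while (q + 2 <= nchar(sseq)) {
        cd <- substr(sseq, q, q + 2)
        r <- if (grepl("N", cd)) "X" else table$codon_map[[cd]]
        if (r == "*") {
          if (length(cur)) frags <- c(frags, paste(cur, collapse = ""))
          cur <- character(0)
        } else cur <- c(cur, r)
        q <- q + 3L
      }
      if (length(cur)) frags <- c(frags, paste(cur, collapse = ""))
    }
  }
  sort(frags[nchar(frags) >= min_len])
}

# --- exhaustive all-window, all-geometry cloverleaf oracle --------------
# Checks every window start against every (D-loop, variable-arm) geometry
# with explicit substring extraction; returns raw (uncollapsed) hits.
oracle_trna_raw <- function(seq, anticodons, params = trna_scan_params()) {
  revcomp <- function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  pairs <- c(AT = TRUE, TA = TRUE, CG = TRUE, GC = TRUE,
             GT = TRUE, TG = TRUE)
  paired <- function(x, y) {
    xv <- strsplit(x, "")[[1]]; yv <- rev(strsplit(y, "")[[1]])
    sum(vapply(seq_along(xv), function(i)
      isTRUE(pairs[paste0(xv[i], yv[i])]), NA))
  }
  L <- nchar(seq)
  hits <- list()
  for (strand in c("+", "-")) {
    sseq <- if (strand == "+") seq else revcomp(seq)
    for (ld in params$d_loop) for (lv in params$var_arm) {
      tot <- 60 + ld + lv
      if (tot < params$min_total_len) next
      if (tot > L) next
      for (w in 1:(L - tot + 1)) {
        win <- substr(sseq, w, w + tot - 1)
        anti <- substr(win, 26 + ld, 28 + ld)
        if (!(anti %in% anticodons)) next
        acc <- paired(substr(win, 1, 7), substr(win, 53 + ld + lv, 59 + ld + lv))
        dd <- paired(substr(win, 10, 13), substr(win, 14 + ld, 17 + ld))
        aca <- paired(substr(win, 19 + ld, 23 + ld),
                      substr(win, 31 + ld, 35 + ld))
        tt <- paired(substr(win, 36 + ld + lv, 40 + ld + lv),
                     substr(win, 48 + ld + lv, 52 + ld + lv))
        ok <- acc >= params$min_acc && dd >= params$min_d &&
          aca >= params$min_ac && tt >= params$min_t &&
          (acc + dd + aca + tt) >= params$min_score
        if (ok && params$require_conserved)
          ok <- substr(win, 25 + ld, 25 + ld) == "T" &&
            substr(win, 41 + ld + lv, 43 + ld + lv) == "TTC"
        if (!ok) next
        s0 <- w - 1L
        if (strand == "+") { g1 <- s0; g2 <- s0 + tot }
        else { g1 <- L - (s0 + tot); g2 <- L - s0 }
        hits[[length(hits) + 1L]] <- data.frame(
          start = g1, end = g2, strand = strand, anticodon = anti,
          score = acc + dd + aca + tt, d_loop_len = ld,
          variable_arm_len = lv, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), anticodon = character(0),
                      score = integer(0)))
  do.call(rbind, hits)
}

# --- exhaustive hairpin maximisation ------------------------------------
oracle_best_hairpin <- function(region, min_stem, max_offset,
                                max_stem = 14) {
  pairs <- c(AT = TRUE, TA = TRUE, CG = TRUE, GC = TRUE,
             GT = TRUE, TG = TRUE)
  n <- nchar(region)
  all_hp <- list()
  for (off in 0:max_offset) for (s in min_stem:max_stem)
    for (lp in 3:12) {
      if (off + 2 * s + lp > n) next
      ok <- TRUE
      for (i in 1:s) {
        x <- substr(region, off + i, off + i)
        y <- substr(region, off + 2 * s + lp - i + 1,
                    off + 2 * s + lp - i + 1)
        if (!isTRUE(pairs[paste0(x, y)])) { ok <- FALSE; break }
      }
      if (ok) all_hp[[length(all_hp) + 1L]] <-
          c(offset = off, stem = s, loop = lp)
    }
  if (!length(all_hp)) return(NULL)
  df <- as.data.frame(do.call(rbind, all_hp))
  df <- df[order(-df$stem, df$offset, df$loop), ]
  as.list(df[1, ])
}

# --- misc generators ----------------------------------------------------
random_protein <- function(n, aa = c("A","R","N","D","C","Q","E","G","H",
                                     "I","L","K","M","F","P","S","T","W",
                                     "Y","V")) {
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# CDS of `n_codons` sense codons (no stops, optionally no TAG either)
random_cds <- function(n_codons, table = genetic_code("bact11"),
                       exclude = c("TAA", "TAG", "TGA")) {
  pool <- setdiff(names(table$codon_map), exclude)
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}
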