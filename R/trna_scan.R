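# Anticodon-constrained cloverleaf scan for tRNA genes.
#
# The scanner uses a parametric cloverleaf template (lengths in nt):
#   acceptor stem 7 | spacer 2 | D stem 4 | D loop 4-11 | D stem' 4 |
#   spacer 1 | anticodon stem 5 | anticodon loop 7 (anticodon centred,
#   preceded by the conserved U33) | anticodon stem' 5 | variable arm 0-23 |
#   T stem 5 | T loop 7 (starting with the conserved T54-T55-C56 "TTC") |
#   T stem' 5 | acceptor stem' 7 | discriminator 1
# Total length 60 + D-loop + variable arm, constrained to >= 70 nt.
# Base pairs are Watson-Crick plus G-T wobble. A hit must reach the
# per-arm minima AND a total paired-bases floor (default 19 of 21); the
# conserved bases and the floor keep the false-positive rate on random
# sequence near zero (see the methods vignette for the calculation).

#' @noRd
pair_ok_matrix <- function() {
  m <- matrix(FALSE, 5, 5, dimnames = list(c("A","C","G","T","N"),
                                           c("A","C","G","T","N")))
  m["A","T"] <- m["T","A"] <- m["C","G"] <- m["G","C"] <- TRUE
  m["G","T"] <- m["T","G"] <- TRUE
  m
}

#' Default stringency parameters for the tRNA scanner
#'
#' @return A list: per-arm paired-base minima (`min_acc` of 7, `min_d` of
#'   4, `min_ac` of 5, `min_t` of 5), total floor `min_score` (of 21),
#'   D-loop and variable-arm length ranges, `require_conserved` for the
#'   U33 / T-loop TTC identity bases.
#' @export
trna_scan_params <- function() {
  list(min_acc = 6L, min_d = 3L, min_ac = 4L, min_t = 4L,
       min_score = 19L, d_loop = 4:11, var_arm = 0:23,
       min_total_len = 70L, require_conserved = TRUE)
}

#' Scan a contig for cloverleaf tRNAs with given anticodons
#'
#' Slides the cloverleaf template over both strands, anchored at
#' occurrences of the target anticodons. Overlapping hits (by more than
#' 50% of the shorter) are collapsed to the best-scoring one. The scan is
#' deterministic.
#'
#' @param contig A single DNA string.
#' @param target_anticodons DNA 3-mers as read 5'->3' in the anticodon
#'   loop; default `c("CTA", "TCA")` (pyrrolysine and selenocysteine).
#' @param contig_id Identifier recorded in hits.
#' @param params Stringency parameters, see [trna_scan_params()].
#' @return A data.frame of hits: `contig_id`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `anticodon` (DNA),
#'   `anticodon_rna`, `acc_score`, `d_score`, `ac_score`, `t_score`,
#'   `score`, `d_loop_len`, `variable_arm_len`, `kind`
#'   (`pyl`/`sec`/`other`).
#' @export
scan_trna <- function(contig, target_anticodons = c("CTA", "TCA"),
                      contig_id = "contig", params = trna_scan_params()) {
  contig <- clean_dna(contig)
  stopifnot(all(nchar(target_anticodons) == 3L))
  L <- nchar(contig)
  pm <- pair_ok_matrix()
  hits <- list()
  for (strand in c("+", "-")) {
    sseq <- if (strand == "+") contig else reverse_complement(contig)
    cs <- chars(sseq)
    n <- length(cs)
    if (n < 70L) next
    for (anti in target_anticodons) {
      ac <- chars(anti)
      idx <- seq_len(n - 2L)
      anchors <- idx[cs[idx] == ac[1L] & cs[idx + 1L] == ac[2L] &
                       cs[idx + 2L] == ac[3L]]
      if (!length(anchors)) next
      for (ld in params$d_loop) for (lv in params$var_arm) {
        if (60L + ld + lv < params$min_total_len) next
        tot <- 60L + ld + lv
        w <- anchors - 25L - ld        # 1-based window starts
        ok <- w >= 1L & (w + tot - 1L) <= n
        w <- w[ok]
        if (!length(w)) next
        pair_cnt <- function(o1, o2, len) {
          s <- rep(0L, length(w))
          for (i in 0:(len - 1L))
            s <- s + pm[cbind(cs[w + o1 + i], cs[w + o2 + (len - 1L - i)])]
          s
        }
        acc <- pair_cnt(0L, 52L + ld + lv, 7L)
        dd <- pair_cnt(9L, 13L + ld, 4L)
        aca <- pair_cnt(18L + ld, 30L + ld, 5L)
        tt <- pair_cnt(35L + ld + lv, 47L + ld + lv, 5L)
        total <- acc + dd + aca + tt
        pass <- acc >= params$min_acc & dd >= params$min_d &
          aca >= params$min_ac & tt >= params$min_t &
          total >= params$min_score
        if (params$require_conserved)
          pass <- pass & cs[w + 24L + ld] == "T" &
            cs[w + 40L + ld + lv] == "T" & cs[w + 41L + ld + lv] == "T" &
            cs[w + 42L + ld + lv] == "C"
        if (!any(pass)) next
        wp <- w[pass]
        s0 <- wp - 1L                 # strand-local 0-based start
        if (strand == "+") { g_start <- s0; g_end <- s0 + tot }
        else { g_start <- L - (s0 + tot); g_end <- L - s0 }
        hits[[length(hits) + 1L]] <- data.frame(
          contig_id = contig_id, start = g_start, end = g_end,
          strand = strand, anticodon = anti,
          anticodon_rna = chartr("T", "U", anti),
          acc_score = acc[pass], d_score = dd[pass], ac_score = aca[pass],
          t_score = tt[pass], score = total[pass], d_loop_len = ld,
          variable_arm_len = lv,
          kind = trna_kind(anti, lv), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out) || !nrow(out)) return(empty_trna_hits())
  collapse_overlaps(out)
}

#' @noRd
trna_kind <- function(anticodon, var_arm_len) {
  if (anticodon == "CTA") "pyl"
  else if (anticodon == "TCA" && var_arm_len >= 10L) "sec"
  else "other"
}

#' @noRd
empty_trna_hits <- function() {
  data.frame(contig_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), anticodon = character(0),
             anticodon_rna = character(0), acc_score = integer(0),
             d_score = integer(0), ac_score = integer(0),
             t_score = integer(0), score = integer(0),
             d_loop_len = integer(0), variable_arm_len = integer(0),
             kind = character(0))
}

# Greedy best-first collapse: a hit is kept only if it overlaps every
# already-kept hit by at most 50% of the shorter of the two.
#' @noRd
collapse_overlaps <- function(hits) {
  ord <- order(-hits$score, hits$start, hits$end)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      shorter <- min(hits$end[i] - hits$start[i],
                     hits$end[j] - hits$start[j])
      if (ov > 0.5 * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a synthetic cloverleaf tRNA gene
#'
#' Builds a DNA sequence that folds into the scanner's cloverleaf template
#' with perfect Watson-Crick stems, the conserved U33 and T-loop TTC
#' bases, and the requested anticodon. Used by the synthetic-data
#' generator and the packaged reference tRNAs.
#'
#' @param anticodon DNA 3-mer, e.g. `"CTA"` (pyrrolysine) or `"TCA"`
#'   (selenocysteine).
#' @param d_loop_len,var_arm_len Loop/arm lengths in nt (defaults 8 and,
#'   for `TCA`, 16 — the long "extra arm" — else 4).
#' @param seed Seed for the random filler bases.
#' @return A DNA string of length `60 + d_loop_len + var_arm_len`.
#' @export
synthetic_trna <- function(anticodon, d_loop_len = 8L,
                           var_arm_len = if (anticodon == "TCA") 16L else 4L,
                           seed = 1L) {
  with_seed(seed, {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rnd <- function(k) sample(c("A", "C", "G", "T"), k, replace = TRUE)
    rc <- function(x) rev(unname(comp[x]))
    acc5 <- rnd(7); d5 <- rnd(4); ac5 <- rnd(5); t5 <- rnd(5)
    acl <- c(rnd(1), "T", chars(anticodon), rnd(2))   # U33 before anticodon
    tl <- c("T", "T", "C", rnd(4))                    # T54-T55-C56
    paste(c(acc5, rnd(2), d5, rnd(d_loop_len), rc(d5), rnd(1),
            ac5, acl, rc(ac5), rnd(var_arm_len),
            t5, tl, rc(t5), rc(acc5), rnd(1)), collapse = "")
  })
}
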