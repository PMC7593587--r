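# Sequence primitives: reverse complement, translation under custom codon
# tables, six-frame translation, FASTA IO.

#' Reverse complement
#'
#' Watson-Crick reverse complement over the alphabet {A,C,G,T,N}. Lowercase
#' input is uppercased and RNA `U` mapped to `T` on ingest.
#'
#' @param s A single DNA string.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(s) {
  s <- clean_dna(s)
  vapply(s, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    "", USE.NAMES = FALSE)
}

# Residue vector for all complete codons of `s` read from offset 0, with '*'
# at stop codons and 'X' at codons containing N. The workhorse behind
# translate() and six_frame_translate().
#' @noRd
codon_residues <- function(s, table) {
  n <- nchar(s)
  nc <- n %/% 3L
  if (nc == 0L) return(character(0))
  starts <- seq.int(1L, by = 3L, length.out = nc)
  codons <- substring(s, starts, starts + 2L)
  res <- unname(table$codon_map[codons])
  res[is.na(res)] <- "X"  # codons containing N
  res
}

#' Translate a nucleotide sequence under a codon table
#'
#' Reading begins at offset 0. Readthrough codons of the table emit their
#' noncanonical residue (`O` for pyrrolysine, `U` for selenocysteine) and
#' translation continues; a stop codon ends translation according to
#' `stop_policy`. A codon containing `N` is emitted as `X`, never skipped.
#' An incomplete trailing codon is ignored with a warning.
#'
#' @param s A single DNA string (length >= 3).
#' @param table A [genetic_code()] table.
#' @param stop_policy `"truncate"` (default) stops before the terminator;
#'   `"trailing_star"` keeps a `*` for the terminator; `"error"` raises an
#'   error if a stop codon is encountered before the final codon position.
#' @return The amino-acid string.
#' @examples
#' translate("ATGGCAAAATAA", genetic_code("bact11"))
#' translate("ATGTAGGCATAA", genetic_code("pyl_readthrough"))
#' @export
translate <- function(s, table,
                      stop_policy = c("truncate", "error", "trailing_star")) {
  stop_policy <- match.arg(stop_policy)
  s <- clean_dna(s)
  if (nchar(s) < 3L) stop("sequence shorter than one codon", call. = FALSE)
  if (nchar(s) %% 3L != 0L)
    warning("incomplete trailing codon (", nchar(s) %% 3L,
            " nt) ignored", call. = FALSE)
  res <- codon_residues(s, table)
  stop_at <- which(res == "*")
  if (!length(stop_at)) return(paste(res, collapse = ""))
  first <- stop_at[1L]
  if (stop_policy == "error")
    stop("stop codon at codon position ", first, call. = FALSE)
  out <- res[seq_len(first - 1L)]
  if (stop_policy == "trailing_star") out <- c(out, "*")
  paste(out, collapse = "")
}

#' Six-frame translation split at stop codons
#'
#' Translates all six reading frames (three forward, three on the reverse
#' complement) under `table`, splitting each frame's translation at stop
#' codons. Readthrough codons of the table do not split.
#'
#' @param s A single DNA string (length >= 3).
#' @param table A [genetic_code()] table.
#' @param min_len Minimum fragment length (aa) to report; default 1.
#' @return A data.frame with columns `frame` (`"+1".."+3"`, `"-1".."-3"`),
#'   `aa_start` (1-based residue offset of the fragment within the frame's
#'   full translation), and `peptide`. Joining a frame's fragments with `*`
#'   (accounting for consecutive stops) reconstructs the frame translation.
#' @export
six_frame_translate <- function(s, table, min_len = 1L) {
  s <- clean_dna(s)
  if (nchar(s) < 3L) stop("sequence shorter than one codon", call. = FALSE)
  rc <- reverse_complement(s)
  out <- vector("list", 6L)
  k <- 0L
  for (strand in c("+", "-")) {
    str_seq <- if (strand == "+") s else rc
    for (off in 0:2) {
      k <- k + 1L
      frame_id <- paste0(strand, off + 1L)
      sub <- substr(str_seq, off + 1L, nchar(str_seq))
      res <- if (nchar(sub) >= 3L) codon_residues(sub, table) else character(0)
      frags <- split_at_stops(res)
      if (nrow(frags)) frags$frame <- frame_id
      out[[k]] <- frags
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out))
    return(data.frame(frame = character(0), aa_start = integer(0),
                      peptide = character(0)))
  out <- out[nchar(out$peptide) >= min_len, c("frame", "aa_start", "peptide")]
  rownames(out) <- NULL
  out
}

#' @noRd
split_at_stops <- function(res) {
  if (!length(res))
    return(data.frame(aa_start = integer(0), peptide = character(0)))
  is_stop <- res == "*"
  grp <- cumsum(is_stop)
  keep <- !is_stop
  if (!any(keep))
    return(data.frame(aa_start = integer(0), peptide = character(0)))
  starts <- tapply(seq_along(res)[keep], grp[keep], min)
  peps <- tapply(res[keep], grp[keep], paste, collapse = "")
  data.frame(aa_start = as.integer(starts), peptide = as.character(peps))
}

#' Read DNA sequences from FASTA or FASTQ
#'
#' @param path File path; FASTQ is detected from the `.fastq`/`.fq`
#'   extension (qualities are ignored). Sequences are uppercased and RNA
#'   `U` mapped to `T`.
#' @return A named character vector of sequences.
#' @export
read_dna <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  ss <- Biostrings::readBStringSet(path, format = fmt)
  if (!length(ss)) stop("no parseable records in ", path, call. = FALSE)
  seqs <- as.character(ss)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(seqs)))
    stop("empty sequence for record '", ids[which(!nzchar(seqs))[1]], "'",
         call. = FALSE)
  setNames(clean_dna(seqs, what = paste0("file ", basename(path))), ids)
}

#' Write sequences as wrapped FASTA
#'
#' @param seqs Named character vector (DNA or protein; `O`/`U` residues are
#'   written as-is).
#' @param path Output path.
#' @param width Line-wrap width, default 60.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
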