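# Writes the packaged genetic-code table files under inst/extdata/tables/.
# Deterministic; run from the repository root.
suppressMessages(library(Biostrings))

bases <- c("T", "C", "A", "G")
codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
std <- GENETIC_CODE[codons]  # residues for table 11 match the standard code

write_table <- function(file, name, starts, stops, readthrough) {
  cm <- std
  cm[stops] <- "*"
  cm[names(readthrough)] <- readthrough
  con <- file(file.path("inst", "extdata", "tables", file), "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# gcescan genetic-code table (", name, ")"),
    paste0("name: ", name),
    paste0("starts: ", paste(starts, collapse = " ")),
    paste0("stops: ", paste(stops, collapse = " ")),
    paste0("readthrough: ",
           paste(names(readthrough), readthrough, sep = "=", collapse = " ")),
    paste(codons, cm[codons])
  ), con)
}

starts <- c("ATG", "GTG", "TTG")
write_table("bact11.txt", "bact11", starts,
            stops = c("TAA", "TAG", "TGA"), readthrough = character(0))
write_table("pyl_readthrough.txt", "pyl_readthrough", starts,
            stops = c("TAA", "TGA"), readthrough = c(TAG = "O"))
write_table("sec_readthrough.txt", "sec_readthrough", starts,
            stops = c("TAA", "TAG"), readthrough = c(TGA = "U"))
cat("wrote 3 tables\n")
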