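# Ground-truth manifests: what was implanted where, and which transcripts
# were simulated from what. JSON on disk; round-trips exactly.

#' @noRd
new_manifest <- function(seed, genome_id, length_nt, gc_fraction,
                         implants, transcripts = NULL) {
  m <- list(seed = as.integer(seed), genome_id = genome_id,
            background = list(length_nt = as.integer(length_nt),
                              gc_fraction = as.numeric(gc_fraction)),
            implants = implants, transcripts = transcripts)
  normalize_manifest(structure(m, class = "gce_manifest"))
}

# Canonical column types so that write -> read -> identical holds.
#' @noRd
normalize_manifest <- function(m) {
  im <- m$implants
  if (!is.null(im) && nrow(im)) {
    for (cl in c("start", "end", "recoded_codon_index"))
      im[[cl]] <- as.integer(im[[cl]])
    im$divergence_pct_applied <- as.numeric(im$divergence_pct_applied)
    rownames(im) <- NULL
  }
  m$implants <- im
  tr <- m$transcripts
  if (!is.null(tr) && nrow(tr)) {
    for (cl in c("window_start", "window_len"))
      tr[[cl]] <- as.integer(tr[[cl]])
    tr$aa_divergence_pct <- as.numeric(tr$aa_divergence_pct)
    tr$covers_recoded_site <- as.logical(tr$covers_recoded_site)
    rownames(tr) <- NULL
  }
  m$transcripts <- tr
  m
}

#' Write a manifest to JSON
#' @param manifest A `gce_manifest`.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a manifest from JSON
#' @param path Path written by [write_manifest()].
#' @return A `gce_manifest`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(m$implants)) m$implants <- as.data.frame(m$implants)
  if (!is.null(m$transcripts) && length(m$transcripts))
    m$transcripts <- as.data.frame(m$transcripts)
  else m$transcripts <- NULL
  normalize_manifest(structure(m, class = "gce_manifest"))
}
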