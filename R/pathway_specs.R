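# Packaged reference set for the Pyl/Sec/TMA pathway. The reference
# proteins are synthetic stand-ins (fixed-seed generation, see
# data-raw/make_reference_set.R); they are versioned in the package so no
# download is ever needed. Each spec carries its own identity/coverage
# thresholds and, where the gene is expected to be recoded, the codon,
# inserted residue and 0-based recoded residue index of the reference.

#' Load the packaged pathway gene specifications
#'
#' @param dir Optional directory holding `pathway_specs.tsv` and
#'   `pathway_proteins.faa` in the packaged format; defaults to the
#'   package's reference set.
#' @return A data.frame of class `pathway_specs`, one row per pathway
#'   component: `key`, `display_name`, `min_identity`, `min_coverage`,
#'   `expects_codon`, `expects_residue`, `recoded_index`,
#'   `verdict_component`, `query_only`, `reference` (protein string),
#'   `ref_id`.
#' @export
load_pathway_specs <- function(dir = NULL) {
  if (is.null(dir))
    dir <- system.file("extdata", "reference", package = "gcescan")
  meta <- utils::read.table(file.path(dir, "pathway_specs.tsv"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, na.strings = "NA")
  aa <- Biostrings::readAAStringSet(file.path(dir, "pathway_proteins.faa"))
  ids <- sub("\\s.*$", "", names(aa))
  meta$reference <- as.character(aa)[match(meta$ref_id, ids)]
  if (anyNA(meta$reference))
    stop("reference protein missing for: ",
         paste(meta$key[is.na(meta$reference)], collapse = ", "),
         call. = FALSE)
  ok_res <- ifelse(is.na(meta$expects_residue), TRUE, mapply(
    function(p, i, r) substr(p, i + 1L, i + 1L) == r,
    meta$reference, meta$recoded_index, meta$expects_residue))
  if (!all(ok_res))
    stop("recoded_index does not address the recoded residue for: ",
         paste(meta$key[!ok_res], collapse = ", "), call. = FALSE)
  class(meta) <- c("pathway_specs", "data.frame")
  meta
}

#' Path to a packaged synthetic reference file
#'
#' Convenience accessor for the synthetic tRNA and selenoprotein CDS
#' sequences shipped with the package.
#'
#' @param file One of `"trna_pyl"`, `"trna_sec"`, `"grdA_cds"`.
#' @return File path.
#' @export
reference_file <- function(file = c("trna_pyl", "trna_sec", "grdA_cds")) {
  file <- match.arg(file)
  fn <- switch(file,
               trna_pyl = "trna_pyl_synthetic.fa",
               trna_sec = "trna_sec_synthetic.fa",
               grdA_cds = "grdA_like_cds_synthetic.fa")
  system.file("extdata", "reference", fn, package = "gcescan",
              mustWork = TRUE)
}
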