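# Genetic-code tables with per-codon stop/readthrough semantics.
#
# Tables are shipped as plain-text key-value files under
# inst/extdata/tables/. Three are packaged:
#   bact11          - standard bacterial code: stops TAA/TAG/TGA,
#                     starts ATG/GTG/TTG
#   pyl_readthrough - as bact11 but TAG is removed from the stop set and
#                     read through as pyrrolysine 'O'
#   sec_readthrough - as bact11 but TGA is read through as selenocysteine 'U'

BASES <- c("T", "C", "A", "G")
ALL_CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))

#' Load a genetic-code table
#'
#' Reads a packaged (or user-supplied) codon table and validates that the
#' stop, readthrough and coding codons partition all 64 codons.
#'
#' @param name Name of a packaged table (`"bact11"`, `"pyl_readthrough"`,
#'   `"sec_readthrough"`) or a path to a table file in the same format.
#' @return An object of class `genetic_code_table`: a list with `name`,
#'   `codon_map` (named character of length 64; stops are `"*"`),
#'   `stops`, `readthrough` (named character, codon -> residue), `starts`.
#' @examples
#' tab <- genetic_code("pyl_readthrough")
#' tab$readthrough
#' @export
genetic_code <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "tables", paste0(name, ".txt"),
                package = "gcescan", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    stop("unknown genetic-code table: ", name, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  hdr <- grepl(":", lines, fixed = TRUE)
  kv <- strsplit(sub(":\\s*", ":", lines[hdr]), ":", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", "")
  getv <- function(k) {
    v <- vals[match(k, keys)]
    if (is.na(v)) "" else v
  }
  splitws <- function(x) {
    x <- trimws(x)
    if (!nzchar(x)) character(0) else strsplit(x, "\\s+")[[1]]
  }
  tab_name <- trimws(getv("name"))
  starts <- splitws(getv("starts"))
  stops <- splitws(getv("stops"))
  rt_raw <- splitws(getv("readthrough"))
  readthrough <- character(0)
  if (length(rt_raw)) {
    parts <- strsplit(rt_raw, "=", fixed = TRUE)
    readthrough <- setNames(vapply(parts, `[`, "", 2L),
                            vapply(parts, `[`, "", 1L))
  }
  body <- strsplit(trimws(lines[!hdr]), "\\s+")
  codon_map <- setNames(vapply(body, `[`, "", 2L), vapply(body, `[`, "", 1L))
  tab <- structure(list(name = tab_name, codon_map = codon_map,
                        stops = stops, readthrough = readthrough,
                        starts = starts),
                   class = "genetic_code_table")
  validate_genetic_code(tab)
  tab
}

#' @noRd
validate_genetic_code <- function(tab) {
  cm <- tab$codon_map
  if (length(cm) != 64 || !setequal(names(cm), ALL_CODONS))
    stop("table '", tab$name, "' must map all 64 codons exactly once",
         call. = FALSE)
  if (any(duplicated(names(cm))))
    stop("table '", tab$name, "' has duplicate codon entries", call. = FALSE)
  stops <- tab$stops
  rt <- names(tab$readthrough)
  coding <- setdiff(ALL_CODONS, c(stops, rt))
  if (length(intersect(stops, rt)))
    stop("stop and readthrough codons overlap in '", tab$name, "'",
         call. = FALSE)
  if (length(stops) + length(rt) + length(coding) != 64)
    stop("stop/readthrough/coding roles do not partition the 64 codons in '",
         tab$name, "'", call. = FALSE)
  if (!all(cm[stops] == "*"))
    stop("stop codons must map to '*' in '", tab$name, "'", call. = FALSE)
  if (length(rt) && !all(cm[rt] == tab$readthrough))
    stop("readthrough codons disagree with the codon map in '", tab$name,
         "'", call. = FALSE)
  if (any(cm[coding] == "*"))
    stop("coding codon maps to '*' in '", tab$name, "'", call. = FALSE)
  if (!all(tab$starts %in% ALL_CODONS))
    stop("invalid start codon in '", tab$name, "'", call. = FALSE)
  invisible(tab)
}

#' @export
print.genetic_code_table <- function(x, ...) {
  cat("Genetic-code table '", x$name, "'\n", sep = "")
  cat("  stops:       ", paste(x$stops, collapse = " "), "\n", sep = "")
  if (length(x$readthrough))
    cat("  readthrough: ",
        paste(names(x$readthrough), x$readthrough, sep = "->",
              collapse = " "), "\n", sep = "")
  cat("  starts:      ", paste(x$starts, collapse = " "), "\n", sep = "")
  invisible(x)
}
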