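# Internal helpers: input cleaning, logging, seeded RNG.

#' @noRd
clean_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- regexpr("[^ACGTN]", x)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("non-IUPAC character '", substr(x[i], bad[i], bad[i]),
         "' at position ", bad[i], " of ", what,
         if (length(x) > 1) paste0(" (record ", i, ")") else "", call. = FALSE)
  }
  x
}

#' @noRd
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Run code with a private RNG stream, restoring the caller's state after.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Logging with stable, greppable prefixes. A log sink can be attached per run.
.log_env <- new.env(parent = emptyenv())
.log_env$file <- NULL

#' @noRd
log_sink <- function(path) {
  .log_env$file <- path
  if (!is.null(path) && file.exists(path)) unlink(path)
  invisible(path)
}

#' @noRd
log_msg <- function(level, ...) {
  line <- paste0("[gcescan] ", level, " ", paste0(..., collapse = ""))
  if (!is.null(.log_env$file))
    cat(line, "\n", file = .log_env$file, append = TRUE, sep = "")
  message(line)
  invisible(line)
}
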