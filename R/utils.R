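# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# delimiter from extension, overridable
.detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_delim <- function(path, sep = NULL) {
  read.delim(path, sep = .detect_sep(path, sep), header = TRUE,
             check.names = FALSE, stringsAsFactors = FALSE,
             na.strings = c("NA", ""), comment.char = "")
}

.write_delim <- function(df, path, sep = NULL) {
  write.table(df, path, sep = .detect_sep(path, sep), quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

# run expr under a local RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
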