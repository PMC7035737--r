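# shared internal helpers

# round half away from zero (matches printed percent cells like 6.78, 4.65)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# tissue codes are "<stage>-<organ>": 0-L, 5-Z, ...; organ letter maps to a
# tissue type pooled across stages in the summary tables
tissue_type <- function(tissue) {
  organ <- sub("^.*-", "", tissue)
  map <- c(L = "leaf", S = "sheath", P = "spikelet", Z = "panicle_axis")
  unname(map[organ])
}

# tab-delimited text with a '#'-prefixed header line
write_tsv_hash <- function(df, path) {
  header <- paste0("#", paste(names(df), collapse = "\t"))
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

read_tsv_hash <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_fmt("empty file: %s", path)
  lines[1] <- sub("^#", "", lines[1])
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
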