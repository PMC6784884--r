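#' Parse a genome constitution string
#'
#' A constitution string spells out the subgenome copies of an accession,
#' e.g. `"ABB"` for a triploid with one A and two B chromosome sets, or
#' `"AABB"` for an allotetraploid.
#'
#' @param text constitution string over the alphabet {A, B}, length 2-4.
#' @return Named integer vector `c(A = nA, B = nB)`.
#' @examples
#' parse_constitution("ABB")   # c(A = 1, B = 2)
#' parse_constitution("AAAB")  # c(A = 3, B = 1)
#' @export
parse_constitution <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  if (length(chars) < 2L || length(chars) > 4L || !all(chars %in% c("A", "B")))
    stop("constitution must be a string of 2-4 letters over {A, B}, got '",
         text, "'")
  c(A = sum(chars == "A"), B = sum(chars == "B"))
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits.  Used to stamp
# output files with a config fingerprint; not cryptographic.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    # xor touches only the low byte since b < 256
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), b)
    # 32-bit modular multiply via 16-bit split (keeps doubles exact)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * m) %% 65536 * 65536 + lo * m) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

config_hash <- function(config) {
  flat <- vapply(config, function(v) paste(format(v), collapse = ","), "")
  fnv1a(paste(names(flat), flat, sep = "=", collapse = ";"))
}

meta_header <- function(config = NULL, seed = NULL) {
  lines <- paste0("# polysub ",
                  as.character(utils::packageVersion("polysub")))
  if (!is.null(seed))
    lines <- c(lines, paste0("# seed: ", seed))
  if (!is.null(config))
    lines <- c(lines, paste0("# config: ", config_hash(config)))
  lines
}

# Tabular writer with '#' metadata header lines; readers skip them.
write_tsv_meta <- function(df, path, meta = character(), col.names = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(meta, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  invisible(path)
}

read_tsv_meta <- function(path, header = TRUE, col.names = NULL) {
  df <- read.table(path, sep = "\t", header = header, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!is.null(col.names)) names(df) <- col.names
  df
}

# Scan the '#' metadata lines of a file into a named character vector.
read_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "# ")]
  kv <- regmatches(lines, regexec("^# ([^:]+): (.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
}
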