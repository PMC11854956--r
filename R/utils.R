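# Small shared helpers.  Coordinates are 0-based half-open internally;
# GTF output is 1-based closed (converted at the boundary).

#' Reverse complement of an RNA/DNA character string
#'
#' Operates on plain character vectors in either T or U alphabet; the
#' alphabet of the input is preserved.
#'
#' @param x character vector of sequences (ACGT or ACGU).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    has_u <- grepl("U", s, fixed = TRUE) || grepl("u", s, fixed = TRUE)
    comp <- chartr("ACGTUacgtu", "TGCAAtgcaa", s)
    if (has_u) comp <- chartr("Tt", "Uu", comp)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Convert between DNA and RNA alphabets
#'
#' @param x character vector.
#' @return `to_rna` replaces T with U; `to_dna` replaces U with T.
#' @export
to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname to_rna
#' @export
to_dna <- function(x) chartr("Uu", "Tt", x)

# deterministic per-stage seed derived from a scenario seed; kept < 2^31
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage)
}

# 0-based half-open interval overlap length
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# distance between two 0-based half-open intervals (0 if they touch/overlap)
interval_distance <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# sample() without the scalar-x surprise: always samples from the elements
# of x, even when length(x) == 1
resample <- function(x, size = 1, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
}
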