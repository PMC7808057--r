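#' Construct an interval set
#'
#' An interval set is an ordered collection of genomic intervals in BED
#' semantics: 0-based, half-open `[start, end)` spans on named chromosomes.
#' Intervals are stored sorted by `(chrom, start, end)`; duplicates and
#' nested intervals are retained, never merged, because the raw interval
#' count `N` enters the similarity index directly and within-set containment
#' is a real feature of functional-genomics tracks (it is what lets the
#' cross-set intersection count exceed `N`).
#'
#' @param chrom character vector of chromosome names (opaque strings;
#'   `"chr1"` and `"1"` are distinct).
#' @param start,end integer coordinates; `end > start` is required, so every
#'   interval has length `end - start >= 1`.
#' @param name label for the set (defaults to `"interval_set"`); for sets
#'   read from disk this is the file name stem.
#' @return An object of class `interval_set`: a data frame with columns
#'   `chrom`, `start`, `end`, sorted by `(chrom, start, end)`, with the set
#'   name in `attr(, "name")`. `N` is `nrow()`.
#' @examples
#' interval_set("chr1", c(0L, 8L), c(5L, 9L), name = "toy")
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), name = "interval_set") {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(chrom), length(start), length(end))
  if (n > 0L) {  # recycle length-1 arguments, as data.frame() would
    if (length(chrom) == 1L) chrom <- rep.int(chrom, n)
    if (length(start) == 1L) start <- rep.int(start, n)
    if (length(end) == 1L) end <- rep.int(end, n)
  }
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  if (anyNA(chrom) || anyNA(start) || anyNA(end))
    stop("interval coordinates must be non-missing integers")
  if (any(end <= start))
    stop("all intervals must satisfy end > start (0-based half-open)")
  ord <- order(chrom, start, end, method = "radix")
  out <- data.frame(chrom = chrom[ord], start = start[ord], end = end[ord],
                    stringsAsFactors = FALSE)
  attr(out, "name") <- as.character(name)[1L]
  class(out) <- c("interval_set", "data.frame")
  out
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("Interval set '%s': N = %d interval%s on %d chromosome%s\n",
              attr(x, "name"), nrow(x), if (nrow(x) == 1L) "" else "s",
              length(unique(x$chrom)),
              if (length(unique(x$chrom)) == 1L) "" else "s"))
  if (nrow(x) > 0L) {
    show <- utils::head(as.data.frame(x), 6L)
    print(show, row.names = FALSE)
    if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Number of intervals in a set
#'
#' @param set an [interval_set()].
#' @return Integer count `N` (duplicates included).
#' @export
n_intervals <- function(set) {
  stopifnot(inherits(set, "interval_set"))
  nrow(set)
}

# strip .bed / .bed.gz / .gz to get the set label from a file name
bed_stem <- function(path) {
  base <- basename(path)
  sub("\\.bed(\\.gz)?$|\\.gz$", "", base)
}

#' Read a BED or gzip-compressed BED file
#'
#' Parses BED3+ (tab- or whitespace-separated). Gzip decoding is applied
#' when the file name ends in `.gz`. Lines starting with `#`, `track` or
#' `browser`, and blank lines, are skipped. Columns beyond the third
#' (names, scores, strand, ...) are ignored: the similarity metric uses only
#' the spans. Records with `end == start` are zero-length and can never
#' overlap anything under half-open coordinates, so they are dropped with a
#' warning rather than failing the whole file; `end < start` marks a corrupt
#' file and is a hard parse error.
#'
#' @param path path to a `.bed` or `.bed.gz` file.
#' @param min_fields minimum number of fields a data line must have
#'   (default 3); fewer is a parse error naming the line.
#' @return An [interval_set()] named after the file stem, sorted by
#'   `(chrom, start, end)`, with duplicates retained.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t5", "chr1\t8\t9", "chr2\t0\t3"), f)
#' read_bed(f)
#' @export
read_bed <- function(path, min_fields = 3L) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^\\s*$|^#|^track\\b|^browser\\b", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(interval_set(name = bed_stem(path)))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < min_fields))
    stop(sprintf("line %d of %s has %d field(s); at least %d required",
                 lineno[which(nf < min_fields)[1L]], path,
                 nf[which(nf < min_fields)[1L]], min_fields))
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start_s <- vapply(fields, `[[`, character(1), 2L)
  end_s <- vapply(fields, `[[`, character(1), 3L)
  start <- suppressWarnings(as.integer(start_s))
  end <- suppressWarnings(as.integer(end_s))
  bad <- which(is.na(start) | is.na(end) |
                 start_s != as.character(start) | end_s != as.character(end))
  if (length(bad) > 0L)
    stop(sprintf("line %d of %s: non-integer coordinates '%s' '%s'",
                 lineno[bad[1L]], path, start_s[bad[1L]], end_s[bad[1L]]))
  rev_ok <- end < start
  if (any(rev_ok))
    stop(sprintf("line %d of %s: end (%d) < start (%d) - corrupt record",
                 lineno[which(rev_ok)[1L]], path,
                 end[which(rev_ok)[1L]], start[which(rev_ok)[1L]]))
  zero <- end == start
  if (any(zero)) {
    warning(sprintf("%s: dropped %d zero-length record(s) (end == start)",
                    path, sum(zero)))
    chrom <- chrom[!zero]; start <- start[!zero]; end <- end[!zero]
  }
  interval_set(chrom, start, end, name = bed_stem(path))
}

#' Write an interval set as BED3
#'
#' Emits one `chrom<TAB>start<TAB>end` line per interval in sorted order;
#' gzip-compresses when the path ends in `.gz`. `read_bed(write_bed(S))`
#' reproduces `S` exactly (same coordinate multiset, same `N`).
#'
#' @param set an [interval_set()].
#' @param path destination path (`.bed` or `.bed.gz`).
#' @return Invisibly, the number of records written.
#' @export
write_bed <- function(set, path) {
  stopifnot(inherits(set, "interval_set"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(set) > 0L)
    writeLines(paste(set$chrom, set$start, set$end, sep = "\t"), con)
  else
    writeLines(character(), con)
  invisible(nrow(set))
}
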