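#' Search a BED database for sets similar to a query
#'
#' Scores the query against every `*.bed` / `*.bed.gz` file in a directory
#' with [compare_sets()] and ranks the results by the similarity index `S`,
#' descending (ties broken by dataset name, ascending). Exactly one
#' comparison is performed per database file. If the database contains a
#' byte-identical copy of the query, that copy scores `S = 1` and occupies
#' rank 1. Fisher-baseline columns (p-value, sample odds ratio, and their
#' ranks) are added only when a universe size is supplied — the baseline is
#' undefined without one.
#'
#' @param query path to the query BED file, or an [interval_set()].
#' @param database directory containing the database BED files.
#' @param universe optional universe size for the Fisher baseline columns.
#' @param recursive search the directory recursively.
#' @return Object of class `seqpare_search`: a data frame with one row per
#'   scored file, ordered by rank, with columns `rank`, `similarity`, `O`,
#'   `N1`, `N2`, `name` and — when `universe` is given — `p`, `odds_ratio`,
#'   `rank_p` (p ascending: smaller is better) and `rank_or` (odds ratio
#'   descending). Files that fail to parse are skipped with a warning and
#'   listed in `attr(, "skipped")`; the number of comparisons performed is
#'   in `attr(, "n_scored")`.
#' @seealso [write_report()] to serialise the ranking.
#' @export
seqpare_search <- function(query, database, universe = NULL,
                           recursive = FALSE) {
  if (is.character(query)) query <- read_bed(query)
  stopifnot(inherits(query, "interval_set"))
  if (!dir.exists(database)) stop("database directory not found: ", database)
  files <- list.files(database, pattern = "\\.bed(\\.gz)?$",
                      full.names = TRUE, recursive = recursive)
  files <- sort(files)
  if (length(files) == 0L)
    stop("no .bed or .bed.gz files in database directory: ", database)
  rows <- vector("list", length(files))
  skipped <- character()
  n_scored <- 0L
  for (k in seq_along(files)) {
    db_set <- tryCatch(read_bed(files[k]), error = function(e) {
      warning(sprintf("skipping unreadable database file %s: %s",
                      files[k], conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(db_set)) {
      skipped <- c(skipped, files[k])
      next
    }
    sc <- compare_sets(query, db_set)
    n_scored <- n_scored + 1L
    row <- data.frame(similarity = sc$S, O = sc$O, N1 = sc$N1, N2 = sc$N2,
                      name = attr(db_set, "name"),
                      stringsAsFactors = FALSE)
    if (!is.null(universe)) {
      n_int <- count_intersections(query, db_set)
      tab <- build_contingency(n_int, sc$N1, sc$N2, universe)
      row$p <- fisher_p(tab)
      row$odds_ratio <- odds_ratio(tab)
    }
    rows[[k]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("no database file could be read: ", database)
  out <- do.call(rbind, rows)
  out <- out[order(-out$similarity, out$name, method = "radix"), ,
             drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  if (!is.null(universe)) {
    out$rank_p <- rank(out$p, ties.method = "first")
    out$rank_or <- rank(-out$odds_ratio, ties.method = "first")
  }
  rownames(out) <- NULL
  structure(out, class = c("seqpare_search", "data.frame"),
            query = attr(query, "name"), universe = universe,
            skipped = skipped, n_scored = n_scored)
}

#' @export
print.seqpare_search <- function(x, ...) {
  cat(sprintf("Seqpare search: query '%s' against %d dataset(s)\n",
              attr(x, "query"), nrow(x)))
  df <- as.data.frame(x)
  df$similarity <- signif(df$similarity, 6)
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("... and %d more row(s)\n", nrow(x) - 10L))
  if (length(attr(x, "skipped")) > 0L)
    cat("skipped unreadable file(s):",
        paste(basename(attr(x, "skipped")), collapse = ", "), "\n")
  invisible(x)
}

#' Write a search ranking as TSV or markdown
#'
#' Serialises a [seqpare_search()] result with a stable column order
#' (`rank`, `similarity`, then `rank_p`, `p`, `rank_or`, `odds_ratio` when
#' the Fisher baseline was computed, then `name`). Similarities are printed
#' with 6 significant digits and p-values in scientific notation, so
#' repeated runs over the same database produce byte-identical reports.
#'
#' @param rows a [seqpare_search()] result.
#' @param path destination file.
#' @param format `"tsv"` (default) or `"markdown"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(rows, path, format = c("tsv", "markdown")) {
  stopifnot(inherits(rows, "seqpare_search"))
  format <- match.arg(format)
  has_fisher <- "p" %in% names(rows)
  cols <- if (has_fisher)
    c("rank", "similarity", "rank_p", "p", "rank_or", "odds_ratio", "name")
  else c("rank", "similarity", "name")
  df <- as.data.frame(rows)[, cols, drop = FALSE]
  df$similarity <- format(signif(df$similarity, 6), trim = TRUE)
  if (has_fisher) {
    df$p <- sprintf("%.3e", df$p)
    df$odds_ratio <- ifelse(is.infinite(rows$odds_ratio), "inf",
                            format(signif(rows$odds_ratio, 4), trim = TRUE))
  }
  df[] <- lapply(df, as.character)
  lines <- if (format == "tsv") {
    c(paste(cols, collapse = "\t"),
      apply(df, 1L, paste, collapse = "\t"))
  } else {
    c(paste0("| ", paste(cols, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
      paste0("| ", apply(df, 1L, paste, collapse = " | "), " |"))
  }
  skipped <- attr(rows, "skipped")
  if (length(skipped) > 0L)
    lines <- c(lines, paste0(if (format == "tsv") "# " else "",
                             "skipped: ", basename(skipped)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
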