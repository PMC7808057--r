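#' Jaccard similarity of two genomic intervals
#'
#' For intervals `v1`, `v2` with lengths `l1`, `l2` and half-open overlap
#' length `o`, the per-pair similarity is
#' \deqn{s = o / (l1 + l2 - o)}
#' the Jaccard index of the two spans: `s = 0` when they do not overlap
#' (including different chromosomes), `s = 1` exactly when they coincide.
#' Symmetric in its arguments.
#'
#' @param chrom1,start1,end1 first interval (0-based half-open).
#' @param chrom2,start2,end2 second interval.
#' @return Similarity in `[0, 1]`. Vectorised over all arguments.
#' @examples
#' interval_similarity("chr1", 1, 2, "chr1", 0, 5)  # 1/5
#' interval_similarity("chr1", 0, 5, "chr1", 4, 9)  # 1/9
#' @export
interval_similarity <- function(chrom1, start1, end1, chrom2, start2, end2) {
  stopifnot(all(end1 > start1), all(end2 > start2))
  o <- pmax(0, pmin(end1, end2) - pmax(start1, start2))
  o <- ifelse(chrom1 == chrom2, o, 0)
  ifelse(o > 0, o / ((end1 - start1) + (end2 - start2) - o), 0)
}

#' Select mutual-best-matching pairs greedily
#'
#' Implements the strict greedy rule that defines the total effective
#' overlap: repeatedly take the remaining intersection pair with the highest
#' similarity `s`, add it to the matching, and discard every remaining pair
#' that shares either of its intervals, until no pairs remain. Every
#' selected pair is a mutual best match among the pairs still available when
#' it is chosen, and a pair whose two intervals intersect only each other is
#' always selected. Ties in `s` are broken deterministically by
#' (set-1 index ascending, set-2 index ascending).
#'
#' @param pairs intersection pairs as returned by
#'   [enumerate_intersections()] (columns `i`, `j`, `o`, `s`); must be the
#'   complete cross-set list with no duplicated `(i, j)` entry.
#' @param n1,n2 interval counts of the two sets.
#' @return An object of class `mbm_result`: list with `pairs` (the chosen
#'   pairs in selection order), `O` (total effective overlap, the sum of `s`
#'   over chosen pairs, bounded by `min(n1, n2)`), `unmatched1`/`unmatched2`
#'   (positions left unpaired), and `n1`, `n2`. No interval position occurs
#'   in more than one chosen pair.
#' @export
select_mbm_pairs <- function(pairs, n1, n2) {
  stopifnot(is.data.frame(pairs), all(c("i", "j", "s") %in% names(pairs)),
            n1 >= 0, n2 >= 0)
  if (anyDuplicated(pairs[c("i", "j")]) > 0L)
    stop("duplicate (i, j) entries: pairs must be a cross-set ",
         "intersection list")
  chosen <- pairs[0L, , drop = FALSE]
  if (nrow(pairs) > 0L) {
    ord <- order(-pairs$s, pairs$i, pairs$j)
    p <- pairs[ord, , drop = FALSE]
    used1 <- logical(n1)
    used2 <- logical(n2)
    take <- logical(nrow(p))
    for (k in seq_len(nrow(p))) {
      i <- p$i[k]; j <- p$j[k]
      if (!used1[i] && !used2[j]) {
        take[k] <- TRUE
        used1[i] <- TRUE
        used2[j] <- TRUE
      }
    }
    chosen <- p[take, , drop = FALSE]
    rownames(chosen) <- NULL
  }
  O <- sum(chosen$s)
  structure(list(pairs = chosen, O = O,
                 unmatched1 = setdiff(seq_len(n1), chosen$i),
                 unmatched2 = setdiff(seq_len(n2), chosen$j),
                 n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "mbm_result")
}

#' @export
print.mbm_result <- function(x, ...) {
  cat(sprintf("Mutual-best-matching: %d pair(s), O = %.6g (N1 = %d, N2 = %d)\n",
              nrow(x$pairs), x$O, x$n1, x$n2))
  if (nrow(x$pairs) > 0L) print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' The interval-set similarity index
#'
#' Combines the total effective overlap `O` with the two set sizes:
#' \deqn{S = O / (N1 + N2 - O)}
#' a Jaccard-style ratio of effective overlap over effective union.
#' `S` lies in `[0, 1]`; `S = 0` exactly when there is no matching pair, and
#' `S = 1` forces `N1 = N2 = O`, i.e. every interval of each set perfectly
#' matched. When both sets are empty the ratio is 0/0; the index is defined
#' as 0 there (no evidence of similarity), with a message.
#'
#' @param O total effective overlap, `0 <= O <= min(n1, n2)`.
#' @param n1,n2 interval counts.
#' @param pair_count number of matched pairs (optional bookkeeping).
#' @return Object of class `seqpare`: list with `S`, `O`, `N1`, `N2`,
#'   `pair_count`.
#' @examples
#' seqpare_index(2, 2, 2)$S    # 1: identical two-interval sets
#' seqpare_index(2/5, 3, 3)$S  # 1/14
#' @export
seqpare_index <- function(O, n1, n2, pair_count = NA_integer_) {
  stopifnot(length(O) == 1L, n1 >= 0, n2 >= 0)
  if (O < 0 || O > min(n1, n2) + 1e-9)
    stop(sprintf("O = %g outside [0, min(N1, N2) = %g]", O, min(n1, n2)))
  if (n1 + n2 == 0) {
    message("both sets empty: similarity defined as 0 (0/0 case)")
    S <- 0
  } else {
    S <- O / (n1 + n2 - O)
  }
  structure(list(S = S, O = O, N1 = as.integer(n1), N2 = as.integer(n2),
                 pair_count = as.integer(pair_count)),
            class = "seqpare")
}

#' Compare two interval sets
#'
#' The full pipeline: enumerate all cross-set intersecting pairs, select the
#' mutual-best-matching pairs greedily, accumulate the total effective
#' overlap `O`, and form the index `S = O / (N1 + N2 - O)`. Symmetric:
#' `compare_sets(A, B)$S == compare_sets(B, A)$S`. A set compared with
#' itself scores exactly 1 through the same code path (every interval's best
#' mutual match with its own copy has `s = 1`), including sets with internal
#' nesting and duplicates.
#'
#' @param setA,setB [interval_set()] objects, or paths to BED/BED.gz files
#'   (read with [read_bed()]).
#' @param detail if `TRUE`, attach the full [select_mbm_pairs()] result as
#'   `$mbm`.
#' @return Object of class `seqpare` with `S`, `O`, `N1`, `N2`,
#'   `pair_count`, `names` (the two set labels) and optionally `mbm`.
#' @examples
#' fx <- make_figure1_fixture("b")
#' compare_sets(fx$set1, fx$set2)  # S = 1/14
#' @export
compare_sets <- function(setA, setB, detail = FALSE) {
  if (is.character(setA)) setA <- read_bed(setA)
  if (is.character(setB)) setB <- read_bed(setB)
  stopifnot(inherits(setA, "interval_set"), inherits(setB, "interval_set"))
  pairs <- enumerate_intersections(setA, setB)
  mbm <- select_mbm_pairs(pairs, nrow(setA), nrow(setB))
  score <- seqpare_index(mbm$O, nrow(setA), nrow(setB),
                         pair_count = nrow(mbm$pairs))
  score$names <- c(attr(setA, "name"), attr(setB, "name"))
  if (isTRUE(detail)) score$mbm <- mbm
  score
}

#' @export
print.seqpare <- function(x, digits = 6, ...) {
  if (!is.null(x$names))
    cat(sprintf("Seqpare comparison: %s vs %s\n", x$names[1L], x$names[2L]))
  cat(sprintf("  S = %s  (O = %s, N1 = %d, N2 = %d, matched pairs = %s)\n",
              format(x$S, digits = digits), format(x$O, digits = digits),
              x$N1, x$N2,
              if (is.na(x$pair_count)) "?" else x$pair_count))
  invisible(x)
}

#' @export
summary.seqpare <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$mbm)) {
    m <- object$mbm
    cat(sprintf("  unmatched in set 1: %d, in set 2: %d\n",
                length(m$unmatched1), length(m$unmatched2)))
    if (nrow(m$pairs) > 0L)
      cat(sprintf("  per-pair s: min %.4g, median %.4g, max %.4g\n",
                  min(m$pairs$s), stats::median(m$pairs$s), max(m$pairs$s)))
  }
  invisible(object)
}
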