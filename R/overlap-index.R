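#' Build a per-chromosome overlap index
#'
#' The index is a single-component augmented interval list: for each
#' chromosome the intervals are held in start-sorted arrays together with a
#' running maximum of the ends, `maxend[k] = max(end[1..k])`. Because
#' `maxend` is non-decreasing, both boundaries of an overlap query can be
#' located by binary search even in the presence of nested intervals, and a
#' probe `[qs, qe)` can only overlap indexed intervals with
#' `start < qe` and `maxend > qs`.
#'
#' @param set an [interval_set()].
#' @return An object of class `interval_index`: a list with one entry per
#'   chromosome, each holding `start`, `end`, `maxend` and `rows` (the
#'   interval's position in the sorted set).
#' @export
build_index <- function(set) {
  stopifnot(inherits(set, "interval_set"))
  idx <- list()
  if (nrow(set) > 0L) {
    grp <- split(seq_len(nrow(set)), set$chrom)
    idx <- lapply(grp, function(rows) {
      # rows are already sorted by (start, end) within the chromosome
      list(start = set$start[rows], end = set$end[rows],
           maxend = cummax(set$end[rows]), rows = rows)
    })
  }
  structure(idx, class = "interval_index", n = nrow(set),
            set_name = attr(set, "name"))
}

#' @export
print.interval_index <- function(x, ...) {
  cat(sprintf("Interval index over %d interval(s), %d chromosome(s)\n",
              attr(x, "n"), length(x)))
  invisible(x)
}

#' Query an index with a single probe interval
#'
#' Returns every indexed interval on the probe's chromosome that overlaps
#' the probe by at least one base under half-open coordinates, i.e. with
#' `min(end, probe_end) - max(start, probe_start) >= 1`. Abutting intervals
#' (overlap length 0) are not hits. An unknown chromosome yields an empty
#' result.
#'
#' @param index an [build_index()] result.
#' @param chrom probe chromosome.
#' @param start,end probe span, 0-based half-open.
#' @return Data frame with columns `pos` (the hit's position in the indexed
#'   sorted set, ascending) and `o` (overlap length in bases).
#' @export
query_overlaps <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "interval_index"), end > start)
  empty <- data.frame(pos = integer(), o = integer())
  ch <- index[[as.character(chrom)]]
  if (is.null(ch)) return(empty)
  hi <- findInterval(end - 1L, ch$start)     # starts < probe end
  lo <- findInterval(start, ch$maxend) + 1L  # first maxend > probe start
  if (lo > hi) return(empty)
  cand <- lo:hi
  cand <- cand[ch$end[cand] > start]
  if (length(cand) == 0L) return(empty)
  data.frame(pos = ch$rows[cand],
             o = as.integer(pmin(ch$end[cand], end) -
                              pmax(ch$start[cand], start)))
}

# shared construction of the intersection-pair data frame
ipair_frame <- function(i, j, o, l1, l2) {
  out <- data.frame(i = as.integer(i), j = as.integer(j), o = as.integer(o),
                    s = o / (l1 + l2 - o))
  out[order(out$i, out$j), , drop = FALSE]
}

empty_ipairs <- function() {
  data.frame(i = integer(), j = integer(), o = integer(), s = numeric())
}

#' Enumerate all cross-set intersecting interval pairs
#'
#' Finds every pair `(i, j)` with interval `i` of `setA` overlapping
#' interval `j` of `setB` by at least one base, and attaches the overlap
#' length `o` and the per-pair Jaccard similarity
#' `s = o / (l1 + l2 - o)`. Indices refer to positions in the sorted sets.
#' The result for `(A, B)` is the `(j, i)`-transpose of the result for
#' `(B, A)`.
#'
#' @param setA,setB [interval_set()] objects.
#' @return Data frame with columns `i`, `j`, `o`, `s`, ordered by `i` then
#'   `j`. One row per intersecting pair; `1 <= o <= min(l1, l2)` and
#'   `0 < s <= 1`, with `s == 1` exactly when the two intervals coincide.
#' @seealso [brute_force_intersections()] for the all-pairs oracle with an
#'   identical output contract.
#' @export
enumerate_intersections <- function(setA, setB) {
  stopifnot(inherits(setA, "interval_set"), inherits(setB, "interval_set"))
  if (nrow(setA) == 0L || nrow(setB) == 0L) return(empty_ipairs())
  idx <- build_index(setB)
  res <- vector("list", length(idx))
  k <- 0L
  for (chrom in names(idx)) {
    rowsA <- which(setA$chrom == chrom)
    if (length(rowsA) == 0L) next
    ch <- idx[[chrom]]
    qs <- setA$start[rowsA]
    qe <- setA$end[rowsA]
    hi <- findInterval(qe - 1L, ch$start)
    lo <- findInterval(qs, ch$maxend) + 1L
    cnt <- pmax(hi - lo + 1L, 0L)
    if (sum(cnt) == 0L) next
    jc <- sequence(cnt, from = lo)           # candidate positions within chrom
    ic <- rep.int(seq_along(rowsA), cnt)
    keep <- ch$end[jc] > qs[ic]
    jc <- jc[keep]; ic <- ic[keep]
    if (length(jc) == 0L) next
    o <- pmin(ch$end[jc], qe[ic]) - pmax(ch$start[jc], qs[ic])
    k <- k + 1L
    res[[k]] <- ipair_frame(rowsA[ic], ch$rows[jc], o,
                            qe[ic] - qs[ic], ch$end[jc] - ch$start[jc])
  }
  if (k == 0L) return(empty_ipairs())
  out <- do.call(rbind, res[seq_len(k)])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' All-pairs intersection oracle
#'
#' Brute-force `O(N1 * N2)` scan over every cross-set pair per chromosome,
#' with an output contract identical to [enumerate_intersections()]. Kept as
#' an independent correctness anchor for the indexed enumeration; intended
#' for small sets.
#'
#' @inheritParams enumerate_intersections
#' @return Same as [enumerate_intersections()].
#' @export
brute_force_intersections <- function(setA, setB) {
  stopifnot(inherits(setA, "interval_set"), inherits(setB, "interval_set"))
  if (nrow(setA) == 0L || nrow(setB) == 0L) return(empty_ipairs())
  chroms <- intersect(unique(setA$chrom), unique(setB$chrom))
  res <- lapply(chroms, function(chrom) {
    ia <- which(setA$chrom == chrom)
    jb <- which(setB$chrom == chrom)
    g <- expand.grid(i = ia, j = jb, KEEP.OUT.ATTRS = FALSE)
    o <- pmin(setA$end[g$i], setB$end[g$j]) -
      pmax(setA$start[g$i], setB$start[g$j])
    keep <- o >= 1L
    if (!any(keep)) return(NULL)
    ipair_frame(g$i[keep], g$j[keep], o[keep],
                setA$end[g$i[keep]] - setA$start[g$i[keep]],
                setB$end[g$j[keep]] - setB$start[g$j[keep]])
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) return(empty_ipairs())
  out <- do.call(rbind, res)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}
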