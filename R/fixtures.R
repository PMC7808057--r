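# Run code under a caller-supplied seed without disturbing the global RNG
# stream; every generator in this file is bit-reproducible given its seed.
with_seed <- function(seed, code) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so state can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Toy two-set geometries for the worked panel examples
#'
#' Minimal integer geometries reproducing the worked examples that motivate
#' the metric. No coordinates are published for the panels, only length
#' ratios and the resulting quantities; the coordinates below are derived so
#' that every printed value (intersection count n, per-pair s multiset,
#' matched-pair count, O, S) is reproduced simultaneously:
#'
#' * panel `"a"` — two identical sets of a length-5 and a length-1 interval
#'   (length ratio 1:5), the two intervals disjoint: n = 2, two matched
#'   pairs each with s = 1, so O = 2 and S = 1.
#' * panel `"b"` — lengths 1:3:5 per set, arranged so set 1's length-5
#'   interval `[0,5)` contains the length-1 `[1,2)` of set 2 (s = 1/5) and
#'   overlaps set 2's length-5 `[4,9)` by exactly 1 base (s = 1/9, which
#'   forces two length-5 intervals with a 1-base overlap), while set 1's
#'   `[8,9)` sits inside `[4,9)` (s = 1/5); the length-3 intervals of both
#'   sets touch nothing. n = 3, greedy matching keeps the two s = 1/5 pairs,
#'   O = 2/5, and with N1 = N2 = 3, S = (2/5)/(6 - 2/5) = 1/14.
#' * panel `"d"` — lengths 2:3:4: set 1 = `{[0,4), [2,4), [2,5)}`,
#'   set 2 = `{[0,4), [2,5)}`; all 6 cross pairs intersect, exactly the two
#'   coordinate-identical pairs have s = 1, and the middle set-1 interval
#'   `[2,4)` ends unmatched: its best match `[2,5)` prefers set 1's `[2,5)`,
#'   so the match is not mutual.
#'
#' Panel "c" of the original illustration is not reconstructed: only its
#' intersection count (4) is published, which under-determines the geometry;
#' its containment behaviour is covered by panel "d" and random tests.
#'
#' @param panel `"a"`, `"b"` or `"d"`.
#' @return List with elements `set1` and `set2` ([interval_set()] objects,
#'   named `fig1<panel>_set1` / `_set2`).
#' @examples
#' fx <- make_figure1_fixture("a")
#' compare_sets(fx$set1, fx$set2)$S  # exactly 1
#' @export
make_figure1_fixture <- function(panel = c("a", "b", "d")) {
  panel <- match.arg(panel)
  geo <- switch(panel,
    a = list(s1 = list(c(0L, 5L), c(8L, 9L)),
             s2 = list(c(0L, 5L), c(8L, 9L))),
    b = list(s1 = list(c(0L, 5L), c(8L, 9L), c(20L, 23L)),
             s2 = list(c(30L, 33L), c(1L, 2L), c(4L, 9L))),
    d = list(s1 = list(c(0L, 4L), c(2L, 4L), c(2L, 5L)),
             s2 = list(c(0L, 4L), c(2L, 5L))))
  mk <- function(coords, nm) {
    m <- do.call(rbind, coords)
    interval_set(rep("chr1", nrow(m)), m[, 1L], m[, 2L], name = nm)
  }
  list(set1 = mk(geo$s1, sprintf("fig1%s_set1", panel)),
       set2 = mk(geo$s2, sprintf("fig1%s_set2", panel)))
}

#' Seeded random interval set
#'
#' Generates `n` intervals with starts uniform on `[0, span)` and lengths
#' uniform on `length_range`, distributed uniformly over `n_chrom`
#' chromosomes. Duplicates and nesting are permitted (and at the default
#' densities common), matching the structure of real functional-genomics
#' tracks where one broad domain can contain many narrow peaks. The output
#' is bit-reproducible for a given argument set and seed, and the caller's
#' RNG stream is left untouched.
#'
#' @param n number of intervals (0 gives an empty set).
#' @param seed RNG seed (required: these sets feed property tests and
#'   search databases that must be reproducible).
#' @param n_chrom number of chromosomes `chr1..chrK`.
#' @param span start coordinates are drawn from `[0, span)` (bases).
#' @param length_range two integers, inclusive bounds for interval lengths;
#'   lower bound must be at least 1 and at most the upper bound.
#' @param name set label.
#' @return An [interval_set()].
#' @export
random_interval_set <- function(n, seed, n_chrom = 1L, span = 1e5,
                                length_range = c(1L, 1000L),
                                name = sprintf("random_seed%d", as.integer(seed))) {
  stopifnot(length(n) == 1L, n >= 0, n_chrom >= 1L, span >= 1)
  if (length(length_range) != 2L || length_range[1L] < 1L ||
      length_range[1L] > length_range[2L])
    stop("length_range must be increasing integer bounds with minimum >= 1")
  if (n == 0) return(interval_set(name = name))
  with_seed(seed, {
    chrom <- paste0("chr", sample.int(n_chrom, n, replace = TRUE))
    start <- sample.int(span, n, replace = TRUE) - 1L
    len <- sample.int(length_range[2L] - length_range[1L] + 1L, n,
                      replace = TRUE) + length_range[1L] - 1L
    interval_set(chrom, start, start + len, name = name)
  })
}

#' Perturb an interval set
#'
#' Returns a copy whose intervals are independently dropped, shifted and
#' resized — the knob used by the similarity-decay property tests: the more
#' a copy is perturbed, the lower its similarity with the original should
#' trend. With all rates at zero the copy is identical. Resizing moves the
#' end coordinate only and never below `start + 1`, so `end > start` is
#' preserved.
#'
#' @param set an [interval_set()].
#' @param drop_rate probability in `[0, 1]` of removing each interval.
#' @param shift_max maximum absolute shift in bases (uniform on
#'   `[-shift_max, shift_max]`, truncated so starts stay non-negative).
#' @param resize_max maximum absolute change of the end coordinate in bases.
#' @param seed RNG seed (required).
#' @return A perturbed [interval_set()].
#' @export
perturb_set <- function(set, drop_rate = 0, shift_max = 0, resize_max = 0,
                        seed) {
  stopifnot(inherits(set, "interval_set"),
            drop_rate >= 0, drop_rate <= 1, shift_max >= 0, resize_max >= 0)
  nm <- paste0(attr(set, "name"), "_perturbed")
  if (nrow(set) == 0L) return(interval_set(name = nm))
  with_seed(seed, {
    keep <- stats::runif(nrow(set)) >= drop_rate
    if (!any(keep)) {
      interval_set(name = nm)
    } else {
      chrom <- set$chrom[keep]
      start <- set$start[keep]
      end <- set$end[keep]
      if (shift_max > 0) {
        shift <- as.integer(round(stats::runif(length(start),
                                               -shift_max, shift_max)))
        shift <- pmax(shift, -start)  # keep coordinates non-negative
        start <- start + shift
        end <- end + shift
      }
      if (resize_max > 0) {
        delta <- as.integer(round(stats::runif(length(end),
                                               -resize_max, resize_max)))
        end <- pmax(end + delta, start + 1L)
      }
      interval_set(chrom, start, end, name = nm)
    }
  })
}
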