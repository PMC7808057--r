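#' Count cross-set intersection pairs
#'
#' The quantity `n` that Fisher's-exact-based interval search tools put in
#' the first contingency cell: the number of intersecting cross-set pairs.
#' Because one interval may contain or cover several intervals of the other
#' set (or of its own set, in a self-comparison), `n` can exceed `N1` and/or
#' `N2`, which is exactly what makes the `N1 - n` and `N2 - n` cells
#' negative and the baseline ill-defined.
#'
#' @inheritParams enumerate_intersections
#' @return Integer pair count, `nrow(enumerate_intersections(setA, setB))`.
#' @export
count_intersections <- function(setA, setB) {
  nrow(enumerate_intersections(setA, setB))
}

#' Build the Fisher contingency table for two interval sets
#'
#' Cells are `(n, N1 - n, N2 - n, m)` with
#' `m = universe - n - (N1 - n) - (N2 - n)` computed on the clamped cells.
#' The universe size (the hypothetical total number of intervals) is not
#' objectively defined for genomic interval sets and must be supplied by the
#' caller; no default is estimated. When `n > N1` or `n > N2` the negative
#' cells are clamped following the convention of the GIGGLE search tool:
#' to 0 for the p-value path and to 1 for the odds-ratio path, recorded in
#' the `clamped_p` / `clamped_or` flags. A negative `m` is floored at 0 with
#' a warning.
#'
#' @param n number of cross-set intersection pairs
#'   (see [count_intersections()]).
#' @param n1,n2 interval counts of the two sets.
#' @param universe total interval count of the assumed universe; must be
#'   positive.
#' @return Object of class `contingency_table`: list with the raw counts,
#'   the clamped 2x2 matrices `p_cells` and `or_cells`, and clamping flags.
#' @examples
#' build_contingency(2, 2, 2, universe = 100)  # [(2, 0), (0, 98)]
#' @export
build_contingency <- function(n, n1, n2, universe) {
  stopifnot(length(universe) == 1L, is.finite(universe))
  if (universe <= 0) stop("universe size must be positive")
  stopifnot(n >= 0, n1 >= 0, n2 >= 0)
  a <- n1 - n  # set-1-only cell
  b <- n2 - n  # set-2-only cell
  clamped_p <- a < 0 || b < 0
  a_p <- max(a, 0); b_p <- max(b, 0)
  a_or <- if (a < 0) 1 else a
  b_or <- if (b < 0) 1 else b
  m_p <- universe - n - a_p - b_p
  m_or <- universe - n - a_or - b_or
  clamped_m <- m_p < 0 || m_or < 0
  if (clamped_m) {
    warning("universe too small for the table: 'neither' cell was ",
            "negative and has been floored at 0")
    m_p <- max(m_p, 0); m_or <- max(m_or, 0)
  }
  cells <- function(a1, b1, m1)
    matrix(c(n, b1, a1, m1), nrow = 2L, byrow = TRUE,
           dimnames = list(set1 = c("in", "out"), set2 = c("in", "out")))
  structure(list(n = n, n1 = n1, n2 = n2, universe = universe,
                 p_cells = cells(a_p, b_p, m_p),
                 or_cells = cells(a_or, b_or, m_or),
                 clamped_p = clamped_p, clamped_or = clamped_p,
                 clamped_m = clamped_m),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table (n = %g, N1 = %g, N2 = %g, universe = %g)\n",
              x$n, x$n1, x$n2, x$universe))
  cat(sprintf("  p-value cells:    [(%g, %g), (%g, %g)]%s\n",
              x$p_cells[1, 1], x$p_cells[1, 2], x$p_cells[2, 1],
              x$p_cells[2, 2], if (x$clamped_p) "  [clamped]" else ""))
  cat(sprintf("  odds-ratio cells: [(%g, %g), (%g, %g)]%s\n",
              x$or_cells[1, 1], x$or_cells[1, 2], x$or_cells[2, 1],
              x$or_cells[2, 2], if (x$clamped_or) "  [clamped]" else ""))
  invisible(x)
}

#' Two-sided Fisher exact p-value of a contingency table
#'
#' The standard two-sided test: with all margins fixed, the p-value is the
#' sum of hypergeometric probabilities of every table at least as extreme as
#' (point probability no larger than) the observed one. Computed on the
#' p-value-path (zero-clamped) cells via [stats::fisher.test()].
#'
#' @param table a [build_contingency()] result.
#' @return p-value in `(0, 1]`.
#' @examples
#' fisher_p(build_contingency(2, 2, 2, 100))  # 2.02e-4 = 1 / choose(100, 2)
#' @export
fisher_p <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  stats::fisher.test(table$p_cells)$p.value
}

#' Sample odds ratio of a contingency table
#'
#' The cross-product ratio `(n * m) / ((N1 - n) * (N2 - n))` on the
#' odds-ratio-path (one-clamped) cells. Returns `Inf` when the denominator
#' is zero, which happens whenever one set's non-overlap cell is 0 — e.g.
#' for any comparison of identical small sets.
#'
#' @param table a [build_contingency()] result.
#' @return Non-negative ratio, possibly `Inf`.
#' @export
odds_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  num <- table$or_cells[1L, 1L] * table$or_cells[2L, 2L]
  den <- table$or_cells[1L, 2L] * table$or_cells[2L, 1L]
  if (den == 0) Inf else num / den
}
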