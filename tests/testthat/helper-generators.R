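# Shared generators for property-style tests. All derived seeds stay well
# below 2^31.

# A pair of random interval sets with mixed densities; small spans produce
# duplicates and heavy mutual overlap, wide length ranges produce nesting.
random_set_pair <- function(seed, max_n = 120L) {
  set.seed(seed)
  n1 <- sample(0:max_n, 1L)
  n2 <- sample(0:max_n, 1L)
  n_chrom <- sample(1:3, 1L)
  span <- sample(c(200, 2000, 50000), 1L)
  lmax <- sample(c(3L, 50L, 500L), 1L)
  list(
    a = random_interval_set(n1, seed = seed * 7L + 1L, n_chrom = n_chrom,
                            span = span, length_range = c(1L, lmax),
                            name = "A"),
    b = random_interval_set(n2, seed = seed * 7L + 2L, n_chrom = n_chrom,
                            span = span, length_range = c(1L, lmax),
                            name = "B")
  )
}

# A set guaranteed to contain nested intervals: every interval of length
# >= 3 also contributes its strict interior.
nested_set <- function(n, seed) {
  base <- random_interval_set(n, seed = seed, span = 5000,
                              length_range = c(3L, 300L), name = "nested")
  interval_set(c(base$chrom, base$chrom),
               c(base$start, base$start + 1L),
               c(base$end, base$end - 1L),
               name = "nested")
}

# Independent two-sided Fisher oracle: enumerate every table with the same
# margins and sum the probabilities of those no more probable than the
# observed one (with the conventional 1e-7 relative slack on "no more").
fisher_two_sided_oracle <- function(cells) {
  r1 <- sum(cells[1L, ]); r2 <- sum(cells[2L, ]); c1 <- sum(cells[, 1L])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  obs <- stats::dhyper(cells[1L, 1L], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

expect_same_coords <- function(x, y) {
  expect_identical(x$chrom, y$chrom)
  expect_identical(x$start, y$start)
  expect_identical(x$end, y$end)
}

expect_same_pairs <- function(x, y) {
  expect_equal(nrow(x), nrow(y))
  expect_identical(x$i, y$i)
  expect_identical(x$j, y$j)
  expect_identical(x$o, y$o)
  expect_equal(x$s, y$s, tolerance = 1e-15)
}
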