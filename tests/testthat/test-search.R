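make_db <- function(dir, k, seed, span = 1e5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(k)) {
    s <- random_interval_set(sample(50:400, 1L), seed = seed + i,
                             span = span, name = sprintf("db%02d", i))
    write_bed(s, file.path(dir, sprintf("db%02d.bed", i)))
  }
  dir
}

test_that("a byte-identical copy of the query ranks first with similarity 1", {
  set.seed(301)
  db <- make_db(tempfile("db"), k = 10, seed = 500)
  query <- file.path(tempdir(), "query.bed")
  write_bed(random_interval_set(300, seed = 777, name = "query"), query)
  file.copy(query, file.path(db, "copy_of_query.bed"))
  res <- seqpare_search(query, db)
  expect_equal(nrow(res), 11L)
  expect_identical(res$name[1L], "copy_of_query")
  expect_identical(res$rank[1L], 1L)
  expect_identical(res$similarity[1L], 1)
  expect_identical(attr(res, "n_scored"), 11L)
})

test_that("a one-file database reproduces the pairwise score", {
  fb <- make_figure1_fixture("b")
  db <- tempfile("db1"); dir.create(db)
  write_bed(fb$set2, file.path(db, "panel_b_set2.bed"))
  q <- tempfile(fileext = ".bed"); write_bed(fb$set1, q)
  res <- seqpare_search(q, db)
  expect_equal(nrow(res), 1L)
  expect_equal(res$similarity, 1 / 14, tolerance = 1e-12)
})

test_that("chromosome-disjoint databases score zero and tie-break by name", {
  db <- tempfile("db0"); dir.create(db)
  for (nm in c("zeta", "alpha", "mid"))
    write_bed(interval_set("chrOther", c(0, 50), c(10, 80), name = nm),
              file.path(db, paste0(nm, ".bed")))
  q <- tempfile(fileext = ".bed")
  write_bed(interval_set("chr1", 0, 100), q)
  res <- seqpare_search(q, db)
  expect_identical(res$similarity, c(0, 0, 0))
  expect_identical(res$name, c("alpha", "mid", "zeta"))
})

test_that("Fisher columns appear only with a universe and rank sensibly", {
  set.seed(302)
  db <- make_db(tempfile("dbF"), k = 5, seed = 900, span = 2000)
  q <- file.path(tempdir(), "queryF.bed")
  write_bed(random_interval_set(100, seed = 901, span = 2000,
                                name = "queryF"), q)
  plain <- seqpare_search(q, db)
  expect_false(any(c("p", "odds_ratio") %in% names(plain)))
  fish <- seqpare_search(q, db, universe = 1e6)
  expect_true(all(c("p", "odds_ratio", "rank_p", "rank_or") %in% names(fish)))
  # p ranks ascend with p, odds-ratio ranks descend with the ratio
  expect_identical(order(fish$p)[fish$rank_p], seq_len(nrow(fish)))
  expect_identical(fish$rank_p[order(fish$p)], seq_len(nrow(fish)))
  expect_identical(fish$rank_or[order(-fish$odds_ratio)], seq_len(nrow(fish)))
})

test_that("unreadable database files are skipped with a warning, bad dirs error", {
  db <- tempfile("dbX"); dir.create(db)
  write_bed(interval_set("chr1", 0, 10, name = "good"),
            file.path(db, "good.bed"))
  writeLines("chr1\tnot_a_number\t5", file.path(db, "broken.bed"))
  q <- tempfile(fileext = ".bed"); write_bed(interval_set("chr1", 0, 10), q)
  expect_warning(res <- seqpare_search(q, db), "skipping")
  expect_equal(nrow(res), 1L)
  expect_match(attr(res, "skipped"), "broken")
  expect_error(seqpare_search(q, tempfile("absent")), "not found")
  empty <- tempfile("dbE"); dir.create(empty)
  expect_error(seqpare_search(q, empty), "no .bed")
})

test_that("reports are byte-identical across runs and parse back exactly", {
  set.seed(303)
  db <- make_db(tempfile("dbR"), k = 6, seed = 1200)
  q <- file.path(tempdir(), "queryR.bed")
  write_bed(random_interval_set(150, seed = 1300, name = "queryR"), q)
  r1 <- seqpare_search(q, db, universe = 10000)
  r2 <- seqpare_search(q, db, universe = 10000)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_report(r1, f1); write_report(r2, f2)
  expect_identical(readLines(f1), readLines(f2))

  parsed <- utils::read.delim(f1, comment.char = "#")
  expect_identical(names(parsed), c("rank", "similarity", "rank_p", "p",
                                    "rank_or", "odds_ratio", "name"))
  expect_identical(parsed$rank, r1$rank)
  expect_equal(parsed$similarity, signif(r1$similarity, 6))

  fm <- tempfile(fileext = ".md")
  write_report(r1, fm, format = "markdown")
  md <- readLines(fm)
  expect_match(md[1L], "^\\| rank \\| similarity")
  expect_equal(length(md), nrow(r1) + 2L)

  # without Fisher columns the header shrinks
  fp <- tempfile(fileext = ".tsv")
  write_report(seqpare_search(q, db), fp)
  expect_identical(readLines(fp)[1L], "rank\tsimilarity\tname")
})

test_that("recursive discovery finds nested database files", {
  db <- tempfile("dbN"); sub <- file.path(db, "nested")
  dir.create(sub, recursive = TRUE)
  write_bed(interval_set("chr1", 0, 10, name = "top"),
            file.path(db, "top.bed"))
  write_bed(interval_set("chr1", 0, 10, name = "deep"),
            file.path(sub, "deep.bed"))
  q <- tempfile(fileext = ".bed"); write_bed(interval_set("chr1", 0, 10), q)
  expect_equal(nrow(seqpare_search(q, db)), 1L)
  expect_equal(nrow(seqpare_search(q, db, recursive = TRUE)), 2L)
})

test_that("the command-line wrapper compares and searches", {
  cli <- system.file("cli", "seqpare", package = "seqpare")
  expect_true(nzchar(cli))
  fx <- make_figure1_fixture("b")
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  write_bed(fx$set1, f1); write_bed(fx$set2, f2)
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- suppressWarnings(
    system2("Rscript", c(cli, "compare", f1, f2), stdout = TRUE, env = env))
  expect_true(any(grepl("S = 0.0714286", out)))
  bad <- suppressWarnings(
    system2("Rscript", c(cli, "compare", f1), stdout = TRUE,
            stderr = TRUE, env = env))
  expect_identical(attr(bad, "status"), 2L)
})
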