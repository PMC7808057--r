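Package: seqpare
Title: Self-Consistent Similarity Metric for Genomic Interval Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the similarity of two genomic interval sets (BED
    files) with a single self-consistent index: per-interval Jaccard
    similarities are combined over greedily selected mutual-best-matching
    interval pairs into a total effective overlap O, and the index
    S = O / (N1 + N2 - O) ranges from 0 (unrelated) to 1 (identical sets).
    Also implements the Fisher's-exact p-value / odds-ratio scoring used by
    interval-database search tools, including its negative-cell clamping
    convention, so the two approaches can be compared; provides a
    one-versus-many search over a directory of BED files ranked by the
    index, toy fixture geometries, and seeded random interval-set
    generators for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
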