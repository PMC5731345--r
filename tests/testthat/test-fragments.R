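test_that("SAM flag pairs classify fragment strand", {
  rec <- data.frame(
    reference_id = "plasmid",
    pos = c(102L, 301L, 500L, 700L, 900L),
    flag = c(163L, 83L, 99L, 147L, 0L),
    isize = c(200L, -200L, 150L, -150L, 100L))
  expect_warning(fr <- load_fragments(rec), "1 record")
  expect_equal(nrow(fr), 2)
  sense <- fr[fr$strand_class == "sense", ]
  expect_equal(sense$start, 102L)
  expect_equal(sense$end, 301L)
  anti <- fr[fr$strand_class == "antisense", ]
  expect_equal(anti$start, 500L)
  expect_equal(anti$end, 649L)
})

test_that("BED strand maps through the library orientation", {
  bed <- data.frame(chrom = "plasmid", start = 0L, end = 100L,
                    name = "f1", score = 0L, strand = "+")
  fwd <- load_fragments(bed, "forward")
  expect_equal(fwd$strand_class, "sense")
  expect_equal(fwd$start, 1L)   # BED 0-based converted
  expect_equal(fwd$end, 100L)
  rev_ <- load_fragments(bed, "reverse")
  expect_equal(rev_$strand_class, "antisense")
  expect_warning(
    load_fragments(data.frame(chrom = "p", start = c(0L, 10L),
                              end = c(100L, 10L), name = "f", score = 0L,
                              strand = "+"), "forward"),
    "dropped")
})

test_that("strand profiles count covering fragments and conserve mass", {
  fr <- fragment_alignments(rep("p", 3), c(1L, 6L, 20L), c(10L, 15L, 39L),
                            c("sense", "sense", "antisense"))
  prof <- build_strand_profiles(fr, 50L)
  expect_equal(prof$sense$values[7], 2)
  expect_equal(prof$sense$values[16], 0)
  expect_equal(sum(prof$sense$values), 10 + 10)   # sum of sense lengths
  expect_equal(sum(prof$antisense$values), 20)
  # antisense fragment leaves the sense profile untouched
  expect_equal(prof$sense$values[25], 0)
  # permutation invariance
  prof2 <- build_strand_profiles(fr[c(3, 1, 2), ], 50L)
  expect_identical(prof$sense$values, prof2$sense$values)
  # empty input
  empty <- build_strand_profiles(fr[0, ], 50L, reference_id = "p")
  expect_equal(sum(empty$sense$values) + sum(empty$antisense$values), 0)
  # out of bounds
  bad <- fragment_alignments("p", 45L, 60L, "sense")
  expect_error(build_strand_profiles(bad, 50L), "bounds")
})

test_that("bedGraph round trip reproduces profile values exactly", {
  set.seed(7)
  vals <- sample(c(0, 1.5, 2, 300.25), 200, replace = TRUE)
  p <- transcription_profile(vals, "p", "sense")
  path <- tempfile(fileext = ".bedgraph")
  write_profile_bedgraph(p, path)
  p2 <- read_profile_bedgraph(path, "sense")
  expect_identical(p2$values, p$values)
  expect_identical(p2$reference_id, "p")
})

test_that("fragment length distribution is the normalized length histogram", {
  fr <- fragment_alignments(rep("p", 4), c(1L, 1L, 1L, 1L),
                            c(50L, 50L, 100L, 100L), rep("sense", 4))
  d <- fragment_length_distribution(fr)
  expect_equal(d$lengths, c(50L, 100L))
  expect_equal(d$probabilities, c(0.5, 0.5))
  one <- fragment_length_distribution(c(100L, 100L, 100L))
  expect_equal(one$lengths, 100L)
  expect_equal(one$probabilities, 1)
  expect_error(fragment_length_distribution(fr[0, ]), "no fragments")
  expect_error(fld(c(10L, 20L), c(0.7, 0.7)), "sum to 1")
})

test_that("union-mode gene counting matches brute-force enumeration", {
  genes <- data.frame(name = c("A", "B", "C"),
                      start = c(100L, 480L, 900L),
                      end = c(500L, 800L, 1200L),
                      strand = c("+", "+", "-"),
                      stringsAsFactors = FALSE)
  # hand-picked cases: inside one gene; spanning two genes (ambiguous);
  # wrong strand; low mapq
  fr <- fragment_alignments(
    rep("p", 5), c(150L, 470L, 950L, 950L, 200L),
    c(250L, 520L, 1050L, 1050L, 300L),
    c("sense", "sense", "sense", "antisense", "sense"),
    mapq = c(60L, 60L, 60L, 60L, 5L))
  tab <- count_gene_fragments(fr, genes, min_mapq = 10)
  expect_equal(tab$counts[, 1], c(A = 1L, B = 0L, C = 1L))
  expect_equal(unname(tab$totals), 5L)

  # randomized property check against the oracle
  set.seed(42)
  for (rep in 1:5) {
    n <- 200
    st <- sample.int(1100, n, replace = TRUE)
    len <- sample.int(300, n, replace = TRUE)
    frr <- fragment_alignments(rep("p", n), st, pmin(st + len, 1300L),
                               sample(c("sense", "antisense"), n, TRUE),
                               mapq = sample(c(3L, 60L), n, TRUE))
    got <- count_gene_fragments(frr, genes)$counts[, 1]
    expect_equal(got, union_count_oracle(frr, genes))
  }
})

test_that("SAM files load through the Rsamtools adapter", {
  skip_if_not_installed("Rsamtools")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:plasmid\tLN:2000",
    paste("r1", 163, "plasmid", 101, 60, "50M", "=", 251, 200,
          paste(rep("A", 50), collapse = ""), "*", sep = "\t"),
    paste("r1", 83, "plasmid", 251, 60, "50M", "=", 101, -200,
          paste(rep("A", 50), collapse = ""), "*", sep = "\t")), sam)
  fr <- load_fragments_sam(sam)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$strand_class, "sense")
  expect_equal(fr$start, 101L)
  expect_equal(fr$end, 300L)
  expect_equal(fr$mapq, 60L)
})
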