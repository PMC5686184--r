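test_that("merge_intervals merges overlaps, keeps disjoint intervals, preserves bases", {
  m <- merge_intervals(gintervals(chrom = "c1", start = c(0, 5),
                                  end = c(10, 20)))
  expect_equal(m$start, 0)
  expect_equal(m$end, 20)

  m2 <- merge_intervals(gintervals(chrom = "c1", start = c(20, 0),
                                   end = c(30, 10)))
  expect_equal(m2$start, c(0, 20))
  expect_equal(m2$end, c(10, 30))

  expect_equal(nrow(merge_intervals(gintervals())), 0)

  set.seed(101)
  rnd <- gintervals(chrom = sample(c("c1", "c2"), 50, replace = TRUE),
                    start = s <- sample.int(500, 50, replace = TRUE),
                    end = s + sample.int(40, 50, replace = TRUE))
  m3 <- merge_intervals(rnd)
  expect_equal(sum(m3$end - m3$start), brute_union_bases(rnd))
  # pairwise disjoint and sorted
  by_chr <- split(m3, m3$chrom)
  for (b in by_chr) {
    expect_true(all(diff(b$start) > 0))
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  # idempotent
  expect_identical(merge_intervals(m3), m3)
})

test_that("distance_to_nearest_tss handles outside, inside and multi-TSS cases", {
  ann <- toy_annotation(c(1000, 5000))
  expect_equal(distance_to_nearest_tss(
    gintervals("c1", 1500, 1700), ann), 500)
  expect_equal(distance_to_nearest_tss(
    gintervals("c1", 1500, 1700), toy_annotation(1600)), 0)
  expect_equal(distance_to_nearest_tss(
    gintervals("c1", 2800, 3000), ann), 1800)
  expect_error(distance_to_nearest_tss(
    gintervals("cX", 0, 10), ann), "no reference TSS")
})

test_that("distance_to_nearest_tss agrees with an exhaustive pairwise scan", {
  set.seed(7)
  pos <- sample.int(1e6, 1000)
  ann <- toy_annotation(pos)
  for (r in 1:50) {
    s <- sample.int(1e6 - 2000, 1)
    iv <- gintervals("c1", s, s + sample.int(2000, 1))
    brute <- min(vapply(pos, function(p)
      max(0, iv$start - p, p - (iv$end - 1)), numeric(1)))
    expect_equal(distance_to_nearest_tss(iv, ann), brute)
  }
})

test_that("window_around clips to chromosome bounds and validates the center", {
  expect_equal(window_around(5000, 1000, 1e6)[, c("start", "end")],
               data.frame(start = 4000, end = 6000))
  expect_equal(window_around(300, 1000, 1e6)$start, 0)
  expect_equal(window_around(300, 1000, 1e6)$end, 1300)
  w <- window_around(5000, 1000, 5500)
  expect_equal(c(w$start, w$end), c(4000, 5500))
  expect_true(all(w$end - w$start <= 2000))
  expect_error(window_around(-1, 1000, 1e6), "outside")
  expect_error(window_around(1e6, 1000, 1e6), "outside")
  expect_error(window_around(10, 0, 1e6), "half_width")
})

test_that("interval validation rejects malformed coordinates", {
  expect_error(gintervals("c", 10, 10), "end > start")
  expect_error(gintervals("c", -1, 10), ">= 0")
  expect_error(gintervals("", 0, 10), "non-empty")
})

test_that("BED, GTF, FASTA and TSV readers round-trip generated fixtures", {
  dir <- withr::local_tempdir()

  bed <- gintervals(chrom = c("c1", "c2"), start = c(100, 0),
                    end = c(200, 50), strand = c("+", "-"),
                    name = c("a", "b"))
  write_bed(bed, f <- file.path(dir, "x.bed"))
  rb <- read_bed(f)
  expect_equal(rb$start, bed$start)
  expect_equal(rb$end, bed$end)
  expect_equal(rb$strand, bed$strand)
  expect_equal(rb$name, bed$name)

  gtf <- data.frame(chrom = "c1", start = c(10, 500), end = c(400, 900),
                    strand = "+", feature = "gene",
                    gene_id = c("gA", "gB"))
  write_gtf(gtf, g <- file.path(dir, "x.gtf"))
  rg <- read_gtf(g)
  expect_equal(rg$start, gtf$start)
  expect_equal(rg$end, gtf$end)
  expect_equal(rg$gene_id, gtf$gene_id)

  seqs <- c(s1 = "ACGU", s2 = "GGGCCC")
  write_fasta(seqs, fa <- file.path(dir, "x.fa"))
  expect_equal(read_fasta(fa), seqs)
  # T read as U by default
  writeLines(c(">t1", "ACGT"), fa2 <- file.path(dir, "y.fa"))
  expect_equal(unname(read_fasta(fa2)), "ACGU")

  df <- data.frame(a = 1:3, b = c("x", "y", "z"))
  write_tsv_file(df, tf <- file.path(dir, "x.tsv"))
  expect_equal(read_tsv_file(tf), df)
  # readers tolerate comment lines
  writeLines(c("# comment", readLines(tf)), tf)
  expect_equal(read_tsv_file(tf), df)
})
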