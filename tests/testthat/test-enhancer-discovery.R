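test_that("consensus_peaks applies the strict 70% replicate-support rule", {
  p <- function(s, e) gintervals("c1", s, e)
  # single replicate: everything kept with support 1
  one <- consensus_peaks(list(p(100, 200)))
  expect_equal(nrow(one), 1)
  expect_equal(one$replicate_support, 1)

  # 2 of 3 replicates = 66.7% <= 70%: dropped
  expect_equal(nrow(consensus_peaks(
    list(p(100, 200), p(120, 220), gintervals()))), 0)

  # 3 of 4 replicates = 75% > 70%: kept, span is the union
  cp <- consensus_peaks(list(p(100, 200), p(120, 220), p(90, 150),
                             gintervals()))
  expect_equal(nrow(cp), 1)
  expect_equal(c(cp$start, cp$end), c(90, 220))
  expect_equal(cp$replicate_support, 0.75)

  # output disjoint
  set.seed(31)
  reps <- lapply(1:3, function(r)
    gintervals("c1", s <- sort(sample.int(5000, 30)) * 10,
               s * 10 + sample.int(300, 30, replace = TRUE)))
  cc <- consensus_peaks(reps)
  expect_true(all(cc$start[-1] >= cc$end[-nrow(cc)]))
})

test_that("zscore_standardize matches the population-sd formula", {
  z <- zscore_standardize(c(1, 2, 3))$z
  expect_equal(z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(z, 4), c(-1.2247, 0, 1.2247))

  # location invariance
  x <- rnorm(20)
  expect_equal(zscore_standardize(x)$z, zscore_standardize(x + 100)$z,
               tolerance = 1e-9)
  expect_error(zscore_standardize(5), "at least 2")
  expect_error(zscore_standardize(rep(3, 10)), "degenerate")
})

test_that("filter criteria 1 and 4 fire on hand-built cases", {
  # population of 40 ordinary peaks + 1 near-TSS peak + 1 K4me3-high peak
  n <- 40
  starts <- 20000 + (0:(n - 1)) * 10000
  peaks <- gintervals("c1", c(starts, 500500, 600500),
                      c(starts + 500, 501000, 601000))
  ann <- annotation(tss = data.frame(gene_id = "g1", chrom = "c1",
                                     pos = 501200, strand = "+"))
  set.seed(42)
  sig_at <- function(centers, lambda) do.call(rbind, lapply(centers,
    function(ce) data.frame(chrom = "c1",
                            pos = ce + sample(-999:999, rpois(1, lambda),
                                              replace = TRUE),
                            strand = ".")))
  centers <- floor((peaks$start + peaks$end) / 2)
  k4me1 <- tag_set(sig_at(centers, 50))
  k4me3 <- tag_set(rbind(sig_at(centers[1:(n + 1)], 30),
                         sig_at(centers[n + 2], 3000)))
  k4peaks <- gintervals("c1", peaks$start - 300, peaks$end - 300)

  f <- filter_candidates(peaks, k4peaks, k4me1, k4me3, ann)
  # peak 500 bp from the TSS fails criterion 1 first
  expect_equal(f$trace$first_fail[n + 1], 1)
  # K4me3-high peak passes c3 (K4me1 normal) but fails c4
  expect_equal(f$trace$first_fail[n + 2], 4)
  expect_gte(f$trace$z_k4me3[n + 2], 3)
  # the z the filter used matches an independent recomputation
  pop <- which(f$trace$c1 & f$trace$c2)
  raw <- vapply(pop, function(i)
    sum(k4me3$positions$pos >= centers[i] - 1000 &
          k4me3$positions$pos < centers[i] + 1000), numeric(1))
  z_oracle <- (raw - mean(raw)) / sqrt(mean((raw - mean(raw))^2))
  expect_equal(f$trace$z_k4me3[pop], z_oracle, tolerance = 1e-9)
  # ordinary peaks survive
  expect_equal(sum(f$trace$kept), n)
})

test_that("filter cascade on a small decoy bundle keeps survivors and labels decoys", {
  cfg <- sim_config(seed = 23, n_true_enhancers = 50L,
                    n_decoys_per_class = 1L)
  b <- generate_genome_bundle(cfg)
  k27 <- consensus_peaks(b$peaks$h3k27ac, 0.7)
  k4 <- consensus_peaks(b$peaks$h3k4me1, 0.7)
  f <- filter_candidates(k27, k4, b$signal$h3k4me1, b$signal$h3k4me3,
                         b$annotation)
  expect_equal(nrow(f$candidates), 50)

  # retained candidates pass all seven criteria
  kept <- f$trace[f$trace$kept, ]
  expect_true(all(kept$c1 & kept$c2 & kept$c3 & kept$c4 & kept$c5 &
                    kept$c6 & kept$c7))

  # low-replicate decoys never reach the filter
  expect_equal(nrow(k27),
               sum(b$truth$survives_consensus))

  # conjunctive cascade: survivors fail no criterion, so dropping any one
  # criterion could only enlarge the survivor set
  dropped <- f$trace[!f$trace$kept, ]
  expect_true(all(rowSums(!dropped[, paste0("c", 1:7)], na.rm = TRUE) >= 1))
})
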