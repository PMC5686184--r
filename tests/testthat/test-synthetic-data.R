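test_that("genome bundle generation is deterministic and capacity-checked", {
  cfg <- sim_config(seed = 11, n_true_enhancers = 50L,
                    n_decoys_per_class = 1L, n_genes = 10L)
  b1 <- generate_genome_bundle(cfg)
  b2 <- generate_genome_bundle(cfg)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$peaks, b2$peaks)
  expect_identical(b1$signal$h3k4me3$positions, b2$signal$h3k4me3$positions)

  expect_error(generate_genome_bundle(
    sim_config(n_true_enhancers = 5000L, chrom_len = 1e5)),
    "capacity error")
  # z-score decoys need a large enough peak population
  expect_error(generate_genome_bundle(sim_config(n_true_enhancers = 20L)),
               "z-score decoy")
})

test_that("every bundle entity carries exactly one truth label with its planted violation", {
  b <- generate_genome_bundle(sim_config(seed = 3, n_true_enhancers = 50L,
                                         n_decoys_per_class = 1L))
  tr <- b$truth
  expect_equal(nrow(tr), 50 + 8 * 1)
  expect_equal(anyDuplicated(tr$entity_id), 0)
  expect_true(all(is.na(tr$expected_first_fail[tr$class %in%
                                                 c("true", "low_replicate")])))
  expect_equal(sort(unique(tr$expected_first_fail)), 1:7)
  # near-TSS decoys planted closer than 1 kb to a TSS, true enhancers farther
  for (i in which(tr$class == "near_tss"))
    expect_lt(distance_to_nearest_tss(
      gintervals(tr$chrom[i], tr$start[i], tr$end[i]), b$annotation), 1000)
  for (i in which(tr$class == "true"))
    expect_gte(distance_to_nearest_tss(
      gintervals(tr$chrom[i], tr$start[i], tr$end[i]), b$annotation), 1000)
})

test_that("tag counts follow the calibrated two-component mixture", {
  cfg <- sim_config(seed = 21)
  cand <- gintervals(chrom = "chrS1", start = (0:9999) * 3000,
                     end = (0:9999) * 3000 + 500)
  tc <- generate_tag_counts(cand, cfg)
  med_high <- median(tc$counts$count[tc$counts$component == "high"])
  expect_gte(med_high, 100)
  expect_lte(med_high, 150)
  frac_high <- mean(tc$counts$component == "high")
  expect_lt(abs(frac_high - 0.353), 0.02)

  # counting the generated tags back recovers each candidate's count
  for (i in sample.int(10000, 25))
    expect_equal(count_center_tags(cand[i, ], tc$tags), tc$counts$count[i])

  # high_fraction = 0 puts everything in the low component
  cfg0 <- sim_config(seed = 21,
                     tag_mixture = list(median_high = 123, median_low = 4,
                                        high_fraction = 1e-12,
                                        sdlog_high = 0.85, sdlog_low = 0.95))
  tc0 <- generate_tag_counts(cand[1:200, ], cfg0)
  expect_true(all(tc0$counts$component == "low"))

  expect_identical(generate_tag_counts(cand[1:50, ], cfg)$counts,
                   generate_tag_counts(cand[1:50, ], cfg)$counts)
})

test_that("catalog series follows the planted Weibull discovery curve", {
  cfg <- sim_config(seed = 5)
  cats <- generate_catalog_series(cfg)
  expect_length(cats, cfg$n_cell_types)
  expect_identical(cats, generate_catalog_series(cfg))

  # Monte-Carlo mean of the full-union count vs the closed form at x = 30
  totals <- vapply(1:200, function(s) {
    cc <- generate_catalog_series(sim_config(seed = 1000 + s))
    length(unique(unlist(lapply(cc, function(x) x$element_id))))
  }, numeric(1))
  truth30 <- expected_discovery_curve(cfg, 30)
  expect_lt(abs(mean(totals) - truth30) / truth30, 0.05)

  # a single cell type: the curve point is that catalogue's size
  cfg1 <- sim_config(seed = 5, n_cell_types = 1L)
  c1 <- generate_catalog_series(cfg1)
  expect_equal(length(c1), 1L)

  expect_error(generate_catalog_series(
    sim_config(weibull_truth = list(A = 500, b = 10, c = 1.3))),
    "c > 1")
  expect_error(generate_catalog_series(
    sim_config(weibull_truth = list(A = 1e7, b = 10, c = 1))),
    "capacity")
})

test_that("SNP panel plants the configured locus enrichment and LD structure", {
  dom <- gintervals(chrom = c("chrS1", "chrS2"), start = 0, end = 2e6)
  loci <- gintervals(chrom = "chrS1", start = (0:39) * 50000,
                     end = (0:39) * 50000 + 1000)
  cfg <- sim_config(seed = 13)
  p <- generate_snp_panel(cfg, loci, dom)
  expect_identical(p$disease, generate_snp_panel(cfg, loci, dom)$disease)

  # observed in-locus count within the 99% binomial band around fold * rho
  rho <- p$truth$locus_fraction
  k <- sum(p$disease$in_locus)
  band <- qbinom(c(0.005, 0.995), cfg$n_disease_snps, 8 * rho)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
  expect_true(all(p$ld_pairs$r2 >= 0 & p$ld_pairs$r2 <= 1))

  # fold = 1: disease and background rates agree
  cfg1 <- sim_config(seed = 13, planted_enrichment_fold = 1)
  p1 <- generate_snp_panel(cfg1, loci, dom)
  expect_lt(abs(mean(p1$disease$in_locus) - mean(p1$background$in_locus)),
            0.03)

  expect_error(generate_snp_panel(cfg, gintervals(), dom), "empty")
})

test_that("structure cases plant disruptive stem SNVs and neutral loop SNVs", {
  cfg <- sim_config(seed = 17,
                    structure = list(n_cases = 5L, stem_len = 5L,
                                     loop_len = 4L, flank_len = 2L))
  sc <- generate_structure_cases(cfg)
  expect_length(sc$seqs, 5)
  expect_equal(nrow(sc$snvs), 10)
  expect_true(all(sc$snvs$alt != sc$snvs$ref))
  # ref matches sequence at the stated position
  for (i in seq_len(nrow(sc$snvs))) {
    s <- sc$snvs[i, ]
    expect_equal(substr(sc$seqs[[s$seq_id]], s$pos + 1, s$pos + 1), s$ref)
  }

  # on an oracle-sized case (18 nt) the disruptive SNV moves the ensemble
  # farther than the loop SNV, measured entirely with the enumeration oracle
  em <- energy_model()
  for (cs in unique(sc$snvs$seq_id)) {
    wt <- sc$seqs[[cs]]
    sv <- sc$snvs[sc$snvs$seq_id == cs, ]
    d <- vapply(seq_len(2), function(j) {
      mt <- wt
      substr(mt, sv$pos[j] + 1, sv$pos[j] + 1) <- sv$alt[j]
      sqrt(sum((enumerate_structures_oracle(wt, em)$p -
                  enumerate_structures_oracle(mt, em)$p)^2) / 2)
    }, numeric(1))
    expect_gt(d[sv$class == "disruptive"], 0)
    expect_gt(d[sv$class == "disruptive"], d[sv$class == "neutral"])
  }

  expect_error(generate_structure_cases(
    sim_config(structure = list(n_cases = 2L, stem_len = 5L,
                                loop_len = 2L, flank_len = 2L))),
    "loop")
})

test_that("bundles round-trip through the package writers and readers", {
  b <- generate_genome_bundle(sim_config(seed = 2, n_true_enhancers = 50L,
                                         n_decoys_per_class = 1L,
                                         n_genes = 8L))
  dir <- withr::local_tempdir()
  manifest <- write_sim_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_equal(manifest$seed, 2L)

  rb <- read_bed(file.path(dir, "h3k27ac_rep1.bed"))
  orig <- b$peaks$h3k27ac[[1]]
  expect_equal(rb$start, orig$start)
  expect_equal(rb$end, orig$end)

  rg <- read_gtf(file.path(dir, "annotation.gtf"))
  genes <- rg[rg$gene_id %in% b$annotation$gene_bodies$gene_id, ]
  expect_equal(sort(genes$start), sort(b$annotation$gene_bodies$start))
  expect_equal(sort(genes$end), sort(b$annotation$gene_bodies$end))
})
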