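test_that("structural distance validates the SNV and clips the window", {
  s <- "AAGGGGGAAAACCCCCAA"
  expect_error(snv_structural_distance(s, 3, "G", "G", min_interval = 10),
               "alt allele equals ref")
  expect_error(snv_structural_distance(s, 3, "C", "A", min_interval = 10),
               "does not match")
  expect_error(snv_structural_distance(s, 50, "G", "A", min_interval = 10),
               "outside")
  expect_error(snv_structural_distance(s, 3, "G", "A", min_interval = 100),
               "shorter than min_interval")
  r <- snv_structural_distance(s, 3, "G", "A", window = 5, min_interval = 5)
  expect_equal(r$window_bounds, c(1, 9))   # left clip
  expect_gte(r$d_max, 0)
})

test_that("interval scan matches the exhaustive interval oracle", {
  set.seed(15)
  for (r in 1:5) {
    s <- random_rna(18)
    pos <- sample(0:17, 1)
    ref <- substr(s, pos + 1, pos + 1)
    alt <- sample(setdiff(c("A", "C", "G", "U"), ref), 1)
    em <- energy_model()
    got <- snv_structural_distance(s, pos, ref, alt, window = 200,
                                   min_interval = 6, em = em)
    # reconstruct D2 from the enumeration oracle, scan by brute force
    mt <- s
    substr(mt, pos + 1, pos + 1) <- alt
    D2 <- (enumerate_structures_oracle(s, em)$p -
             enumerate_structures_oracle(mt, em)$p)^2
    brute <- brute_interval_scan(D2, pos + 1, 6)
    expect_equal(got$d_max, brute$d_max, tolerance = 1e-9)
    expect_equal(got$interval, brute$interval)
  }
})

test_that("distance is monotone under interval inclusion", {
  sc <- generate_structure_cases(sim_config(seed = 44,
    structure = list(n_cases = 3L, stem_len = 10L, loop_len = 5L,
                     flank_len = 10L)))
  sv <- sc$snvs[1, ]
  s <- sc$seqs[[sv$seq_id]]
  d_small <- snv_structural_distance(s, sv$pos, sv$ref, sv$alt,
                                     min_interval = 30)$d_max
  d_full <- snv_structural_distance(s, sv$pos, sv$ref, sv$alt,
                                    min_interval = nchar(s))$d_max
  # the full window is always an allowed interval, so relaxing the minimum
  # length can only keep or increase the maximum
  expect_gte(d_small, d_full - 1e-12)
  # unnormalized distance is maximized by the full window
  expect_equal(d_small, d_full, tolerance = 1e-12)
  # the normalized variant may prefer a smaller interval
  dn <- snv_structural_distance(s, sv$pos, sv$ref, sv$alt,
                                min_interval = 10, normalized = TRUE)
  expect_lte(dn$interval[2] - dn$interval[1] + 1, nchar(s))
})

test_that("stem-breaking SNVs score higher than loop SNVs in the same molecule", {
  sc <- generate_structure_cases(sim_config(seed = 9,
    structure = list(n_cases = 20L, stem_len = 12L, loop_len = 6L,
                     flank_len = 15L)))
  wins <- 0
  for (cs in unique(sc$snvs$seq_id)) {
    sv <- sc$snvs[sc$snvs$seq_id == cs, ]
    d <- vapply(1:2, function(j)
      snv_structural_distance(sc$seqs[[cs]], sv$pos[j], sv$ref[j],
                              sv$alt[j], min_interval = 20)$d_max,
      numeric(1))
    expect_gt(d[sv$class == "disruptive"], 0)
    wins <- wins + (d[sv$class == "disruptive"] > d[sv$class == "neutral"])
  }
  expect_gte(wins, 18)
})

test_that("empirical p-values are reproducible, floored and thresholded strictly", {
  sc <- generate_structure_cases(sim_config(seed = 10,
    structure = list(n_cases = 2L, stem_len = 12L, loop_len = 6L,
                     flank_len = 15L)))
  sv <- sc$snvs[sc$snvs$class == "disruptive", ][1, ]
  s <- sc$seqs[[sv$seq_id]]
  set.seed(33)
  r1 <- empirical_structure_pvalue(s, sv$pos, sv$ref, sv$alt, n_null = 50,
                                   min_interval = 20)
  set.seed(33)
  r2 <- empirical_structure_pvalue(s, sv$pos, sv$ref, sv$alt, n_null = 50,
                                   min_interval = 20)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 51)          # add-one floor
  expect_error(empirical_structure_pvalue(s, sv$pos, sv$ref, sv$alt,
                                          n_null = 10), "at least 50")

  calls <- call_ribosnitches(data.frame(p_value = c(0.19, 0.2, 0.05, 0.95)))
  expect_equal(calls$is_ribosnitch, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("score_snvs drives the full per-SNV table", {
  sc <- generate_structure_cases(sim_config(seed = 12,
    structure = list(n_cases = 3L, stem_len = 12L, loop_len = 6L,
                     flank_len = 15L)))
  set.seed(2)
  tab <- score_snvs(sc$seqs, sc$snvs, n_null = 50, min_interval = 20)
  expect_equal(nrow(tab), nrow(sc$snvs))
  expect_true(all(tab$d_max >= 0))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true(is.logical(tab$is_ribosnitch))
})
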