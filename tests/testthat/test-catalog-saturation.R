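test_that("master list merges, splits long spans and records membership", {
  cats <- list(a = gintervals("c1", 0, 3000), b = gintervals("c1", 2000, 5000))
  ml <- build_master_list(cats)
  expect_equal(nrow(ml$elements), 1)
  expect_equal(c(ml$elements$start, ml$elements$end), c(0, 5000))
  expect_equal(ml$elements$membership, "a;b")

  ml2 <- build_master_list(list(a = gintervals("c1", 0, 6000)))
  expect_equal(ml2$elements$start, c(0, 3000))
  expect_equal(ml2$elements$end, c(3000, 6000))
  expect_true(all(ml2$elements$end - ml2$elements$start <= 5000))

  cats3 <- list(a = gintervals("c1", 0, 100), b = gintervals("c1", 500, 900))
  ml3 <- build_master_list(cats3)
  expect_equal(ml3$elements$start, c(0, 500))
  expect_equal(ml3$elements$end, c(100, 900))
})

test_that("cell specificity equals a brute-force overlap recount", {
  set.seed(19)
  cats <- lapply(1:5, function(i)
    gintervals("c1", s <- sort(sample.int(200, 30)) * 100,
               s * 100 + sample.int(150, 30, replace = TRUE)))
  names(cats) <- paste0("ct", 1:5)
  ml <- build_master_list(cats)
  cs <- cell_specificity(ml)
  brute <- vapply(seq_len(nrow(ml$elements)), function(e) {
    sum(vapply(cats, function(cc)
      any(cc$start < ml$elements$end[e] & cc$end > ml$elements$start[e]),
      logical(1)))
  }, numeric(1))
  expect_equal(unname(cs$counts), brute)
  expect_true(all(cs$counts >= 1))
})

test_that("master-list coverage is invariant to catalog order", {
  set.seed(77)
  cats <- lapply(1:4, function(i)
    gintervals("c1", s <- sort(sample.int(300, 40)) * 50,
               s * 50 + 40))
  names(cats) <- paste0("ct", 1:4)
  cov1 <- with(build_master_list(cats)$elements, sum(end - start))
  cov2 <- with(build_master_list(rev(cats))$elements, sum(end - start))
  expect_equal(cov1, cov2)
})

test_that("saturation curve endpoints match closed forms", {
  cats <- generate_catalog_series(sim_config(seed = 4, n_cell_types = 6L))
  set.seed(1)
  cv <- saturation_curve(cats, n_samples = 40)
  # x = n_cells: every subset is the full set
  full <- build_master_list(cats)
  expect_equal(cv$mean_count[6], nrow(full$elements))
  expect_equal(cv$mean_coverage[6],
               sum(full$elements$end - full$elements$start))
  # x = 1: expectation is the average single-catalog size
  mean1 <- mean(vapply(cats, function(x)
    nrow(build_master_list(list(x))$elements), numeric(1)))
  expect_lt(abs(cv$mean_count[1] - mean1) / mean1, 0.1)
  # monotone non-decreasing in expectation (generous Monte-Carlo slack)
  expect_true(all(diff(cv$mean_count) > -0.05 * max(cv$mean_count)))
  # fixed seed reproduces the curve
  set.seed(1)
  expect_identical(saturation_curve(cats, n_samples = 40), cv)
  expect_error(saturation_curve(cats, n_samples = 0), "positive")
})

test_that("Weibull fit is self-consistent and flags degenerate inputs", {
  x <- 1:50
  y <- 1000 * (1 - exp(-(x / 20)^1.2))
  f <- fit_weibull(x, y)
  expect_lt(abs(f$A - 1000) / 1000, 0.01)
  expect_gt(f$r2, 0.999)
  expect_lt(abs(f$b - 20) / 20, 0.01)
  expect_lt(abs(f$c - 1.2) / 1.2, 0.01)

  # constant y: either an explicit failure or a flagged degenerate fit
  res <- tryCatch(fit_weibull(1:10, rep(5, 10)), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "weibull fit failed")
  } else {
    expect_true(is.na(res$r2) || is.na(res$A_sd) ||
                  abs(res$A - 5) / 5 < 0.1)
  }

  # bootstrap SD agrees with the covariance SD in order of magnitude
  set.seed(2)
  yn <- y + rnorm(50, 0, 5)
  f1 <- fit_weibull(x, yn)
  f2 <- fit_weibull(x, yn, sd_method = "bootstrap", n_boot = 60)
  expect_gt(f2$A_sd, f1$A_sd / 10)
  expect_lt(f2$A_sd, f1$A_sd * 10)
})

test_that("consensus keeps >= 2-set regions and dedup collapses shifted hits", {
  s1 <- gintervals("c1", c(100, 5000), c(200, 5100))
  s2 <- gintervals("c1", 9000, 9100)
  s3 <- gintervals("c1", 120, 230)
  cc <- consensus_calls(list(s1, s2, s3))
  expect_equal(nrow(cc), 1)       # only the region shared by sets 1 and 3
  expect_equal(c(cc$start, cc$end), c(100, 230))

  hits <- gintervals("c1", c(100, 104, 150), c(200, 204, 250),
                     model = c("RF001", "RF001", "RF001"))
  dd <- dedup_hits(hits, shift_tol = 10)
  expect_equal(nrow(dd), 2)       # 104/204 collapses onto 100/200; 150 not
  expect_equal(dd$n_hits, c(2, 1))
  # different models never collapse
  hits2 <- gintervals("c1", c(100, 104), c(200, 204),
                      model = c("RF001", "RF002"))
  expect_equal(nrow(dedup_hits(hits2, 10)), 2)
})
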