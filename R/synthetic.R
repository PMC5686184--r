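#' Configuration for the synthetic-data generators
#'
#' Defaults encode the statistical structure the pipeline assumes: a
#' two-component log-normal tag-count mixture with component medians 123
#' and 4 and a high-component fraction of 0.353; histone-mark peaks that
#' co-occur at planted enhancers across replicates; cross-cell-type element
#' presence whose discovery curve saturates along a Weibull form; LD blocks
#' with Beta-distributed r-squared; and stem-loop RNAs carrying structure-
#' disruptive versus neutral SNVs.
#'
#' @param seed RNG seed; every generator is deterministic given the config.
#' @param n_chroms,chrom_len synthetic genome shape.
#' @param n_genes,n_rrna,n_true_enhancers,n_decoys_per_class,n_replicates
#'   entity counts for the genome bundle; decoy classes each violate exactly
#'   one filter criterion (see [generate_genome_bundle()]).
#' @param tag_mixture list: `median_high`, `median_low`, `high_fraction`,
#'   `sdlog_high`, `sdlog_low` (log-normal sigma, natural log). The sigmas
#'   make the two components overlap slightly so the classifier threshold
#'   is earned, not trivial.
#' @param n_cell_types,weibull_truth catalogue-series truth: asymptote `A`,
#'   scale `b` (cell types) and shape `c` of the Weibull discovery curve
#'   (`c <= 1`; see [generate_catalog_series()]).
#' @param element_len,element_gap geometry of catalogue elements in bp.
#' @param ld_block_size LD block extent in bp.
#' @param planted_enrichment_fold disease-SNP enrichment over background in
#'   loci.
#' @param n_disease_snps,n_background_snps SNP panel sizes.
#' @param structure list: `n_cases`, `stem_len`, `loop_len`, `flank_len`
#'   for the hairpin riboSNitch fixtures.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_len = 2e6,
                       n_genes = 40L, n_rrna = 4L,
                       n_true_enhancers = 100L,
                       n_decoys_per_class = 2L,
                       n_replicates = 3L,
                       tag_mixture = list(median_high = 123,
                                          median_low = 4,
                                          high_fraction = 0.353,
                                          sdlog_high = 0.85,
                                          sdlog_low = 0.95),
                       n_cell_types = 30L,
                       weibull_truth = list(A = 500, b = 10, c = 1),
                       element_len = 1000L, element_gap = 500L,
                       ld_block_size = 25000,
                       planted_enrichment_fold = 8,
                       n_disease_snps = 500L,
                       n_background_snps = 2000L,
                       structure = list(n_cases = 50L, stem_len = 12L,
                                        loop_len = 6L, flank_len = 15L)) {
  cfg <- list(seed = as.integer(seed), n_chroms = n_chroms,
              chrom_len = chrom_len, n_genes = n_genes, n_rrna = n_rrna,
              n_true_enhancers = n_true_enhancers,
              n_decoys_per_class = n_decoys_per_class,
              n_replicates = n_replicates, tag_mixture = tag_mixture,
              n_cell_types = n_cell_types, weibull_truth = weibull_truth,
              element_len = element_len, element_gap = element_gap,
              ld_block_size = ld_block_size,
              planted_enrichment_fold = planted_enrichment_fold,
              n_disease_snps = n_disease_snps,
              n_background_snps = n_background_snps,
              structure = structure)
  with(cfg, stopifnot(
    n_chroms >= 1, chrom_len > 0, n_genes > 0, n_true_enhancers > 0,
    n_replicates >= 1,
    tag_mixture$high_fraction > 0, tag_mixture$high_fraction < 1,
    tag_mixture$median_high > 0, tag_mixture$median_low > 0,
    weibull_truth$A > 0, weibull_truth$b > 0, weibull_truth$c > 0,
    planted_enrichment_fold > 0,
    structure$stem_len >= 3, structure$loop_len >= 3))
  structure(cfg, class = "sim_config")
}

DECOY_CLASSES <- c(near_tss = 1L, est_span = 2L, marks_both_high = 3L,
                   k4me3_high = 4L, no_k4me1 = 5L, genic = 6L, rrna = 7L,
                   low_replicate = NA_integer_)

## internal: uniform integer positions in [lo, hi)
runif_pos <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo))

#' Generate an annotated genome bundle with planted enhancers and decoys
#'
#' Lays genes, rRNA genes, planted enhancers and decoy peaks into distinct
#' 12-kb slots of a synthetic genome, so that spacing constraints (1 kb to
#' TSSs, 2 kb mark windows) hold by construction. Planted ("true")
#' enhancers carry H3K27ac and H3K4me1 peaks in every replicate and pass
#' all seven filter criteria; each decoy class violates exactly one:
#' `near_tss` (criterion 1), `est_span` (2), `marks_both_high` (3),
#' `k4me3_high` (4), `no_k4me1` (5), `genic` (6), `rrna` (7), plus
#' `low_replicate` decoys that appear in too few replicates and disappear
#' at the consensus stage. Mark signal is Poisson tag counts in the 2-kb
#' window: lambda 50 (H3K4me1) / 30 (H3K4me3) at ordinary peaks, 5,000 at
#' `marks_both_high` decoys and 2,750 (H3K4me3 only) at `k4me3_high`
#' decoys — magnitudes chosen so the population z-scores of the decoys
#' clear 5 and 3 respectively while ordinary peaks stay far below.
#'
#' @param cfg a [sim_config()].
#' @return list: `annotation`, `peaks` (`h3k27ac`, `h3k4me1`: lists of
#'   replicate data.frames), `signal` (`h3k4me1`, `h3k4me3`: [tag_set()]s),
#'   `truth` (entity table with `class` and `expected_first_fail`), `cfg`.
#' @export
generate_genome_bundle <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  slot_w <- 12000
  chroms <- paste0("chrS", seq_len(cfg$n_chroms))
  slots_per_chrom <- floor(cfg$chrom_len / slot_w) - 1L
  slot_tab <- expand.grid(chrom = chroms, slot = seq_len(slots_per_chrom),
                          stringsAsFactors = FALSE)
  slot_tab$pos <- (slot_tab$slot - 1L) * slot_w

  n_decoy <- cfg$n_decoys_per_class * length(DECOY_CLASSES)
  need <- cfg$n_genes + cfg$n_rrna + cfg$n_true_enhancers + n_decoy
  if (need > nrow(slot_tab))
    stop("capacity error: ", need, " entities exceed ", nrow(slot_tab),
         " genome slots; enlarge chrom_len or n_chroms")
  ## the z-score decoy classes are only constructible when the peak
  ## population is large enough: with n_d outliers per mark among N peaks,
  ## the attainable z is ~sqrt((N - n_d)/n_d), so "five sigma" needs a
  ## small outlier fraction. Predict the planted z-scores (normal-peak
  ## signal is negligible against the decoy magnitudes) and refuse configs
  ## whose decoys could not violate their criterion.
  n_pop <- cfg$n_true_enhancers + 5L * cfg$n_decoys_per_class
  f <- cfg$n_decoys_per_class / n_pop
  r <- 0.55                      # k4me3_high magnitude relative to both_high
  mu <- f * (1 + r)
  sg <- sqrt(f * (1 + r^2) - mu^2)
  if ((1 - mu) / sg < 5.3 || (r - mu) / sg < 3.3)
    stop("capacity error: too few true enhancers for the z-score decoy ",
         "classes (predicted z ", round((1 - mu) / sg, 2), " / ",
         round((r - mu) / sg, 2), "); increase n_true_enhancers or ",
         "reduce n_decoys_per_class")

  pick <- slot_tab[sample.int(nrow(slot_tab), need), , drop = FALSE]
  rownames(pick) <- NULL
  idx <- 0L
  take <- function(k) {
    out <- pick[idx + seq_len(k), , drop = FALSE]
    idx <<- idx + k
    out
  }

  ## --- genes ------------------------------------------------------------
  gs <- take(cfg$n_genes)
  glen <- runif_pos(cfg$n_genes, 3000, 6000)
  gstrand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  gene_bodies <- gintervals(chrom = gs$chrom, start = gs$pos + 2000,
                            end = gs$pos + 2000 + glen, strand = gstrand,
                            gene_id = sprintf("G%03d", seq_len(cfg$n_genes)))
  tss <- data.frame(gene_id = gene_bodies$gene_id,
                    chrom = gene_bodies$chrom,
                    pos = ifelse(gstrand == "+", gene_bodies$start,
                                 gene_bodies$end - 1L),
                    strand = gstrand, stringsAsFactors = FALSE)

  ## --- rRNA genes (separate track: no TSS entry, not a gene body) -------
  rs <- take(cfg$n_rrna)
  rrna <- gintervals(chrom = rs$chrom, start = rs$pos + 2000,
                     end = rs$pos + 2500)

  est <- gintervals()
  est$five_prime <- numeric(0)
  truth <- list()
  k27_peaks <- list()     # per-entity: interval + replicate presence
  k4_peaks <- list()
  sig1 <- list(); sig3 <- list()

  add_signal <- function(chrom, center, lambda1, lambda3) {
    n1 <- stats::rpois(1, lambda1); n3 <- stats::rpois(1, lambda3)
    sig1[[length(sig1) + 1L]] <<- data.frame(
      chrom = chrom, pos = runif_pos(n1, center - 1000, center + 1000),
      strand = ".")
    sig3[[length(sig3) + 1L]] <<- data.frame(
      chrom = chrom, pos = runif_pos(n3, center - 1000, center + 1000),
      strand = ".")
  }

  add_entity <- function(id, class, chrom, start, end, reps,
                         k4me1_peak = TRUE, lambda1 = 50, lambda3 = 30,
                         expected_first_fail = NA_integer_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      entity_id = id, class = class, chrom = chrom, start = start,
      end = end, expected_first_fail = expected_first_fail,
      survives_consensus = length(reps) / cfg$n_replicates > 0.7,
      stringsAsFactors = FALSE)
    k27_peaks[[length(k27_peaks) + 1L]] <<- list(
      chrom = chrom, start = start, end = end, reps = reps)
    if (k4me1_peak) {
      off <- runif_pos(1, -800, 800)
      k4_peaks[[length(k4_peaks) + 1L]] <<- list(
        chrom = chrom, start = start + off, end = end + off,
        reps = seq_len(cfg$n_replicates))
    }
    add_signal(chrom, floor((start + end) / 2), lambda1, lambda3)
  }

  all_reps <- seq_len(cfg$n_replicates)
  low_reps <- seq_len(floor(0.7 * cfg$n_replicates))
  v_high <- 5000; v_mid <- r * v_high

  ## --- planted true enhancers -------------------------------------------
  ts <- take(cfg$n_true_enhancers)
  for (i in seq_len(cfg$n_true_enhancers)) {
    w <- runif_pos(1, 400, 1200)
    s <- ts$pos[i] + 2000
    add_entity(sprintf("TRUE%03d", i), "true", ts$chrom[i], s, s + w,
               all_reps)
  }

  ## --- decoys -----------------------------------------------------------
  for (class in names(DECOY_CLASSES)) {
    ds <- take(cfg$n_decoys_per_class)
    for (i in seq_len(cfg$n_decoys_per_class)) {
      id <- sprintf("DECOY_%s_%d", class, i)
      chrom <- ds$chrom[i]; base <- ds$pos[i]
      ff <- DECOY_CLASSES[[class]]
      switch(class,
        near_tss = {
          gid <- paste0(id, "_gene")
          gene_bodies <- rbind(gene_bodies,
            gintervals(chrom = chrom, start = base + 2700, end = base + 6700,
                       strand = "+", gene_id = gid))
          tss <- rbind(tss, data.frame(gene_id = gid, chrom = chrom,
                                        pos = base + 2700, strand = "+"))
          add_entity(id, class, chrom, base + 2000, base + 2300, all_reps,
                     expected_first_fail = ff)
        },
        est_span = {
          gid <- paste0(id, "_gene")
          gene_bodies <- rbind(gene_bodies,
            gintervals(chrom = chrom, start = base + 5800, end = base + 7800,
                       strand = "+", gene_id = gid))
          tss <- rbind(tss, data.frame(gene_id = gid, chrom = chrom,
                                        pos = base + 5800, strand = "+"))
          e <- gintervals(chrom = chrom, start = base + 3500,
                          end = base + 6300, strand = "+")
          e$five_prime <- base + 3500
          est <- rbind(est, e)
          add_entity(id, class, chrom, base + 2000, base + 2300, all_reps,
                     expected_first_fail = ff)
        },
        marks_both_high = add_entity(id, class, chrom, base + 2000,
                                     base + 2600, all_reps,
                                     lambda1 = v_high, lambda3 = v_high,
                                     expected_first_fail = ff),
        k4me3_high = add_entity(id, class, chrom, base + 2000, base + 2600,
                                all_reps, lambda3 = v_mid,
                                expected_first_fail = ff),
        no_k4me1 = add_entity(id, class, chrom, base + 2000, base + 2600,
                              all_reps, k4me1_peak = FALSE,
                              expected_first_fail = ff),
        genic = {
          gid <- paste0(id, "_gene")
          gene_bodies <- rbind(gene_bodies,
            gintervals(chrom = chrom, start = base + 2000, end = base + 10000,
                       strand = "+", gene_id = gid))
          tss <- rbind(tss, data.frame(gene_id = gid, chrom = chrom,
                                        pos = base + 2000, strand = "+"))
          add_entity(id, class, chrom, base + 5850, base + 6150, all_reps,
                     expected_first_fail = ff)
        },
        rrna = {
          rrna <- rbind(rrna, gintervals(chrom = chrom, start = base + 2000,
                                          end = base + 2500))
          add_entity(id, class, chrom, base + 2100, base + 2400, all_reps,
                     expected_first_fail = ff)
        },
        low_replicate = add_entity(id, class, chrom, base + 2000,
                                   base + 2600, low_reps))
    }
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  ## replicate peak sets: jitter each replicate's copy by <= 50 bp
  rep_sets <- function(peaks) {
    lapply(seq_len(cfg$n_replicates), function(r) {
      member <- Filter(function(p) r %in% p$reps, peaks)
      if (!length(member)) return(gintervals())
      df <- do.call(rbind, lapply(member, function(p) {
        j <- runif_pos(1, -50, 51)
        data.frame(chrom = p$chrom, start = p$start + j, end = p$end + j,
                   strand = ".", stringsAsFactors = FALSE)
      }))
      df[order(df$chrom, df$start), , drop = FALSE]
    })
  }

  chrom_lens <- stats::setNames(rep(cfg$chrom_len, cfg$n_chroms), chroms)
  ann <- annotation(tss = tss, gene_bodies = gene_bodies, rrna_genes = rrna,
                    est_records = est, chrom_lens = chrom_lens)
  list(annotation = ann,
       peaks = list(h3k27ac = rep_sets(k27_peaks),
                    h3k4me1 = rep_sets(k4_peaks)),
       signal = list(h3k4me1 = tag_set(do.call(rbind, sig1)),
                     h3k4me3 = tag_set(do.call(rbind, sig3))),
       truth = truth, cfg = cfg)
}

#' Generate poly(A) tag counts from the two-component mixture
#'
#' Each candidate draws its tag count from a log-normal mixture: with
#' probability `high_fraction` from the high component (median 123 by
#' default), otherwise from the low component (median 4). Counts are
#' rounded to integers and realized as stranded tag positions uniform in
#' the +/- 1 kb counting window around the candidate center, with 80% of a
#' candidate's tags on its (randomly chosen) true strand.
#'
#' @param candidates interval data.frame.
#' @param cfg a [sim_config()]; the RNG is re-seeded from `cfg$seed` so the
#'   draw is reproducible independently of call order.
#' @return list: `tags` (a [tag_set()]), `counts` (per-candidate
#'   data.frame with `count`, `component`, `true_strand`).
#' @export
generate_tag_counts <- function(candidates, cfg = sim_config()) {
  validate_gintervals(candidates)
  stopifnot(nrow(candidates) > 0)
  set.seed(cfg$seed + 1L)
  tm <- cfg$tag_mixture
  n <- nrow(candidates)
  high <- stats::runif(n) < tm$high_fraction
  counts <- integer(n)
  counts[high] <- round(stats::rlnorm(sum(high), log(tm$median_high),
                                      tm$sdlog_high))
  counts[!high] <- round(stats::rlnorm(sum(!high), log(tm$median_low),
                                       tm$sdlog_low))
  true_strand <- sample(c("+", "-"), n, replace = TRUE)

  pos_list <- lapply(seq_len(n), function(i) {
    k <- counts[i]
    if (k == 0L) return(NULL)
    center <- floor((candidates$start[i] + candidates$end[i]) / 2)
    on_true <- stats::runif(k) < 0.8
    data.frame(chrom = candidates$chrom[i],
               pos = runif_pos(k, center - 1000, center + 1000),
               strand = ifelse(on_true, true_strand[i],
                               setdiff(c("+", "-"), true_strand[i])),
               stringsAsFactors = FALSE)
  })
  pos <- do.call(rbind, pos_list)
  if (is.null(pos)) pos <- data.frame(chrom = character(), pos = numeric(),
                                      strand = character())
  list(tags = tag_set(pos, total_tags = sum(counts)),
       counts = data.frame(candidate = seq_len(n), count = counts,
                           component = ifelse(high, "high", "low"),
                           true_strand = true_strand))
}

#' Generate per-cell-type catalogues with a Weibull discovery curve
#'
#' Each of `A` elements receives a per-cell inclusion probability
#' `q = 1 - exp(-lambda)` with `lambda` drawn so that the expected number
#' of distinct elements discovered after x cell types is exactly
#' `A * (1 - exp(-(x/b)^c))`: for shape `c = 1`, `lambda = 1/b` for every
#' element; for `c < 1` the Weibull survival function is completely
#' monotone and `lambda` is `1/b` times a one-sided stable(c) variate
#' (Kanter's sampler). Shapes `c > 1` cannot arise from independent
#' element-to-cell assignment and are rejected.
#'
#' @param cfg a [sim_config()].
#' @return named list of per-cell-type interval data.frames; the element
#'   table and truth parameters are attached as attribute `"truth"`.
#' @export
generate_catalog_series <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  wt <- cfg$weibull_truth
  A <- wt$A
  pitch <- cfg$element_len + cfg$element_gap
  per_chrom <- floor(cfg$chrom_len / pitch)
  if (A > per_chrom * cfg$n_chroms)
    stop("capacity error: asymptote A = ", A, " exceeds ",
         per_chrom * cfg$n_chroms, " genome slots")
  slot <- seq_len(A) - 1L
  elements <- gintervals(
    chrom = paste0("chrS", slot %/% per_chrom + 1L),
    start = (slot %% per_chrom) * pitch,
    end = (slot %% per_chrom) * pitch + cfg$element_len)
  elements$element_id <- seq_len(A)

  lambda <- if (wt$c == 1) {
    rep(1 / wt$b, A)
  } else if (wt$c < 1) {
    u <- stats::runif(A, 0, pi)
    w <- stats::rexp(A)
    s <- (sin(wt$c * u) / sin(u)^(1 / wt$c)) *
      (sin((1 - wt$c) * u) / w)^((1 - wt$c) / wt$c)
    s / wt$b
  } else {
    stop("weibull shape c > 1 cannot be realized by independent ",
         "element-to-cell assignment")
  }
  q <- 1 - exp(-lambda)

  catalogs <- lapply(seq_len(cfg$n_cell_types), function(t) {
    inc <- stats::runif(A) < q
    el <- elements[inc, , drop = FALSE]
    rownames(el) <- NULL
    el
  })
  names(catalogs) <- paste0("cell", seq_len(cfg$n_cell_types))
  attr(catalogs, "truth") <- list(elements = elements, lambda = lambda,
                                  A = A, b = wt$b, c = wt$c)
  catalogs
}

#' Expected Weibull discovery curve of a catalogue series
#' @param cfg a [sim_config()].
#' @param x cell-type counts at which to evaluate.
#' @return expected distinct-element counts `A * (1 - exp(-(x/b)^c))`.
#' @export
expected_discovery_curve <- function(cfg, x = seq_len(cfg$n_cell_types)) {
  wt <- cfg$weibull_truth
  wt$A * (1 - exp(-(x / wt$b)^wt$c))
}

#' Generate a SNP panel with LD blocks and planted locus enrichment
#'
#' Background SNPs are uniform over the domain, so their in-locus fraction
#' matches the locus fraction of the domain; disease SNPs fall inside the
#' loci with `planted_enrichment_fold` times that rate. LD pairs connect
#' SNPs within `ld_block_size` blocks, with r-squared drawn from a
#' block-specific Beta distribution (the pipeline consumes r-squared values
#' only, so no haplotypes are simulated).
#'
#' @param cfg a [sim_config()].
#' @param loci interval data.frame of target loci (non-empty).
#' @param domain interval data.frame containing the loci.
#' @return list: `disease` and `background` SNP data.frames (`id`, `chrom`,
#'   `pos`, `in_locus`), `ld_pairs` (`snp_a`, `snp_b`, `r2`), `truth`.
#' @export
generate_snp_panel <- function(cfg, loci, domain) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(loci) || nrow(loci) == 0L)
    stop("empty-domain: loci must be non-empty")
  set.seed(cfg$seed + 3L)
  dom <- concat_domain(domain)
  L <- attr(dom, "total_len")
  loci_m <- merge_intervals(loci)
  lens <- loci_m$end - loci_m$start
  rho <- sum(lens) / L
  p_in <- cfg$planted_enrichment_fold * rho
  if (p_in >= 0.95)
    stop("planted fold times locus fraction reaches ", round(p_in, 2),
         "; shrink the loci or the fold")

  draw_in_loci <- function(k) {
    picks <- sample.int(length(lens), k, replace = TRUE, prob = lens)
    data.frame(chrom = loci_m$chrom[picks],
               pos = runif_pos(k, loci_m$start[picks], loci_m$end[picks]))
  }
  draw_in_domain <- function(k) {
    picks <- sample.int(nrow(dom), k, replace = TRUE,
                        prob = dom$end - dom$start)
    data.frame(chrom = dom$chrom[picks],
               pos = runif_pos(k, dom$start[picks], dom$end[picks]))
  }
  in_locus_of <- function(df) {
    vapply(seq_len(nrow(df)), function(i)
      any(loci_m$chrom == df$chrom[i] & loci_m$start <= df$pos[i] &
            df$pos[i] < loci_m$end), logical(1))
  }

  nd <- cfg$n_disease_snps
  hit <- stats::runif(nd) < p_in
  disease <- rbind(
    if (any(hit)) draw_in_loci(sum(hit)),
    if (any(!hit)) {
      out <- draw_in_domain(round(sum(!hit) * 1.4) + 20)
      out <- out[!in_locus_of(out), , drop = FALSE][seq_len(sum(!hit)), ]
      out
    })
  disease$id <- sprintf("rsD%04d", seq_len(nd))
  background <- draw_in_domain(cfg$n_background_snps)
  background$id <- sprintf("rsB%04d", seq_len(cfg$n_background_snps))
  disease$in_locus <- in_locus_of(disease)
  background$in_locus <- in_locus_of(background)

  all_snps <- rbind(disease[, c("id", "chrom", "pos")],
                    background[, c("id", "chrom", "pos")])
  all_snps$block <- paste0(all_snps$chrom, "_",
                           all_snps$pos %/% cfg$ld_block_size)
  pairs <- lapply(split(all_snps, all_snps$block), function(b) {
    if (nrow(b) < 2L) return(NULL)
    b <- b[order(b$pos), ]
    shape1 <- stats::runif(1, 2, 8); shape2 <- stats::runif(1, 1, 4)
    data.frame(snp_a = b$id[-nrow(b)], snp_b = b$id[-1],
               r2 = stats::rbeta(nrow(b) - 1L, shape1, shape2))
  })
  ld_pairs <- do.call(rbind, pairs)
  rownames(ld_pairs) <- NULL
  list(disease = disease[, c("id", "chrom", "pos", "in_locus")],
       background = background[, c("id", "chrom", "pos", "in_locus")],
       ld_pairs = ld_pairs,
       truth = list(fold = cfg$planted_enrichment_fold, locus_fraction = rho,
                    p_in = p_in))
}

#' Generate hairpin RNAs with disruptive and neutral SNVs
#'
#' Each case is a stem-loop: an unpaired A-rich flank, a random Watson-
#' Crick stem, an all-A loop, the reverse-complement stem, and the second
#' flank. The "disruptive" SNV substitutes a stem base so that the new base
#' cannot pair with its partner (wobble pairs are also excluded); the
#' "neutral" SNV substitutes a loop base. Truth labels accompany every SNV.
#'
#' @param cfg a [sim_config()].
#' @return list: `seqs` (named character vector), `snvs` (data.frame:
#'   `seq_id`, `pos` 0-based, `ref`, `alt`, `class`).
#' @export
generate_structure_cases <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  st <- cfg$structure
  if (st$loop_len < 3)
    stop("loop_len below the minimum hairpin loop of 3 nt")
  set.seed(cfg$seed + 4L)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  pairs_ok <- c("GC", "CG", "AU", "UA", "GU", "UG")

  seqs <- character(st$n_cases)
  snv_rows <- list()
  for (i in seq_len(st$n_cases)) {
    stem <- sample(c("G", "C", "A", "U"), st$stem_len, replace = TRUE,
                   prob = c(0.35, 0.35, 0.15, 0.15))
    flank <- rep("A", st$flank_len)
    loop <- rep("A", st$loop_len)
    seq_chars <- c(flank, stem, loop, rev(unname(comp[stem])), flank)
    id <- sprintf("hairpin%03d", i)
    seqs[i] <- paste(seq_chars, collapse = "")

    ## disruptive: break a stem pair, excluding wobble rescues
    k <- sample.int(st$stem_len, 1)
    pos_d <- st$flank_len + k - 1L                  # 0-based
    ref_d <- stem[k]
    partner <- comp[ref_d]
    alts <- setdiff(c("A", "C", "G", "U"), ref_d)
    alts <- alts[!(paste0(alts, partner) %in% pairs_ok)]
    alt_d <- if (length(alts) > 1) sample(alts, 1) else alts

    ## neutral: substitute inside the loop
    l <- sample.int(st$loop_len, 1)
    pos_n <- st$flank_len + st$stem_len + l - 1L    # 0-based
    alt_n <- sample(c("C", "G", "U"), 1)            # loop is all A

    snv_rows[[i]] <- data.frame(
      seq_id = id, pos = c(pos_d, pos_n), ref = c(ref_d, "A"),
      alt = c(alt_d, alt_n), class = c("disruptive", "neutral"),
      stringsAsFactors = FALSE)
  }
  names(seqs) <- sprintf("hairpin%03d", seq_len(st$n_cases))
  list(seqs = seqs, snvs = do.call(rbind, snv_rows))
}

#' Generate eRNA-gene expression pairs with a target Spearman correlation
#'
#' Pairs are bivariate log-normal across pseudo-cell-types; the latent
#' Pearson correlation is set to `2 * sin(pi * rho / 6)` so the Spearman
#' correlation of each pair equals `rho` in population, and the log-normal
#' transform (monotone) leaves it unchanged.
#'
#' @param n_pairs number of eRNA-gene pairs.
#' @param n_cell_types profile length (the study's characterization subset
#'   uses 14 cell types).
#' @param rho target Spearman correlation.
#' @param seed RNG seed.
#' @return list of matrices `erna` and `gene` (`n_pairs` x `n_cell_types`).
#' @export
generate_expression_pairs <- function(n_pairs = 500, n_cell_types = 14,
                                      rho = 0.6, seed = 1L) {
  stopifnot(abs(rho) < 1)
  set.seed(seed + 5L)
  r_pearson <- 2 * sin(pi * rho / 6)
  z1 <- matrix(stats::rnorm(n_pairs * n_cell_types), n_pairs)
  z2 <- matrix(stats::rnorm(n_pairs * n_cell_types), n_pairs)
  x <- z1
  y <- r_pearson * z1 + sqrt(1 - r_pearson^2) * z2
  list(erna = exp(x), gene = exp(y))
}

#' Write a genome bundle to plain-text fixtures with a manifest
#'
#' Emits the annotation (GTF for genes and rRNA, BED for ESTs), the
#' replicate peak sets (BED) and the mark signal (TSV), plus a
#' `manifest.json` listing each file's role and the generating seed.
#'
#' @param bundle a [generate_genome_bundle()] result.
#' @param dir output directory (created if needed).
#' @return the manifest as a list, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  put <- function(name, role) {
    files[[length(files) + 1L]] <<- list(file = name, role = role)
    file.path(dir, name)
  }

  ann <- bundle$annotation
  genes <- ann$gene_bodies
  gtf <- data.frame(chrom = genes$chrom, start = genes$start,
                    end = genes$end, strand = genes$strand,
                    feature = "gene", gene_id = genes$gene_id)
  if (nrow(ann$rrna_genes)) {
    rr <- ann$rrna_genes
    gtf <- rbind(gtf, data.frame(chrom = rr$chrom, start = rr$start,
                                 end = rr$end, strand = ".",
                                 feature = "gene",
                                 gene_id = sprintf("RRNA%02d",
                                                   seq_len(nrow(rr)))))
  }
  write_gtf(gtf, put("annotation.gtf", "gene and rRNA models"))
  if (nrow(ann$est_records)) {
    est <- ann$est_records
    est$name <- sprintf("EST%03d", seq_len(nrow(est)))
    write_bed(est, put("ests.bed", "spliced ESTs (5' end = strand-aware start)"))
  }
  for (mark in names(bundle$peaks)) {
    for (r in seq_along(bundle$peaks[[mark]])) {
      f <- sprintf("%s_rep%d.bed", mark, r)
      write_bed(bundle$peaks[[mark]][[r]],
                put(f, paste(mark, "peaks, replicate", r)))
    }
  }
  for (mark in names(bundle$signal))
    write_tsv_file(bundle$signal[[mark]]$positions,
                   put(paste0(mark, "_signal.tsv"), paste(mark, "signal tags")))
  write_tsv_file(bundle$truth, put("truth.tsv", "entity truth labels"))
  manifest <- list(seed = bundle$cfg$seed, files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
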