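test_that("region intersection follows any-overlap, half-open arithmetic", {
  cna <- data.frame(chrom = "chr1", start = 10, end = 20)
  segs <- data.frame(chrom = "chr1", start = c(0, 15, 30),
                     end = c(10, 30, 40))
  # [10,20) vs [0,10): disjoint (half-open); vs [15,30): overlap 5
  ov <- intersect_regions(cna, segs)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$segment_index, 2)
  expect_equal(ov$overlap_bp, 5)

  # fully disjoint inputs
  expect_equal(nrow(intersect_regions(
    cna, data.frame(chrom = "chr2", start = 0, end = 100))), 0)

  # a CNA spanning two tiling segments: overlaps sum to the CNA length
  tiling <- data.frame(chrom = "chr1", start = c(0, 10), end = c(10, 30))
  cna2 <- data.frame(chrom = "chr1", start = 5, end = 25)
  ov2 <- intersect_regions(cna2, tiling)
  expect_equal(nrow(ov2), 2)
  expect_equal(ov2$overlap_bp, c(5, 15))
  expect_equal(sum(ov2$overlap_bp), 25 - 5)
})

test_that("detection requires direction match before the Z cutoff", {
  big <- line_layout(400)
  co <- make_cohort(big, n_donors = 15, seed = 40)
  # strong LOSS in plasma, but the queried CNA claims a gain there
  tr <- manual_truth("chr1", 100e6, 200e6, copy = 1)
  p <- make_plasma(tr, big, co$gc, co$panel, tumor_fraction = 0.6, seed = 3)
  gain_query <- data.frame(chrom = "chr1", start = 100e6, end = 200e6,
                           type = "gain", tumor_log2 = 0.585)
  rec <- evaluate_cna_in_plasma(gain_query, p, co$panel, z_cut = 1.5)
  expect_lt(rec$plasma_z, -1.5)          # |Z| clears the cutoff...
  expect_false(rec$direction_match)      # ...but direction disagrees
  expect_false(rec$detected)

  loss_query <- gain_query
  loss_query$type <- "loss"
  loss_query$tumor_log2 <- -1
  rec2 <- evaluate_cna_in_plasma(loss_query, p, co$panel, z_cut = 1.5)
  expect_true(rec2$direction_match)
  expect_true(rec2$detected)
})

test_that("a strong spike is detected and the null mostly is not", {
  big <- line_layout(400)
  co <- make_cohort(big, n_donors = 20, seed = 60)
  query <- data.frame(chrom = "chr1", start = 100e6, end = 200e6,
                      type = "gain", tumor_log2 = 0.585)
  tr <- manual_truth("chr1", 100e6, 200e6, copy = 3)
  det <- vapply(1:20, function(s) {
    p <- make_plasma(tr, big, co$gc, co$panel, tumor_fraction = 0.3,
                     seed = 300 + s)
    evaluate_cna_in_plasma(query, p, co$panel)$detected
  }, logical(1))
  expect_true(all(det))

  det0 <- vapply(1:30, function(s) {
    p <- make_plasma(tr, big, co$gc, co$panel, tumor_fraction = 0,
                     seed = 600 + s)
    evaluate_cna_in_plasma(query, p, co$panel)$detected
  }, logical(1))
  # one-sided 1.5-sigma tail with direction match: ~6.7% per region
  expect_lte(mean(det0), 0.2)
})

test_that("patient-level flags follow the any-detected rule", {
  big <- line_layout(300)
  co <- make_cohort(big, n_donors = 12, seed = 80)
  tr <- manual_truth("chr1", 50e6, 120e6, copy = 3)
  p <- make_plasma(tr, big, co$gc, co$panel, tumor_fraction = 0.3, seed = 5)

  # tumor with no CNAs: zero records, flag false
  d0 <- detect_patient(data.frame(chrom = character(), start = numeric(),
                                  end = numeric(), type = character(),
                                  tumor_log2 = numeric()),
                       p, co$panel)
  expect_equal(nrow(d0$records), 0)
  expect_false(d0$detected)

  calls <- data.frame(
    chrom = "chr1",
    start = c(50e6, 200e6, 250e6),
    end = c(120e6, 220e6, 270e6),
    type = c("gain", "loss", "gain"),
    tumor_log2 = c(0.585, -1, 0.585))
  d1 <- detect_patient(calls, p, co$panel)
  expect_true(d1$records$detected[1])
  expect_true(d1$detected)               # one of three suffices

  # z_cut = Inf: nothing can be detected
  dInf <- detect_patient(calls, p, co$panel, z_cut = Inf)
  expect_false(dInf$detected)
  expect_false(any(dInf$records$detected))
})

test_that("percent genome altered uses the union of detected regions", {
  ly <- tiny_layout()  # 100 Mb total
  rec <- data.frame(patient_id = "pt", chrom = "chrA",
                    start = c(0, 20e6, 25e6), end = c(30e6, 35e6, 28e6),
                    type = "gain", detected = c(TRUE, TRUE, TRUE))
  # brute-force union oracle on a 1 Mb lattice
  pts <- (0:99) * 1e6
  covered <- vapply(pts, function(x)
    any(x >= rec$start & x < rec$end), logical(1))
  oracle_bp <- sum(covered) * 1e6

  pga <- percent_genome_altered(rec, ly)
  expect_equal(pga$altered_bp, oracle_bp)
  expect_equal(pga$pct_genome_altered, 100 * oracle_bp / 100e6)

  # no detected regions -> 0%; order invariance; additivity
  rec0 <- rec; rec0$detected <- FALSE
  expect_equal(percent_genome_altered(rec0, ly)$pct_genome_altered, 0)
  expect_equal(percent_genome_altered(rec[3:1, ], ly)$pct_genome_altered,
               pga$pct_genome_altered)
  one30 <- data.frame(patient_id = "pt", chrom = "chrA", start = 0,
                      end = 30e6, detected = TRUE)
  expect_equal(percent_genome_altered(one30, ly)$pct_genome_altered, 30)

  disjoint <- data.frame(patient_id = "pt", chrom = c("chrA", "chrB"),
                         start = c(0, 0), end = c(10e6, 5e6),
                         detected = TRUE)
  expect_equal(percent_genome_altered(disjoint, ly)$pct_genome_altered,
               10 + 5)
})

test_that("donor specificity handles the trivial limits and monotonicity", {
  big <- line_layout(300)
  co <- make_cohort(big, n_donors = 8, seed = 120)
  regions <- data.frame(chrom = "chr1",
                        start = c(10e6, 150e6), end = c(60e6, 200e6),
                        type = c("gain", "loss"))
  # zero query regions: trivially specific
  s0 <- donor_specificity(co$donors, regions[0, ])
  expect_equal(s0$specificity, 1)
  # infinite cutoff: no detections possible
  sInf <- donor_specificity(co$donors, regions, z_cut = 1e9)
  expect_equal(sInf$specificity, 1)
  # specificity nondecreasing in z_cut
  sp <- vapply(c(0.5, 1.5, 3), function(zc)
    donor_specificity(co$donors, regions, z_cut = zc)$specificity,
    numeric(1))
  expect_true(all(diff(sp) >= 0))
  expect_equal(s0$n_donors, 8)
})

test_that("detection probability is nondecreasing in tumor fraction", {
  big <- line_layout(400)
  co <- make_cohort(big, n_donors = 20, seed = 140)
  tr <- manual_truth("chr1", 100e6, 200e6, copy = 3)
  query <- data.frame(chrom = "chr1", start = 100e6, end = 200e6,
                      type = "gain")
  rate <- vapply(c(0, 0.01, 0.05, 0.2), function(tf) {
    mean(vapply(1:25, function(s) {
      p <- make_plasma(tr, big, co$gc, co$panel, tumor_fraction = tf,
                       seed = 7000 + s)
      evaluate_cna_in_plasma(query, p, co$panel)$detected
    }, logical(1)))
  }, numeric(1))
  # allow small Monte-Carlo wiggle at neighbouring fractions
  expect_true(all(diff(rate) >= -0.1))
  expect_gt(rate[4], rate[1])
})

test_that("unevaluable CNA regions are flagged and excluded", {
  big <- line_layout(100)
  co <- make_cohort(big, n_donors = 6, seed = 160)
  tr <- simulate_tumor_truth(big, 0, seed = 1)
  p <- make_plasma(tr, big, co$gc, co$panel, tumor_fraction = 0, seed = 1)
  p$mask[11:20] <- FALSE
  calls <- data.frame(chrom = "chr1", start = c(10e6, 50e6),
                      end = c(20e6, 60e6), type = "gain",
                      tumor_log2 = 0.585)
  expect_message(d <- detect_patient(calls, p, co$panel), "no usable bins")
  expect_false(d$records$evaluable[1])
  expect_equal(d$n_unevaluable, 1L)
  expect_false(d$records$detected[1])
})

test_that("tumor-plasma agreement recovers collinear and noisy fits", {
  toy <- data.frame(tumor_log2 = c(-1, -0.5, 0.3, 0.6, 1),
                    plasma_z = 2 * c(-1, -0.5, 0.3, 0.6, 1))
  fit <- tumor_plasma_agreement(toy)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-6)

  expect_warning(f2 <- tumor_plasma_agreement(toy[1:2, ]), "2 points")
  expect_equal(f2$r_squared, 1, tolerance = 1e-9)

  expect_error(tumor_plasma_agreement(toy[1, ]), "at least 2")

  set.seed(3)
  noisy <- data.frame(tumor_log2 = runif(20, -1, 1))
  noisy$plasma_z <- 3 * noisy$tumor_log2 + rnorm(20, 0, 0.5)
  f3 <- tumor_plasma_agreement(noisy)
  expect_gt(f3$slope, 0)
  expect_gt(f3$r_squared, 0.5)
})
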