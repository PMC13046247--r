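test_that("unique-read counting excludes ambiguous and unmapped reads", {
  r <- data.frame(status = c("target_unique", "target_unique",
                             "spike_unique", "ambiguous"))
  expect_equal(unname(count_unique_reads(r)), c(2, 1))
  empty <- data.frame(status = character(0))
  expect_equal(unname(count_unique_reads(empty)), c(0, 0))
  expect_error(count_unique_reads(data.frame(status = "junk")), "status")
})

test_that("unique-read counts agree with the simulator's bookkeeping", {
  layout <- tiny_layout(2e5)
  fs <- plant_features(layout, n_hotspots = 10, seed = 1)
  rd <- simulate_experiment(layout, fs, occupancy_model(), 2e4, seed = 2)
  for (r in rd) {
    gt <- attr(r, "ground_truth")
    cnt <- count_unique_reads(r)
    expect_equal(unname(cnt[["n_spike_unique"]]), gt$n_spike)
    expect_equal(cnt[["n_target_unique"]] + sum(r$status == "ambiguous"),
                 gt$n_target)
  }
})

test_that("scaling factors follow the printed arithmetic exactly", {
  sf <- compute_scaling(2000, 200, 2.5)
  expect_identical(sf$sf1, 10)
  expect_identical(sf$sf2, 4)
  sf1 <- compute_scaling(100, 100, 1)
  expect_identical(sf1$sf1, 1)
  expect_identical(sf1$sf2, 1)
  expect_error(compute_scaling(100, 0, 1), "no spike-in signal")
  expect_error(compute_scaling(100, 10, 0), "coverage")
})

test_that("binning uses half-open floor(pos/bin) bins and conserves reads", {
  layout <- make_genome_layout(100, "chr1")
  r <- data.frame(chrom = "chr1", pos = c(7, 10, 99), strand = "+",
                  status = "target_unique")
  tr <- bin_reads(r, layout, bin_size = 10)
  expect_equal(tr$values$chr1[1], 1)  # pos 7 -> bin 0
  expect_equal(tr$values$chr1[2], 1)  # pos 10 -> bin 1 (half-open)
  expect_equal(sum(tr$values$chr1), 3)
  # only unique target reads contribute
  r2 <- rbind(r, data.frame(chrom = "chr1", pos = 5, strand = "+",
                            status = "ambiguous"))
  expect_equal(sum(bin_reads(r2, layout)$values$chr1), 3)
  r3 <- data.frame(chrom = "chr1", pos = 100, strand = "+",
                   status = "target_unique")
  expect_error(bin_reads(r3, layout), "read 1")
})

test_that("bin totals equal unique target counts for simulated samples", {
  layout <- tiny_layout(c(2e5, 1e5))
  fs <- plant_features(layout, n_hotspots = 10, seed = 5)
  rd <- simulate_experiment(layout, fs, occupancy_model(), 2e4, seed = 6)
  for (r in rd)
    expect_equal(track_total(bin_reads(r, layout)),
                 unname(count_unique_reads(r)[["n_target_unique"]]))
})

test_that("calibration arithmetic: identity, example, negatives retained", {
  sf2 <- function(x) structure(list(sf1 = x, sf2 = x, sample_id = NA),
                               class = "ScalingFactors")
  chip <- track_from(list(c(5, 1, 2)))
  unt <- track_from(list(c(3, 5, 2)))
  out <- calibrate(chip, unt, sf2(2), sf2(1), scale = "none")
  expect_equal(out$values$chr1, c(5 * 2 - 3, 1 * 2 - 5, 2 * 2 - 2))
  expect_equal(out$values$chr1[2], -3)  # negative retained, not clamped
  same <- calibrate(chip, chip, sf2(1.5), sf2(1.5), scale = "none")
  expect_true(all(same$values$chr1 == 0))
  expect_identical(out$state, "calibrated")
  other <- track_from(list(c(1, 2)))
  expect_error(calibrate(chip, other, sf2(1), sf2(1)), "different")
})

test_that("calibration is invariant under joint count/SF rescaling", {
  chip <- track_from(list(c(4, 0, 6, 2)))
  unt <- track_from(list(c(1, 1, 2, 0)))
  sf <- function(x) structure(list(sf1 = x, sf2 = x, sample_id = NA),
                              class = "ScalingFactors")
  a <- calibrate(chip, unt, sf(3), sf(2), scale = "none")
  chip2 <- track_from(list(chip$values$chr1 * 5))
  unt2 <- track_from(list(unt$values$chr1 * 5))
  b <- calibrate(chip2, unt2, sf(3 / 5), sf(2 / 5), scale = "none")
  expect_equal(a$values, b$values)
})

test_that("default calibration scale is depth-invariant", {
  chip <- track_from(list(c(4, 0, 6, 2)))
  chip3x <- track_from(list(c(4, 0, 6, 2) * 3))
  unt <- track_from(list(c(1, 1, 2, 0)))
  sf <- function(x) structure(list(sf1 = x, sf2 = x, sample_id = NA),
                              class = "ScalingFactors")
  a <- calibrate(chip, unt, sf(2), sf(1))
  b <- calibrate(chip3x, unt, sf(2), sf(1))
  expect_equal(a$values, b$values)
})

test_that("replicate averaging is the per-bin mean", {
  t1 <- track_from(list(c(2, 0)))
  t2 <- track_from(list(c(4, 2)))
  t3 <- track_from(list(c(0, 4)))
  expect_equal(average_replicates(list(t1, t2))$values$chr1, c(3, 1))
  expect_equal(average_replicates(list(t1))$values$chr1, t1$values$chr1)
  expect_equal(average_replicates(list(t1, t2, t3))$values$chr1, c(2, 2))
  expect_error(average_replicates(list()), "no tracks")
  expect_error(average_replicates(list(t1, track_from(list(c(1, 2, 3))))),
               "different")
})

test_that("constant tracks are fixed points of the smoother", {
  tr <- track_from(list(rep(5, 200), rep(-1, 50)))
  sm <- smooth_track(tr, 1000)
  expect_equal(sm$values$chr1, rep(5, 200), tolerance = 1e-12)
  expect_equal(sm$values$chr2, rep(-1, 50), tolerance = 1e-12)
  expect_identical(sm$state, "smoothed")
  expect_error(smooth_track(tr, 0), "positive")
})

test_that("smoother equals the direct-summation Nadaraya-Watson oracle", {
  set.seed(41)
  n <- 1000
  v <- rnorm(n)
  v[500] <- 50  # unit-mass-style spike
  tr <- track_from(list(chrA = v))
  sm <- smooth_track(tr, 1000)
  centers <- (seq_len(n) - 0.5) * 10
  expect_lt(max(abs(sm$values$chrA - nw_oracle(v, centers, 1000))), 1e-9)
  # short final bin: oracle uses the true center of the partial bin
  layout <- make_genome_layout(10007, "chrB")
  v2 <- rnorm(ceiling(10007 / 10))
  tr2 <- binned_track(list(chrB = v2), layout, 10)
  sm2 <- smooth_track(tr2, 500)
  ctr <- (seq_along(v2) - 0.5) * 10
  ctr[length(v2)] <- ((length(v2) - 1) * 10 + 10007) / 2
  expect_lt(max(abs(sm2$values$chrB - nw_oracle(v2, ctr, 500))), 1e-9)
})

test_that("smoother agrees with the classic ksmooth interface convention", {
  set.seed(42)
  v <- rnorm(500)
  tr <- track_from(list(chrA = v))
  sm <- smooth_track(tr, 800)
  x <- (seq_along(v) - 0.5) * 10
  ks <- ksmooth(x, v, kernel = "normal", bandwidth = 800, x.points = x)$y
  expect_lt(max(abs(sm$values$chrA - ks)), 1e-3)
})

test_that("spike-in calibration recovers relative occupancy", {
  layout <- make_genome_layout(c(5e5, 5e5))
  fs <- plant_features(layout, n_hotspots = 60, n_axis = 20, seed = 21)
  model <- occupancy_model()
  rd <- simulate_experiment(
    layout, fs, model, n_reads = c(1e5, 1e5, 1e5),
    samples = data.frame(sample_id = c("a", "b", "unt"),
                         role = c("chip", "chip", "untagged")),
    occupancy_scale = c(1, 2, 1), seed = 22)
  tr <- lapply(rd, bin_reads, layout = layout)
  cov <- track_mean_coverage(tr$unt)
  sf <- lapply(rd, function(r) {
    cnt <- count_unique_reads(r)
    compute_scaling(cnt[[1]], cnt[[2]], cov)
  })
  sa <- track_total(calibrate(tr$a, tr$unt, sf$a, sf$unt))
  sb <- track_total(calibrate(tr$b, tr$unt, sf$b, sf$unt))
  expect_gt(sb / sa, 2 * 0.9)
  expect_lt(sb / sa, 2 * 1.1)
})
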