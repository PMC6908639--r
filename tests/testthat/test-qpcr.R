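test_that("replicate aggregation applies the median-distance outlier rule", {
  res <- aggregate_replicates(c(20.0, 20.1, 19.9))
  expect_equal(res$ct, 20.0)
  expect_length(res$qc_flags, 0)

  res <- aggregate_replicates(c(20.0, 20.1, 25.0))
  expect_equal(res$ct, 20.05)
  expect_true("ct_outlier_dropped" %in% res$qc_flags)

  res <- aggregate_replicates(22.3)
  expect_equal(res$ct, 22.3)
  expect_true("low_replication" %in% res$qc_flags)

  expect_error(aggregate_replicates(c(NA, NaN, Inf)), "no finite")
})

test_that("a perfect-doubling dilution series fits slope -3.3219, efficiency 1", {
  q <- 180 / 3^(0:4)  # the five-level 3-fold design, 2.22 to 180 ng
  expect_equal(max(q) / min(q), 81)
  expect_equal(min(q), 2.22, tolerance = 1e-2)
  plate <- as_plate(data.frame(
    well = seq_along(rep(q, 3)), sample = "std", target = "TEL",
    role = "standard", ct = -3.3219 * log10(rep(q, 3)) + 35,
    quantity_ng = rep(q, 3)))
  cv <- fit_standard_curve(plate, "TEL")
  expect_equal(cv$slope, -3.3219, tolerance = 1e-6)
  expect_equal(cv$intercept, 35, tolerance = 1e-6)
  expect_equal(cv$efficiency, 1.0, tolerance = 1e-4)
  expect_equal(cv$r_squared, 1.0, tolerance = 1e-10)

  # shuffled well order gives the identical curve
  set.seed(1)
  cv2 <- fit_standard_curve(plate[sample(nrow(plate)), ], "TEL")
  expect_equal(cv2[c("slope", "intercept")], cv[c("slope", "intercept")])

  expect_error(fit_standard_curve(plate[plate$quantity_ng > 50, ], "TEL"),
               "at least 3 distinct")
  bad <- plate; bad$ct <- rev(bad$ct)
  expect_error(fit_standard_curve(bad, "TEL"), "non-negative slope")
})

test_that("quantification inverts the curve and flags extrapolation", {
  cv <- structure(list(target = "TEL", slope = -3.3219, intercept = 35,
                       r_squared = 1, efficiency = 1,
                       quantity_range = c(2.22, 180)),
                  class = "standard_curve")
  ct20 <- -3.3219 * log10(20) + 35
  expect_equal(quantify(cv, ct20)$quantity, 20, tolerance = 1e-6)
  # one cycle lower doubles the quantity at perfect efficiency
  expect_equal(quantify(cv, ct20 - 1)$quantity / 20, 2, tolerance = 1e-4)
  ct_low <- -3.3219 * log10(1.0) + 35  # below the 2.22 ng standard
  expect_true("extrapolated" %in% quantify(cv, ct_low)$qc_flags)
  expect_error(quantify(cv, NA_real_), "non-finite")
})

test_that("zero-noise plates round-trip T/S exactly", {
  ts_true <- c(A = 0.72, B = 0.95, C = 1.31)
  plate <- simulate_plate(ts_true, s_quantity = c(10, 20, 40), ct_sd = 0)
  out <- compute_ts(plate)
  expect_equal(setNames(out$ts, out$sample), ts_true, tolerance = 1e-9)
  expect_equal(out$s_quantity, c(10, 20, 40), tolerance = 1e-9)

  # reference sample renormalizes to 1
  plate <- simulate_plate(c(R = 1.1, S = 0.9), ct_sd = 0, reference = "R")
  out <- compute_ts(plate)
  expect_equal(out$ts[out$sample == "R"], 1.0, tolerance = 1e-9)
  expect_equal(out$ts[out$sample == "S"], 0.9 / 1.1, tolerance = 1e-9)
})

test_that("T/S is monotone in Ct and invariant to a uniform Ct shift", {
  plate <- simulate_plate(c(X = 0.9), ct_sd = 0)
  ts0 <- compute_ts(plate)$ts
  # lower telomere Ct (same SCG) -> strictly larger T/S
  plate_lo <- plate
  sel <- plate_lo$sample == "X" & plate_lo$target == "TEL"
  plate_lo$ct[sel] <- plate_lo$ct[sel] - 0.3
  expect_gt(compute_ts(plate_lo)$ts, ts0)
  # equal-slope curves: adding a constant to every Ct leaves T/S unchanged
  plate_sh <- plate
  plate_sh$ct <- plate_sh$ct + 1.7
  expect_equal(compute_ts(plate_sh)$ts, ts0, tolerance = 1e-9)
})

test_that("noisy plates recover the generating T/S", {
  ts_true <- setNames(rep(0.9, 12), paste0("S", 1:12))
  plate <- simulate_plate(ts_true, ct_sd = 0.05, seed = 8)
  out <- compute_ts(plate)
  expect_lt(abs(mean(out$ts) - 0.9), 0.03)
  expect_lt(median(abs(out$ts - 0.9)), 0.03)
})

test_that("a sample missing one target is skipped with a flag", {
  plate <- simulate_plate(c(A = 1, B = 1), ct_sd = 0)
  plate <- plate[!(plate$sample == "B" & plate$target == "SCG"), ]
  expect_warning(out <- compute_ts(plate), "missing a target")
  expect_true(is.na(out$ts[out$sample == "B"]))
  expect_equal(out$qc_flags[out$sample == "B"], "missing_target")
})
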