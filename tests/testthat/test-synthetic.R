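test_that("silent profile yields an all-zero recording of the right shape", {
  prof <- subject_profile("z", 30, "male", band_gains = zero_gains(),
                          noise_level = 0)
  rec <- generate_recording(prof, duration_s = 8, fs = 250, seed = 7)
  expect_identical(dim(rec$data), c(19L, 2000L))
  expect_true(all(rec$data == 0))
  expect_identical(rec$channel_names,
                   c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "Fz", "T3", "T4",
                     "C3", "C4", "Cz", "T5", "T6", "P3", "P4", "Pz", "O1", "O2"))
})

test_that("180 s at 250 Hz gives 45,000 samples per channel", {
  prof <- subject_profile("s", 40, "female")
  rec <- generate_recording(prof, duration_s = 180, fs = 250, seed = 1)
  expect_identical(ncol(rec$data), 45000L)
})

test_that("recordings are bit-identical for a fixed seed and finite/bounded", {
  prof <- subject_profile("s", 55, "male")
  r1 <- generate_recording(prof, duration_s = 10, seed = 123)
  r2 <- generate_recording(prof, duration_s = 10, seed = 123)
  r3 <- generate_recording(prof, duration_s = 10, seed = 124)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, r3$data))
  expect_true(all(is.finite(r1$data)))
  expect_true(max(abs(r1$data)) <= 500)
  expect_lt(abs(mean(r1$data)), 1)   # zero-mean up to noise
})

test_that("profile validation rejects bad band names, ages and noise", {
  bad <- zero_gains()
  names(bad)[1] <- "sigma"
  expect_error(subject_profile("x", 30, "male", band_gains = bad), "band")
  expect_error(subject_profile("x", 3, "male"), "age")
  expect_error(subject_profile("x", 30, "male", noise_level = -1), "noise")
})

test_that("eyes-closed default profile has posterior alpha above delta (oracle)", {
  prof <- subject_profile("s", 30, "female")
  rec <- generate_recording(prof, duration_s = 60, fs = 250, seed = 5)
  o1 <- rec$data["O1", ]
  alpha <- direct_relative_band_power(o1, 250, 8, 12)
  delta <- direct_relative_band_power(o1, 250, 1, 4)
  expect_gt(alpha, delta)
})

test_that("cohorts are deterministic, age-bounded and sex-balanced", {
  c1 <- generate_cohort(10, age_range = c(20, 60), seed = 9, duration_s = 4)
  c2 <- generate_cohort(10, age_range = c(20, 60), seed = 9, duration_s = 4)
  expect_identical(c1[[3]]$recording$data, c2[[3]]$recording$data)
  ages <- vapply(c1, function(s) s$profile$age, numeric(1))
  expect_true(all(ages >= 20 & ages <= 60))
  big <- generate_cohort(25, age_range = c(20, 60), seed = 1, duration_s = 4)
  sexes <- vapply(big, function(s) s$profile$sex, character(1))
  expect_lte(abs(sum(sexes == "male") - sum(sexes == "female")), 1)
})

test_that("a 553:736 male:female cohort shape is expressible via male_frac", {
  co <- generate_cohort(20, seed = 2, male_frac = 553 / 1289, duration_s = 4)
  sexes <- vapply(co, function(s) s$profile$sex, character(1))
  expect_equal(sum(sexes == "male"), round(20 * 553 / 1289))
})

test_that("ADD recordings slow relative to controls in expectation (oracle)", {
  ## independent periodogram oracle on the O1 channel, n = 30 per group
  n <- 30
  ds <- generate_labeled_dataset(n, n, separation = 1, seed = 31, duration_s = 8)
  lab <- vapply(ds, `[[`, character(1), "label")
  theta <- vapply(ds, function(s)
    direct_relative_band_power(s$recording$data["O1", ], 250, 4, 8), numeric(1))
  alpha <- vapply(ds, function(s)
    direct_relative_band_power(s$recording$data["O1", ], 250, 8, 12), numeric(1))
  slowing <- vapply(ds, function(s)
    direct_relative_band_power(s$recording$data["O1", ], 250, 1, 8), numeric(1))
  expect_gt(mean(theta[lab == "ADD"]), mean(theta[lab == "NADD"]))
  expect_gt(mean(slowing[lab == "ADD"]), mean(slowing[lab == "NADD"]))
  expect_lt(mean(alpha[lab == "ADD"]), mean(alpha[lab == "NADD"]))
})

test_that("separation = 0 makes the two groups exchangeable in alpha power", {
  diffs <- vapply(1:5, function(sd) {
    ds <- generate_labeled_dataset(8, 8, separation = 0, seed = sd,
                                   duration_s = 8)
    lab <- vapply(ds, `[[`, character(1), "label")
    alpha <- vapply(ds, function(s)
      direct_relative_band_power(s$recording$data["O1", ], 250, 8, 12),
      numeric(1))
    mean(alpha[lab == "ADD"]) - mean(alpha[lab == "NADD"])
  }, numeric(1))
  ## sign flips across seeds and magnitudes stay small: no systematic shift
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("class imbalance matching a 137:628 cohort is supported", {
  ds <- generate_labeled_dataset(4, 18, separation = 1, seed = 3, duration_s = 4)
  lab <- vapply(ds, `[[`, character(1), "label")
  expect_identical(unname(table(lab)["ADD"]), 4L)
  expect_identical(unname(table(lab)["NADD"]), 18L)
})
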