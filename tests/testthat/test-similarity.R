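ref_profile <- function(times = c(0, 1, 2, 4, 8),
                        mean = c(0, 10, 20, 12, 5),
                        sd = c(0, 2, 4, 3, 1)) {
  tibble::tibble(time = times, mean = mean, sd = sd, n = 12)
}

test_that("weighted RMSE and MAPE match hand-computed single-point oracles", {
  ref <- ref_profile(times = c(0, 1), mean = c(0, 10), sd = c(0, 2))
  sim <- tibble::tibble(time = c(0, 1), mean = c(0, 12))
  expect_equal(weighted_rmse(ref, sim), sqrt((10 - 12)^2 / 2^2)) # = 1
  expect_equal(weighted_rmse(ref, sim), 1)
  expect_equal(weighted_mape(ref, sim), (1 / 2) * (2 / 10) * 100) # = 10%
  expect_equal(weighted_mape(ref, sim), 10)

  # identical profiles score zero on both indices
  same <- tibble::tibble(time = ref$time, mean = ref$mean)
  expect_equal(weighted_rmse(ref, same), 0)
  expect_equal(weighted_mape(ref, same), 0)

  # multi-point hand oracle
  ref2 <- ref_profile()
  sim2 <- tibble::tibble(time = ref2$time, mean = c(0, 11, 18, 12, 4.5))
  idx <- 2:5
  expect_equal(
    weighted_rmse(ref2, sim2),
    sqrt(mean((ref2$mean[idx] - sim2$mean[idx])^2 / ref2$sd[idx]^2)))
  expect_equal(
    weighted_mape(ref2, sim2),
    mean(abs(ref2$mean[idx] - sim2$mean[idx]) / ref2$mean[idx] /
           ref2$sd[idx]) * 100)
})

test_that("the indices increase when any point moves away and rescale correctly", {
  ref <- ref_profile()
  sim <- tibble::tibble(time = ref$time, mean = c(0, 11, 18, 12, 4.5))
  r0 <- weighted_rmse(ref, sim)
  m0 <- weighted_mape(ref, sim)
  worse <- sim
  worse$mean[4] <- 16 # move one point further from ref (12)
  expect_gt(weighted_rmse(ref, worse), r0)
  expect_gt(weighted_mape(ref, worse), m0)

  # under joint rescaling of ref, sim and sd by k the SD weight contributes
  # a 1/k factor: (1/(k sd)) * |k ref - k sim| / (k ref) = term / k
  k <- 3.7
  ref_k <- ref
  ref_k$mean <- ref$mean * k
  ref_k$sd <- ref$sd * k
  sim_k <- sim
  sim_k$mean <- sim$mean * k
  expect_equal(weighted_mape(ref_k, sim_k), m0 / k)
  # ...while RMSE is invariant when deviations and sd rescale together
  expect_equal(weighted_rmse(ref_k, sim_k), r0)

  expect_error(weighted_rmse(ref_profile(sd = c(0, 0, 4, 3, 1)), sim), "SD")
})

test_that("band coverage counts points outside the referent mean +/- 1 SD", {
  ref <- ref_profile()
  sim_in <- tibble::tibble(time = ref$time, mean = ref$mean)
  bc <- band_coverage(ref, sim_in)
  expect_equal(bc$coverage, 1)
  expect_length(bc$outside, 0)

  sim_out <- tibble::tibble(time = ref$time, mean = c(0, 13, 20, 12, 5))
  bc2 <- band_coverage(ref, sim_out) # |13 - 10| > sd 2 at t = 1
  expect_equal(bc2$coverage, 0.75)
  expect_equal(bc2$outside, 1)

  # a zero-SD point counts as outside for any difference
  ref0 <- ref_profile(sd = c(0, 2, 4, 3, 0))
  sim0 <- tibble::tibble(time = ref0$time, mean = c(0, 10, 20, 12, 5.001))
  expect_equal(band_coverage(ref0, sim0)$outside, 8)

  expect_error(band_coverage(ref, tibble::tibble(time = c(0, 1), mean = c(0, 1))),
               "grid")
})

test_that("descriptive similarity applies the 25% rule parameter-wise", {
  pkv <- tibble::tibble(AUC = 295.81, Cmax = 101.39, Tmax = 0.5, Kel = 0.28,
                        T1_2 = 3.74, CL_F = 57.72, V_F = 205.2)
  same <- descriptive_similarity(pkv, pkv)
  expect_true(same$verdict)
  expect_true(all(same$diffs$absolute == 0))

  sim <- pkv
  sim$AUC <- 318.83
  d <- descriptive_similarity(pkv, sim)
  arow <- d$diffs[d$diffs$parameter == "AUC", ]
  expect_equal(arow$absolute, 23.02, tolerance = 1e-3)
  expect_equal(arow$relative, 7.8, tolerance = 0.01)
  expect_true(d$verdict)

  sim2 <- pkv
  sim2$Cmax <- pkv$Cmax * 1.26 # 26% off -> fails the 25% rule
  expect_false(descriptive_similarity(pkv, sim2)$verdict)

  # Tmax compared in absolute terms only
  expect_true(is.na(d$diffs$relative[d$diffs$parameter == "Tmax"]))
})

test_that("the three-level report verdicts combine correctly", {
  ref <- ref_profile()
  sim <- tibble::tibble(time = ref$time, mean = ref$mean)
  rep <- similarity_report(ref, sim)
  expect_true(rep$verdicts$level1)
  expect_true(rep$verdicts$level2)
  expect_true(is.na(rep$verdicts$level3))
  g <- glance(rep)
  expect_equal(g$weightedRMSE, 0)
  expect_equal(g$bandCoverage, 1)

  # worsening any single point never flips the level-2 verdict false -> true
  sim_bad <- sim
  sim_bad$mean[2] <- sim$mean[2] + 30 # far outside
  rep_bad <- similarity_report(ref, sim_bad)
  expect_false(rep_bad$verdicts$level2)
  sim_worse <- sim_bad
  sim_worse$mean[3] <- sim_bad$mean[3] + 30
  rep_worse <- similarity_report(ref, sim_worse)
  expect_false(rep_worse$verdicts$level2)
  expect_gt(rep_worse$weightedRMSE, rep_bad$weightedRMSE)

  expect_output(print(rep), "Similarity criteria")
})
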