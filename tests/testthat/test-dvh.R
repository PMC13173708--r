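mk_vol <- function(vals, dims = NULL, spacing = c(2, 2, 2), kind = "dose") {
  if (is.null(dims)) dims <- dim(vals)
  volume_grid(array(vals, dims), spacing = spacing, kind = kind)
}

test_that("compute_dvh matches hand-computable cases", {
  dims <- c(4, 4, 2)
  mask <- mk_vol(rep(1, 32), dims, kind = "mask")
  # uniform dose: step curve
  d <- mk_vol(rep(20, 32), dims)
  curve <- compute_dvh(d, mask, bin_width = 1)
  expect_equal(curve$cum_volume[curve$dose_bins <= 20], rep(1, 21))
  expect_equal(curve$cum_volume[curve$dose_bins > 20],
               rep(0, sum(curve$dose_bins > 20)))
  expect_equal(curve$cum_volume[1], 1)
  expect_true(all(diff(curve$cum_volume) <= 0))
  # two voxels {40, 50}: V45 = 50%
  m2 <- mk_vol(c(1, 1, rep(0, 30)), dims, kind = "mask")
  d2 <- mk_vol(c(40, 50, rep(0, 30)), dims)
  expect_equal(endpoint(d2, m2, "V45"), 50)
  expect_equal(endpoint(d2, m2, "D50%"), 45) # linear interpolation
  expect_error(compute_dvh(d2, mk_vol(rep(0, 32), dims, kind = "mask"),
                           roi = "Rectum"), "Rectum")
})

test_that("endpoints match the independent sort-based oracle", {
  set.seed(42)
  metrics <- c("Dmax", "Dmean", "D2%", "D50%", "D98%", "V20", "V45",
               "V95%", "HI", "CI")
  for (rep in 1:12) {
    dims <- c(16, 16, 16)
    vals <- array(runif(prod(dims), 0, 55), dims)
    mvals <- array(rbinom(prod(dims), 1, 0.3), dims)
    if (sum(mvals) < 5) next
    dose <- mk_vol(vals); mask <- mk_vol(mvals, kind = "mask")
    for (m in metrics) {
      got <- endpoint(dose, mask, m, prescription = 45)
      want <- oracle_endpoint(vals, mvals, m, 45)
      expect_equal(got, want, tolerance = 1e-9, label = m)
    }
  }
})

test_that("endpoint monotonicity holds in dose and volume", {
  set.seed(1)
  dims <- c(12, 12, 6)
  dose <- mk_vol(array(runif(prod(dims), 0, 50), dims))
  mask <- mk_vol(array(1, dims), kind = "mask")
  v <- vapply(c(10, 20, 30, 40), function(d) endpoint(dose, mask, paste0("V", d)),
              numeric(1))
  expect_true(all(diff(v) <= 0))
  dp <- vapply(c(2, 25, 50, 75, 98), function(p)
    endpoint(dose, mask, paste0("D", p, "%")), numeric(1))
  expect_true(all(diff(dp) <= 0))
  expect_lte(endpoint(dose, mask, "D2%"), endpoint(dose, mask, "Dmax"))
})

test_that("HI and CI have their textbook limiting values", {
  dims <- c(10, 10, 4)
  mask_vals <- array(0, dims); mask_vals[4:7, 4:7, 2:3] <- 1
  mask <- mk_vol(mask_vals, kind = "mask")
  uniform <- mk_vol(array(30, dims))
  expect_equal(endpoint(uniform, mask, "HI"), 0)
  # dose exactly the prescription on the target, zero elsewhere: Paddick 1
  conf <- mk_vol(45 * mask_vals)
  expect_equal(endpoint(conf, mask, "CI", prescription = 45), 1)
  expect_equal(endpoint(conf, mask, "CI", prescription = 45,
                        ci_type = "rtog"), 1)
})

test_that("dose_score equals the brute-force restricted MAE", {
  set.seed(9)
  dims <- c(10, 8, 6)
  pred <- mk_vol(array(runif(prod(dims), 0, 50), dims))
  ref <- mk_vol(array(runif(prod(dims), 0, 50), dims))
  body <- mk_vol(array(rbinom(prod(dims), 1, 0.6), dims), kind = "mask")
  expect_equal(dose_score(pred, pred, body), 0)
  # constant offset
  shifted <- pred; shifted$values <- pred$values + 1
  expect_equal(dose_score(shifted, pred, body), 1.0, tolerance = 1e-12)
  # naive loop oracle
  acc <- 0; n <- 0
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3])
    if (body$values[i, j, k] > 0) {
      acc <- acc + abs(pred$values[i, j, k] - ref$values[i, j, k]); n <- n + 1
    }
  expect_equal(dose_score(pred, ref, body), acc / n, tolerance = 1e-12)
})

test_that("dvh_score and sn_dvh_score follow their definitions", {
  ph <- small_phantom()
  dose <- forward_dose(ph$structures, rep(2, 4), c(0, 45, 90, 135))
  expect_equal(dvh_score(dose, dose, ph$structures), 0)
  expect_equal(sn_dvh_score(dose, dose, ph$structures), 0)
  # translation by c moves every pure-D endpoint by exactly c
  shifted <- dose
  shifted$values <- dose$values + 2
  shifted$values[ph$structures$masks$Body$values == 0] <- 0
  sp <- spec_openkbp() # all D-type metrics
  expect_equal(dvh_score(shifted, dose, ph$structures, sp), 2, tolerance = 1e-9)
  # snDVH on a hand-computed toy spec: one D and one V endpoint
  toy <- list(PTV = c("Dmean", "V30"))
  tp <- endpoint_table(shifted, ph$structures, toy, 45)
  tr <- endpoint_table(dose, ph$structures, toy, 45)
  want <- sum(abs(tp$value - tr$value) / c(45, 100))
  expect_equal(sn_dvh_score(shifted, dose, ph$structures, toy, 45), want,
               tolerance = 1e-12)
  # per-endpoint oracle recomputation
  got <- dvh_score(shifted, dose, ph$structures, toy, 45)
  man <- mean(abs(tp$value - tr$value))
  expect_equal(got, man, tolerance = 1e-12)
  expect_error(sn_dvh_score(dose, dose, ph$structures, scales = c(D = -1, V = 100, other = 1)),
               "positive")
  expect_error(dvh_score(dose, dose, ph$structures, list()), "empty")
  expect_error(dvh_score(dose, dose, ph$structures, list(Liver = "Dmean")),
               "Liver")
})

test_that("endpoint tables round-trip through CSV", {
  ph <- small_phantom()
  dose <- forward_dose(ph$structures, rep(2, 4), c(0, 45, 90, 135))
  tab <- endpoint_table(dose, ph$structures, spec_protocol(), 45)
  f <- tempfile(fileext = ".csv")
  write_endpoints(tab, f)
  expect_equal(read_endpoints(f), tab, tolerance = 1e-12)
})
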