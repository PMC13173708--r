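test_that("extract_targets matches the endpoint oracle row by row", {
  ph <- small_phantom()
  dose <- forward_dose(ph$structures, rep(3, 4), c(0, 45, 90, 135))
  M0 <- extract_targets(dose, ph$structures, prescription = 45)
  expect_identical(nrow(M0), nrow(default_protocol()))
  for (i in seq_len(nrow(M0))) {
    want <- oracle_endpoint(dose$values,
                            ph$structures$masks[[M0$roi[i]]]$values,
                            M0$metric[i], 45)
    expect_equal(M0$value[i], want, tolerance = 1e-9,
                 label = paste(M0$roi[i], M0$metric[i]))
  }
  # identical dose twice: identical tables
  expect_identical(M0, extract_targets(dose, ph$structures, prescription = 45))
  # a dose meeting prescription on the PTV reports V95% == 100
  conf <- dose
  conf$values <- 45 * ph$structures$masks$PTV$values
  tab <- extract_targets(conf, ph$structures, list(PTV = "V95%"), 45)
  expect_equal(tab$value, 100)
})

test_that("assemble_objectives maps goal rows one-to-one and round-trips", {
  ph <- small_phantom()
  dose <- forward_dose(ph$structures, rep(3, 4), c(0, 45, 90, 135))
  M0 <- extract_targets(dose, ph$structures, prescription = 45)
  objs <- assemble_objectives(M0)
  expect_identical(length(objs), nrow(M0))
  for (i in seq_along(objs)) {
    expect_equal(objs[[i]]$goal, M0$value[i]) # goals reproduce M0 exactly
    expect_identical(objs[[i]]$roi, M0$roi[i])
  }
  # identity mapping example: an OAR V-metric becomes an upper bound
  j <- which(M0$roi == "Bladder" & M0$metric == "V40")
  expect_identical(objs[[j]]$kind, "oar_max_dvh")
  bad <- M0[1, ]; bad$metric <- "V77"
  expect_error(assemble_objectives(bad), "no protocol mapping")
})

test_that("aggregate_violation implements the scaled one-sided shortfall", {
  M0 <- data.frame(roi = c("PTV", "Bladder"), metric = c("D98%", "Dmean"),
                   value = c(43, 30), units = "Gy")
  kinds <- c("target_min_dvh", "oar_mean")
  met <- data.frame(roi = M0$roi, metric = M0$metric, value = c(43.5, 29),
                    units = "Gy")
  expect_equal(aggregate_violation(met, M0, kinds, 45), 0)
  # one OAR D-metric 4.5 Gy over its bound: 4.5 / 45 = 0.1
  over <- met; over$value <- c(43.5, 34.5)
  expect_equal(aggregate_violation(over, M0, kinds, 45), 0.1)
  # worsening any metric never decreases the violation
  worse <- over; worse$value[1] <- 41
  expect_gte(aggregate_violation(worse, M0, kinds, 45),
             aggregate_violation(over, M0, kinds, 45))
  expect_error(aggregate_violation(met[1, ], M0, kinds), "aligned")
})

test_that("the optimizer descends deterministically and fits a lone target", {
  ph <- small_phantom()
  geom <- beam_geometry(ph$structures, small_config())
  objs <- list(objective("PTV", "target_min_dvh", "D98%", 45, weight = 10))
  fit1 <- optimize_beamlets(objs, ph$structures, geom, 45)
  fit2 <- optimize_beamlets(objs, ph$structures, geom, 45)
  expect_identical(fit1$weights, fit2$weights) # deterministic
  expect_true(all(diff(fit1$objective_trace) <= 1e-12)) # monotone descent
  ptv <- ph$structures$masks$PTV
  dmean <- mean(fit1$dose$values[ptv$values > 0])
  # a single coverage objective pulls the target to (at least) its goal
  expect_gte(dmean, 45 * 0.98)
  expect_error(optimize_beamlets(list(), ph$structures, geom), "no objectives")
})

test_that("the planning loop stops early, caps at five and keeps the best", {
  ph <- small_phantom()
  cfg <- small_config()
  geom <- beam_geometry(ph$structures, cfg)
  ref <- generate_reference_plan(ph$ct, ph$structures, cfg)
  # feasible goals: extracted from an achievable reference plan
  M0 <- extract_targets(ref, ph$structures, prescription = 45)
  plan <- iterate_plan(M0, ph$structures, geom, prescription = 45)
  expect_lte(length(plan$iterations), 5)
  expect_gte(length(plan$iterations), 1)
  viols <- vapply(plan$iterations, `[[`, numeric(1), "aggregate_violation")
  expect_equal(plan$retained, which.min(viols))
  expect_true(all(viols[plan$retained] <= viols))
  # met objectives keep their goals between iterations
  if (length(plan$iterations) > 1) {
    for (it in 2:length(plan$iterations)) {
      prev <- plan$iterations[[it - 1]]
      expect_equal(plan$iterations[[it]]$goals[prev$met],
                   prev$goals[prev$met])
    }
  }
})

test_that("an infeasible goal runs all five iterations with 2% tightening", {
  ph <- small_phantom()
  geom <- beam_geometry(ph$structures, small_config())
  # target coverage plus a near-zero bound on the abutting bladder: the
  # bladder sits inside the target's beam corridors, so both cannot hold
  M0 <- data.frame(roi = c("PTV", "Bladder"), metric = c("D98%", "Dmean"),
                   value = c(44, 0.2), units = "Gy")
  protocol <- data.frame(roi = c("PTV", "Bladder"),
                         metric = c("D98%", "Dmean"),
                         kind = c("target_min_dvh", "oar_mean"),
                         weight = c(60, 2))
  plan <- iterate_plan(M0, ph$structures, geom, protocol, prescription = 45,
                       optimizer_args = list(max_iter = 60))
  expect_identical(length(plan$iterations), 5L)
  expect_gt(plan$iterations[[plan$retained]]$aggregate_violation, 0)
  # unmet upper bounds tighten multiplicatively by 2% per iteration
  g1 <- plan$iterations[[1]]$goals
  g2 <- plan$iterations[[2]]$goals
  unmet_upper <- !plan$iterations[[1]]$met & plan$kinds == "oar_mean"
  expect_equal(g2[unmet_upper], g1[unmet_upper] * 0.98)
})

test_that("a 30 Gy unmet OAR bound becomes 29.4 Gy after one tightening", {
  # pure goal arithmetic, isolated from the optimizer
  expect_equal(30 * (1 - 0.02), 29.4)
  ph <- small_phantom()
  geom <- beam_geometry(ph$structures, small_config())
  M0 <- data.frame(roi = c("PTV", "Bladder"), metric = c("D98%", "Dmean"),
                   value = c(44, 30), units = "Gy")
  protocol <- data.frame(roi = c("PTV", "Bladder"),
                         metric = c("D98%", "Dmean"),
                         kind = c("target_min_dvh", "oar_mean"),
                         weight = c(60, 2))
  plan <- iterate_plan(M0, ph$structures, geom, protocol, prescription = 45,
                       optimizer_args = list(max_iter = 60))
  if (length(plan$iterations) > 1 && !plan$iterations[[1]]$met[2])
    expect_equal(plan$iterations[[2]]$goals[2], 29.4)
})

test_that("plan results serialise with their iteration history", {
  ph <- small_phantom()
  cfg <- small_config()
  geom <- beam_geometry(ph$structures, cfg)
  ref <- generate_reference_plan(ph$ct, ph$structures, cfg)
  M0 <- extract_targets(ref, ph$structures, prescription = 45)
  plan <- iterate_plan(M0, ph$structures, geom, prescription = 45)
  dir <- tempfile()
  write_plan_result(plan, dir)
  meta <- jsonlite::read_json(file.path(dir, "plan.json"), simplifyVector = TRUE)
  expect_equal(meta$retained, plan$retained)
  expect_equal(length(meta$iterations$index), length(plan$iterations))
  dose <- read_volume(file.path(dir, "plan_dose.nii.gz"), kind = "dose")
  expect_equal(dose$values, plan$dose$values, tolerance = 1e-6)
})
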