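#' Pipeline configuration
#'
#' One object holding everything a full run needs: phantom settings, cohort
#' size, the two training configurations, the band count and the root seed.
#' Round-trips losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param out_dir output directory of the run.
#' @param n_cases cohort size.
#' @param phantom a [phantom_config()].
#' @param train1,train2 [train_config()]s for the two stages.
#' @param k_bands band-mask count.
#' @param seed root seed; all stage seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, n_cases = 6,
                            phantom = phantom_config(shape = c(32, 32, 16),
                                                     spacing = c(5, 5, 10)),
                            train1 = train_config(epochs = 8, width = 8),
                            train2 = train_config(epochs = 6, width = 8),
                            k_bands = 4, seed = 1L) {
  phantom$seed <- as.integer(seed)
  train1$seed <- as.integer(seed)
  train2$seed <- as.integer(seed)
  train1$k_bands <- train2$k_bands <- as.integer(k_bands)
  structure(list(out_dir = out_dir, n_cases = as.integer(n_cases),
                 phantom = phantom, train1 = train1, train2 = train2,
                 k_bands = as.integer(k_bands), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @rdname pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), identity, how = "list"), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    out_dir = raw$out_dir, n_cases = raw$n_cases,
    phantom = do.call(phantom_config, raw$phantom[setdiff(names(raw$phantom), "seed")]),
    train1 = do.call(train_config,
                     c(raw$train1[setdiff(names(raw$train1),
                                          c("seed", "weights", "k_bands"))],
                       list(weights = do.call(loss_weights, raw$train1$weights)))),
    train2 = do.call(train_config,
                     c(raw$train2[setdiff(names(raw$train2),
                                          c("seed", "weights", "k_bands"))],
                       list(weights = do.call(loss_weights, raw$train2$weights)))),
    k_bands = raw$k_bands, seed = raw$seed)
  cfg
}

pipeline_log <- function(run_dir, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  logf <- file.path(run_dir, "run.jsonl")
  cat(jsonlite::toJSON(list(stage = stage, msg = msg), auto_unbox = TRUE),
      "\n", file = logf, append = TRUE)
}

#' Run the full auto-planning pipeline
#'
#' simulate -> band masks -> Stage-1 training -> Stage-2 training ->
#' prediction -> DVH-driven planning -> scoring -> gamma. Each stage writes
#' its artifacts under `config$out_dir` and is skipped when its output
#' already exists, so deleting one intermediate re-executes only the stages
#' downstream of it. Deterministic given the config (including its seed).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage logging.
#' @return the run report (also written to `report.json`), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- if (quiet) function(...) invisible() else
    function(stage, msg) pipeline_log(out, stage, msg)
  cohort <- file.path(out, "cohort")
  if (!file.exists(file.path(cohort, "manifest.json"))) {
    log("simulate", sprintf("generating %d cases", config$n_cases))
    generate_cohort(config$n_cases, config$phantom, cohort)
  } else log("simulate", "cohort exists, skipping")
  man <- read_manifest(cohort)
  ids_test <- man$cases$id[man$cases$split == "test"]

  bands_json <- file.path(out, "band_coverage.json")
  if (!file.exists(bands_json)) {
    log("bands", "computing band coverage on test cases")
    cov <- vapply(ids_test, function(id) {
      cs <- read_case(cohort, id)
      bs <- make_band_set(cs$structures$masks$PTV, k = config$k_bands)
      band_dose_coverage(cs$dose, bs)
    }, numeric(1))
    jsonlite::write_json(list(k = config$k_bands, coverage = as.list(cov)),
                         bands_json, auto_unbox = TRUE, digits = NA)
  } else log("bands", "exists, skipping")

  ck1_path <- file.path(out, "stage1.ckpt")
  if (!file.exists(ck1_path)) {
    log("train1", sprintf("%d epochs", config$train1$epochs))
    ck1 <- train_stage1(cohort, config$train1, quiet = TRUE)
    write_checkpoint(ck1, ck1_path)
  } else { log("train1", "checkpoint exists, skipping"); ck1 <- read_checkpoint(ck1_path) }

  ck2_path <- file.path(out, "stage2.ckpt")
  if (!file.exists(ck2_path)) {
    log("train2", sprintf("%d epochs", config$train2$epochs))
    ck2 <- train_stage2(cohort, ck1, config$train2, quiet = TRUE)
    write_checkpoint(ck2, ck2_path)
  } else { log("train2", "checkpoint exists, skipping"); ck2 <- read_checkpoint(ck2_path) }

  pred_dir <- file.path(out, "pred")
  dir.create(pred_dir, showWarnings = FALSE)
  for (id in ids_test) {
    f <- file.path(pred_dir, paste0(id, "_refined.nii.gz"))
    if (file.exists(f)) next
    log("predict", id)
    cs <- read_case(cohort, id)
    pr <- predict_dose(cs, ck1, ck2)
    write_volume(pr$coarse, file.path(pred_dir, paste0(id, "_coarse.nii.gz")))
    write_volume(pr$refined, f)
  }

  rx <- config$phantom$prescription
  plan_root <- file.path(out, "plans")
  for (id in ids_test) {
    pdir <- file.path(plan_root, id)
    if (file.exists(file.path(pdir, "plan.json"))) next
    log("plan", id)
    cs <- read_case(cohort, id)
    refined <- read_volume(file.path(pred_dir, paste0(id, "_refined.nii.gz")),
                           kind = "dose")
    M0 <- extract_targets(refined, cs$structures, prescription = rx)
    geom <- beam_geometry(cs$structures, config$phantom)
    plan <- iterate_plan(M0, cs$structures, geom, prescription = rx)
    write_plan_result(plan, pdir)
  }

  report_path <- file.path(out, "report.json")
  log("score", "scoring test cases")
  per_case <- lapply(ids_test, function(id) {
    cs <- read_case(cohort, id)
    refined <- read_volume(file.path(pred_dir, paste0(id, "_refined.nii.gz")),
                           kind = "dose")
    plan_dose <- read_volume(file.path(plan_root, id, "plan_dose.nii.gz"),
                             kind = "dose")
    sr <- score_report(refined, cs$dose, cs$structures, rx)
    list(id = id,
         pred_dose_score = sr$dose_score, pred_dvh_score = sr$dvh_score,
         pred_sndvh_score = sr$sndvh_score,
         plan_dose_score = dose_score(plan_dose, cs$dose,
                                      cs$structures$masks$Body),
         gamma_plan_vs_ref = gamma_pass_rate(cs$dose, plan_dose),
         gamma_pred_vs_ref = gamma_pass_rate(cs$dose, refined))
  })
  num <- function(field) vapply(per_case, `[[`, numeric(1), field)
  report <- list(
    seed = config$seed, n_cases = config$n_cases, test_ids = ids_test,
    per_case = per_case,
    summary = list(
      median_pred_dose_score = stats::median(num("pred_dose_score")),
      median_pred_dvh_score = stats::median(num("pred_dvh_score")),
      median_pred_sndvh_score = stats::median(num("pred_sndvh_score")),
      median_plan_dose_score = stats::median(num("plan_dose_score")),
      median_gamma_plan = stats::median(num("gamma_plan_vs_ref")),
      median_gamma_pred = stats::median(num("gamma_pred_vs_ref"))))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log("score", "report written")
  invisible(report)
}

band_ablation_angles <- function(k_values) {
  # nested angle subsets: angles from the k_max uniform set, added in a
  # bisection order (0, 90, 45, 135, ...) so every smaller arm is a subset
  kmax <- max(k_values)
  full <- (seq_len(kmax) - 1) * 180 / kmax
  ord <- order(vapply(seq_along(full), function(i) {
    # bisection rank: reverse the bits of (i-1) over the binary tree
    r <- i - 1; rank <- 0; n <- kmax
    while (n > 1) { rank <- 2 * rank + r %% 2; r <- r %/% 2; n <- n / 2 }
    rank
  }, numeric(1)))
  full[ord]
}

#' Band-count ablation
#'
#' Computes the thresholded-dose-mass coverage of the band union for each
#' `k` on the cohort's test cases, using nested angle subsets (smaller arms
#' are subsets of larger ones) so coverage is non-decreasing in `k` by
#' construction. Also reports the band-mask storage per case, which grows
#' linearly with `k`.
#'
#' @param cohort_dir cohort directory.
#' @param k_values increasing band counts to test (powers of two give exact
#'   nesting; other values are nested by bisection order).
#' @param threshold_fraction coverage dose threshold (see
#'   [band_dose_coverage()]).
#' @return data.frame per (k, case) plus a `summary` attribute of per-k
#'   median coverage and storage bytes.
#' @export
ablate_bands <- function(cohort_dir, k_values = c(1, 2, 4, 8),
                         threshold_fraction = 0.5) {
  if (length(k_values) == 0) stop("k_values is empty", call. = FALSE)
  k_values <- sort(unique(k_values))
  angles_all <- band_ablation_angles(k_values)
  man <- read_manifest(cohort_dir)
  ids <- man$cases$id[man$cases$split == "test"]
  if (length(ids) == 0) ids <- man$cases$id
  rows <- list()
  for (id in ids) {
    cs <- read_case(cohort_dir, id)
    for (k in k_values) {
      bs <- make_band_set(cs$structures$masks$PTV,
                          angles = angles_all[seq_len(k)])
      rows[[length(rows) + 1]] <- data.frame(
        id = id, k = k,
        coverage = band_dose_coverage(cs$dose, bs, threshold_fraction),
        band_bytes = as.numeric(utils::object.size(
          lapply(bs$bands, function(b) b$values))))
    }
  }
  df <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(df, df$k), function(g)
    data.frame(k = g$k[1], median_coverage = stats::median(g$coverage),
               band_bytes = stats::median(g$band_bytes))))
  attr(df, "summary") <- summ
  df
}

loss_arm_weights <- function() {
  list(baseline = loss_weights(1, 0, 0, 0) ,
       band = loss_weights(1, 1, 0, 0),
       band_grad = loss_weights(1, 1, 1, 0),
       band_grad_dvh = loss_weights(1, 1, 1, 1))
}

#' Loss-term ablation
#'
#' Trains the Stage-2 refinement under the four cumulative loss
#' configurations (body MAE only; + band term; + gradient term; + DVH
#' term) with identical seeds, splits and Stage-1 checkpoints across arms,
#' then scores each arm's refined test doses. Arms are summarised by the
#' median over seeds; a seed-paired sign summary of the final arm against
#' the baseline is included.
#'
#' @param cohort_dir cohort directory.
#' @param base_config Stage-2 [train_config()] shared by all arms (its
#'   `weights` field is overridden per arm).
#' @param seeds integer vector of seeds (Stage-1 is retrained per seed,
#'   shared across the four arms of that seed).
#' @param stage1_epochs Stage-1 epochs per seed.
#' @param quiet suppress logging.
#' @return list with `per_run` data.frame (seed x arm scores), `summary`
#'   (per-arm medians in the cumulative order), `paired_sign` counts.
#' @export
ablate_losses <- function(cohort_dir, base_config = train_config(width = 8),
                          seeds = 1:3, stage1_epochs = base_config$epochs,
                          quiet = FALSE) {
  arms <- loss_arm_weights()
  man <- read_manifest(cohort_dir)
  ids_test <- man$cases$id[man$cases$split == "test"]
  rx <- base_config$prescription
  rows <- list()
  s1rows <- list()
  # validation MAE of the trivial all-zero predictor, for the learning floor
  ids_va <- man$cases$id[man$cases$split == "val"]
  zero_mae <- mean(vapply(ids_va, function(id) {
    cs <- read_case(cohort_dir, id)
    b <- cs$structures$masks$Body$values > 0
    mean(abs(cs$dose$values[b]))
  }, numeric(1)))
  for (sd in seeds) {
    cfg1 <- base_config; cfg1$seed <- as.integer(sd); cfg1$epochs <- as.integer(stage1_epochs)
    if (!quiet) message("ablate_losses: stage 1, seed ", sd)
    ck1 <- train_stage1(cohort_dir, cfg1, quiet = TRUE)
    s1_scores <- vapply(ids_test, function(id) {
      cs <- read_case(cohort_dir, id)
      pr <- predict_dose(cs, ck1)
      dose_score(pr$coarse, cs$dose, cs$structures$masks$Body)
    }, numeric(1))
    s1rows[[length(s1rows) + 1]] <- data.frame(
      seed = sd, zero_val_mae_gy = zero_mae,
      epoch1_val_mae_gy = ck1$history$val_mae_gy[1],
      best_val_mae_gy = min(ck1$history$val_mae_gy),
      stage1_test_dose_score = stats::median(s1_scores))
    for (arm in names(arms)) {
      cfg2 <- base_config; cfg2$seed <- as.integer(sd); cfg2$weights <- arms[[arm]]
      if (!quiet) message("ablate_losses: stage 2 arm '", arm, "', seed ", sd)
      ck2 <- train_stage2(cohort_dir, ck1, cfg2, quiet = TRUE)
      for (id in ids_test) {
        cs <- read_case(cohort_dir, id)
        pr <- predict_dose(cs, ck1, ck2)
        body <- cs$structures$masks$Body
        rows[[length(rows) + 1]] <- data.frame(
          seed = sd, arm = arm, id = id,
          dose_score = dose_score(pr$refined, cs$dose, body),
          coarse_dose_score = dose_score(pr$coarse, cs$dose, body),
          dvh_score = dvh_score(pr$refined, cs$dose, cs$structures,
                                prescription = rx),
          sndvh_score = sn_dvh_score(pr$refined, cs$dose, cs$structures,
                                     prescription = rx))
      }
    }
  }
  per_run <- do.call(rbind, rows)
  arm_order <- names(arms)
  summ <- do.call(rbind, lapply(arm_order, function(a) {
    g <- per_run[per_run$arm == a, ]
    data.frame(arm = a,
               median_dose_score = stats::median(g$dose_score),
               median_dvh_score = stats::median(g$dvh_score),
               median_sndvh_score = stats::median(g$sndvh_score))
  }))
  # seed-paired comparison of the full composite vs the baseline arm
  base <- stats::aggregate(dose_score ~ seed, data = per_run[per_run$arm == "baseline", ], FUN = stats::median)
  full <- stats::aggregate(dose_score ~ seed, data = per_run[per_run$arm == "band_grad_dvh", ], FUN = stats::median)
  diffs <- full$dose_score - base$dose_score[match(full$seed, base$seed)]
  list(per_run = per_run, summary = summ, stage1 = do.call(rbind, s1rows),
       paired_sign = list(improved = sum(diffs < 0), worsened = sum(diffs > 0),
                          tied = sum(diffs == 0)))
}
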