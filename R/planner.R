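#' Inverse-planning objective
#'
#' One optimization objective tying an ROI and a DVH metric to a goal value.
#' Kinds: `target_min_dvh` (metric must reach at least the goal),
#' `target_uniformity` (target hot-spot metric at most the goal),
#' `oar_max_dvh` (V-metric at most the goal, in %), `oar_mean` (mean dose at
#' most the goal), `oar_max` (maximum dose at most the goal).
#'
#' @param roi ROI name.
#' @param kind objective kind (see above).
#' @param metric DVH metric name the goal refers to.
#' @param goal goal value (> 0; Gy for D-type, % for V-type).
#' @param weight positive penalty weight.
#' @return an `objective` list.
#' @export
objective <- function(roi, kind = c("target_min_dvh", "target_uniformity",
                                    "oar_max_dvh", "oar_mean", "oar_max"),
                      metric, goal, weight = 1) {
  kind <- match.arg(kind)
  vol_metric <- parse_metric(metric)$kind %in% c("Vdose", "Vpct")
  if (goal < 0 || (!vol_metric && goal <= 0))
    stop("objective goal must be > 0 (volume goals may be 0)", call. = FALSE)
  if (weight <= 0) stop("objective weight must be > 0", call. = FALSE)
  structure(list(roi = roi, kind = kind, metric = metric, goal = goal,
                 weight = weight), class = "objective")
}

objective_is_lower_bound <- function(kind) kind == "target_min_dvh"

# threshold dose (Gy) that a metric's goal refers to at the voxel level
metric_threshold <- function(metric, goal, prescription) {
  pm <- parse_metric(metric)
  switch(pm$kind,
    Dpct = , Dmax = , Dmean = goal,
    Vdose = pm$d,
    Vpct = pm$p / 100 * prescription,
    stop("metric '", metric, "' cannot drive the optimizer", call. = FALSE))
}

#' Default planning protocol
#'
#' The mapping from report metrics to objective kinds and weights used when
#' assembling plan-specific objectives from predicted DVH endpoints.
#'
#' @return data.frame with columns `roi`, `metric`, `kind`, `weight`.
#' @export
default_protocol <- function() {
  rbind(
    data.frame(roi = "PTV", metric = "D98%", kind = "target_min_dvh", weight = 60),
    data.frame(roi = "PTV", metric = "D2%", kind = "target_uniformity", weight = 40),
    data.frame(roi = "Bladder", metric = "Dmean", kind = "oar_mean", weight = 2),
    data.frame(roi = "Bladder", metric = "V40", kind = "oar_max_dvh", weight = 1),
    data.frame(roi = "Rectum", metric = "Dmean", kind = "oar_mean", weight = 2),
    data.frame(roi = "Rectum", metric = "V40", kind = "oar_max_dvh", weight = 1),
    data.frame(roi = "SmallIntestine", metric = "Dmean", kind = "oar_mean", weight = 2),
    data.frame(roi = "SpinalCord", metric = "Dmax", kind = "oar_max", weight = 4),
    data.frame(roi = "Marrow", metric = "Dmean", kind = "oar_mean", weight = 0.5),
    data.frame(roi = "FemoralHeadL", metric = "Dmean", kind = "oar_mean", weight = 1),
    data.frame(roi = "FemoralHeadR", metric = "Dmean", kind = "oar_mean", weight = 1))
}

protocol_to_spec <- function(protocol) {
  split_metrics <- split(protocol$metric, protocol$roi)
  split_metrics[unique(protocol$roi)]
}

#' Extract target DVH metrics (M0) from a predicted dose
#'
#' Evaluates each protocol (roi, metric) pair on the refined predicted dose;
#' the result is the goal table the planning loop drives toward.
#'
#' @param refined_dose dose `volume_grid`.
#' @param structures a [structure_set()].
#' @param protocol protocol data.frame (see [default_protocol()]), or an
#'   endpoint spec list (ROI -> metrics) for evaluation-only tables.
#' @param prescription prescription dose (Gy).
#' @return endpoint table data.frame (`roi`, `metric`, `value`, `units`).
#' @export
extract_targets <- function(refined_dose, structures, protocol = default_protocol(),
                            prescription = 45) {
  spec <- if (is.data.frame(protocol)) protocol_to_spec(protocol) else protocol
  endpoint_table(refined_dose, structures, spec, prescription)
}

#' Assemble optimization objectives from a goal table
#'
#' Maps every row of `M0` to one [objective()]: target metrics become lower
#' bounds (or uniformity caps), OAR metrics upper bounds, with kinds and
#' weights taken from the protocol.
#'
#' @param M0 goal endpoint table (from [extract_targets()]).
#' @param protocol protocol data.frame.
#' @return list of `objective`s, one per `M0` row.
#' @export
assemble_objectives <- function(M0, protocol = default_protocol()) {
  lapply(seq_len(nrow(M0)), function(i) {
    row <- M0[i, ]
    j <- which(protocol$roi == row$roi & protocol$metric == row$metric)
    if (length(j) != 1)
      stop("no protocol mapping for ", row$roi, " ", row$metric, call. = FALSE)
    objective(row$roi, protocol$kind[j], row$metric, row$value,
              protocol$weight[j])
  })
}

# one-sided quadratic penalty and its dose-gradient for one objective
objective_penalty <- function(obj, dvec, masks, prescription) {
  idx <- masks[[obj$roi]]
  d <- dvec[idx]
  n <- length(d)
  if (n == 0) # ROI empty on this grid: nothing to penalise
    return(list(f = 0, g = numeric(length(dvec))))
  rx2 <- prescription^2
  g <- numeric(length(dvec))
  t <- metric_threshold(obj$metric, obj$goal, prescription)
  if (obj$kind == "target_min_dvh") {
    u <- pmax(0, t - d)
    f <- sum(u^2) / (n * rx2)
    g[idx] <- -2 * u / (n * rx2)
  } else if (obj$kind %in% c("target_uniformity", "oar_max")) {
    u <- pmax(0, d - t)
    f <- sum(u^2) / (n * rx2)
    g[idx] <- 2 * u / (n * rx2)
  } else if (obj$kind == "oar_mean") {
    u <- max(0, mean(d) - obj$goal)
    f <- u^2 / rx2
    g[idx] <- 2 * u / (n * rx2)
  } else { # oar_max_dvh: V{t} must not exceed goal percent
    q <- obj$goal / 100
    over <- which(d > t)
    excess_frac <- length(over) / n - q
    f <- 0
    if (excess_frac > 0) {
      m <- ceiling(excess_frac * n)
      # penalize the m violating voxels closest to the threshold: pushing
      # them under t restores the volume constraint at least cost
      ord <- over[order(d[over])][seq_len(m)]
      u <- d[ord] - t
      f <- sum(u^2) / (n * rx2)
      gi <- numeric(n)
      gi[ord] <- 2 * u / (n * rx2)
      g[idx] <- gi
    }
  }
  list(f = obj$weight * f, g = obj$weight * g)
}

#' Surrogate inverse optimization over beamlet weights
#'
#' Minimises the weighted sum of one-sided quadratic penalties over
#' non-negative beamlet weights by projected gradient descent with
#' backtracking (monotone, deterministic). This stands in for a clinical
#' TPS optimizer so the planning loop is testable end to end.
#'
#' @param objectives list of [objective()]s.
#' @param structures a [structure_set()].
#' @param geometry beamlet model from [beam_geometry()].
#' @param prescription prescription dose (Gy).
#' @param max_iter gradient iterations (default 200).
#' @param tol relative objective-decrease tolerance for convergence.
#' @param seed unused (the optimizer is deterministic); kept so callers can
#'   thread one seed through the pipeline.
#' @return list with `dose` (`volume_grid`), `weights`, `objective_trace`,
#'   `converged`.
#' @export
optimize_beamlets <- function(objectives, structures, geometry,
                              prescription = 45, max_iter = 200,
                              tol = 1e-5, seed = NULL) {
  if (length(objectives) == 0) stop("no objectives given", call. = FALSE)
  A <- geometry$A
  masks <- lapply(structures$masks, function(m) which(m$values > 0))
  penalty <- function(dvec) {
    f <- 0; g <- numeric(length(dvec))
    for (obj in objectives) {
      p <- objective_penalty(obj, dvec, masks, prescription)
      f <- f + p$f; g <- g + p$g
    }
    list(f = f, g = g)
  }
  nb <- ncol(A)
  # start from uniform weights scaled to put the prescription on the target
  d1 <- as.numeric(A %*% rep(1, nb))
  ptv <- masks$PTV
  scale0 <- prescription / max(mean(d1[ptv]), 1e-9)
  w <- rep(scale0, nb)
  dvec <- as.numeric(A %*% w)
  cur <- penalty(dvec)
  trace <- numeric(max_iter)
  converged <- FALSE
  eta <- NULL
  for (it in seq_len(max_iter)) {
    gw <- as.numeric(Matrix::crossprod(A, cur$g))
    gmax <- max(abs(gw))
    if (gmax == 0) { converged <- TRUE; trace <- trace[1:max(it - 1, 1)]; break }
    # adaptive step: seed from the weight scale, then grow on easy accepts
    if (is.null(eta)) eta <- 0.25 * max(scale0, max(w)) / gmax
    step <- eta; accepted <- FALSE
    for (bt in 1:40) {
      w_new <- pmax(0, w - step * gw)
      d_new <- as.numeric(A %*% w_new)
      nxt <- penalty(d_new)
      if (nxt$f <= cur$f) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; trace <- trace[1:max(it - 1, 1)]; break }
    eta <- if (step == eta) eta * 1.5 else step
    rel <- (cur$f - nxt$f) / max(cur$f, 1e-12)
    w <- w_new; dvec <- d_new; cur <- nxt
    trace[it] <- cur$f
    if (rel < tol) { converged <- TRUE; trace <- trace[1:it]; break }
  }
  # a penalty driven below 0.1% of its starting value counts as solved even
  # if it was still creeping down when the iteration budget ran out
  if (!converged && length(trace) > 0 && cur$f <= 1e-3 * max(trace[1], 1e-12))
    converged <- TRUE
  sh <- geometry$shape
  dose <- volume_grid(array(pmax(dvec, 0), dim = sh), spacing = geometry$spacing,
                      kind = "dose")
  list(dose = dose, weights = w, objective_trace = trace, converged = converged)
}

#' Aggregate goal violation of an achieved plan
#'
#' Sums, over aligned metric rows, the scale-normalised one-sided shortfall
#' of the achieved value `Mc` against the goal `M0`: for lower-bound
#' (target) metrics the deficit below the goal, for upper-bound (OAR)
#' metrics the excess above it. Scales: prescription for D-type metrics,
#' 100 for V-type, 1 otherwise. Zero iff every metric is met.
#'
#' @param Mc,M0 aligned endpoint tables (same roi/metric rows in order).
#' @param kinds character vector of objective kinds aligned with the rows.
#' @param prescription prescription dose (Gy).
#' @return non-negative dimensionless scalar.
#' @export
aggregate_violation <- function(Mc, M0, kinds, prescription = 45) {
  if (nrow(Mc) != nrow(M0) || any(Mc$roi != M0$roi) || any(Mc$metric != M0$metric))
    stop("Mc and M0 tables are not aligned", call. = FALSE)
  if (length(kinds) != nrow(M0))
    stop("need one objective kind per metric row", call. = FALSE)
  sc <- vapply(M0$metric, function(m) {
    k <- parse_metric(m)$kind
    if (k %in% c("Dmax", "Dmean", "Dpct")) prescription
    else if (k %in% c("Vdose", "Vpct")) 100 else 1
  }, numeric(1))
  lower <- objective_is_lower_bound(kinds)
  short <- ifelse(lower, M0$value - Mc$value, Mc$value - M0$value)
  sum(pmax(0, short) / sc)
}

#' DVH-driven iterative plan generation
#'
#' Implements the closed planning loop: optimize against goals assembled
#' from `M0`, compare the achieved metrics `Mc` with `M0`, and for every
#' unmet metric tighten only that objective's working goal by the step
#' fraction (lower-bound goals multiplied by `1 + step`, upper-bound goals
#' by `1 - step`), then re-optimize. The loop stops as soon as all metrics
#' are met, and never runs more than `max_iter` iterations; the retained
#' iteration minimises the aggregate violation (ties broken toward the
#' earliest iteration).
#'
#' @param M0 goal endpoint table (see [extract_targets()]).
#' @param structures a [structure_set()].
#' @param geometry beamlet model from [beam_geometry()].
#' @param protocol protocol data.frame mapping rows to objective kinds.
#' @param max_iter iteration cap (default 5).
#' @param step goal adjustment fraction per iteration (default 0.02).
#' @param met_tol scale-normalised tolerance under which a metric counts as
#'   met (default 0.002, i.e. 0.09 Gy at 45 Gy or 0.2 percentage points).
#' @param prescription prescription dose (Gy).
#' @param optimizer_args extra arguments passed to [optimize_beamlets()].
#' @return a `plan_result`: `iterations` (goals, weights, `Mc`, violation,
#'   per-metric `met`), `retained` index, `dose` of the retained iteration,
#'   `M0`, and a `failed` flag if the optimizer aborted mid-loop.
#' @export
iterate_plan <- function(M0, structures, geometry, protocol = default_protocol(),
                         max_iter = 5, step = 0.02, met_tol = 0.002,
                         prescription = 45, optimizer_args = list()) {
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  kinds <- vapply(seq_len(nrow(M0)), function(i) {
    j <- which(protocol$roi == M0$roi[i] & protocol$metric == M0$metric[i])
    if (length(j) != 1)
      stop("no protocol mapping for ", M0$roi[i], " ", M0$metric[i], call. = FALSE)
    protocol$kind[j]
  }, character(1))
  weights <- vapply(seq_len(nrow(M0)), function(i) {
    j <- which(protocol$roi == M0$roi[i] & protocol$metric == M0$metric[i])
    protocol$weight[j]
  }, numeric(1))
  sc <- vapply(M0$metric, function(m) {
    k <- parse_metric(m)$kind
    if (k %in% c("Dmax", "Dmean", "Dpct")) prescription
    else if (k %in% c("Vdose", "Vpct")) 100 else 1
  }, numeric(1))
  lower <- objective_is_lower_bound(kinds)
  goals <- M0$value
  spec <- stats::setNames(split(M0$metric, M0$roi)[unique(M0$roi)], unique(M0$roi))
  iterations <- list()
  failed <- FALSE
  for (it in seq_len(max_iter)) {
    objs <- lapply(seq_len(nrow(M0)), function(i)
      objective(M0$roi[i], kinds[i], M0$metric[i], goals[i], weights[i]))
    fit <- tryCatch(
      do.call(optimize_beamlets,
              c(list(objs, structures, geometry, prescription = prescription),
                optimizer_args)),
      error = function(e) e)
    if (inherits(fit, "error")) { failed <- TRUE; break }
    Mc <- endpoint_table(fit$dose, structures, spec, prescription)
    Mc <- Mc[match(paste(M0$roi, M0$metric), paste(Mc$roi, Mc$metric)), ]
    short <- ifelse(lower, M0$value - Mc$value, Mc$value - M0$value) / sc
    met <- short <= met_tol
    viol <- aggregate_violation(Mc, M0, kinds, prescription)
    iterations[[it]] <- list(index = it, goals = goals, weights = fit$weights,
                             dose = fit$dose, Mc = Mc, met = met,
                             aggregate_violation = viol)
    if (all(met)) break
    # tighten only the unmet goals toward M0's intent
    goals[!met & lower] <- goals[!met & lower] * (1 + step)
    goals[!met & !lower] <- goals[!met & !lower] * (1 - step)
  }
  if (length(iterations) == 0)
    stop("optimizer failed before completing any iteration", call. = FALSE)
  viols <- vapply(iterations, `[[`, numeric(1), "aggregate_violation")
  retained <- which.min(viols) # which.min takes the earliest tie
  structure(list(iterations = iterations, retained = retained,
                 dose = iterations[[retained]]$dose, M0 = M0, kinds = kinds,
                 failed = failed),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("<plan_result> %d iteration(s), retained #%d (violation %.4g)%s\n",
              length(x$iterations), x$retained,
              x$iterations[[x$retained]]$aggregate_violation,
              if (isTRUE(x$failed)) " [optimizer failure flagged]" else ""))
  invisible(x)
}

#' Write a plan result to disk
#'
#' Per-iteration goals/violations and the retained index as JSON, plus the
#' retained dose as NIfTI.
#'
#' @param x a `plan_result`.
#' @param dir output directory.
#' @export
write_plan_result <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    retained = x$retained, failed = isTRUE(x$failed),
    iterations = lapply(x$iterations, function(it)
      list(index = it$index, goals = it$goals,
           aggregate_violation = it$aggregate_violation, met = it$met)))
  jsonlite::write_json(meta, file.path(dir, "plan.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_volume(x$dose, file.path(dir, "plan_dose.nii.gz"))
  invisible(dir)
}
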