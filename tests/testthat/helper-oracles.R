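# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's code paths (and stats::quantile):
# endpoints come from an explicit sort-and-interpolate, gamma from a
# vectorised exhaustive search.

# dose to the hottest p% of the ROI: linear interpolation between order
# statistics of the sorted voxel doses (position h = (n-1)q + 1)
oracle_dpct <- function(doses, p) {
  x <- sort(doses)
  n <- length(x)
  if (n == 1) return(x)
  q <- 1 - p / 100
  h <- (n - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_endpoint <- function(dose_vals, mask_vals, metric, rx = 45) {
  d <- dose_vals[mask_vals > 0]
  if (metric == "Dmax") return(max(d))
  if (metric == "Dmean") return(sum(d) / length(d))
  if (metric == "HI")
    return((oracle_dpct(d, 2) - oracle_dpct(d, 98)) / oracle_dpct(d, 50))
  if (metric == "CI") {
    piv <- sum(dose_vals >= rx); tv <- length(d); tvpiv <- sum(d >= rx)
    return(if (piv == 0) 0 else tvpiv^2 / (tv * piv))
  }
  if (grepl("^D.*%$", metric))
    return(oracle_dpct(d, as.numeric(sub("^D(.*)%$", "\\1", metric))))
  if (grepl("^V.*%$", metric)) {
    p <- as.numeric(sub("^V(.*)%$", "\\1", metric))
    return(100 * sum(d >= p / 100 * rx) / length(d))
  }
  thr <- as.numeric(sub("^V", "", metric))
  100 * sum(d >= thr) / length(d)
}

# exhaustive global gamma: every displacement on the 3x refined grid within
# radius 3*dta, evaluated dose trilinearly interpolated, no early exit
oracle_gamma_pass <- function(ref, eval, spacing, dd_percent = 3, dta = 3,
                              low = 0.1) {
  dims <- dim(ref)
  rmax <- max(ref)
  dd_abs <- dd_percent / 100 * rmax
  steps <- spacing / 3
  nn <- floor(3 * dta / steps)
  offs <- expand.grid(a = -nn[1]:nn[1], b = -nn[2]:nn[2], c = -nn[3]:nn[3])
  offs$ry <- offs$a * steps[1]; offs$rx <- offs$b * steps[2]
  offs$rz <- offs$c * steps[3]
  offs$r2 <- offs$ry^2 + offs$rx^2 + offs$rz^2
  offs <- offs[offs$r2 <= (3 * dta)^2, ]
  idx <- which(ref >= low * rmax, arr.ind = TRUE)
  interp <- function(i, j, k) {
    # clamped trilinear sample of eval at fractional 0-based offsets
    i <- pmin(pmax(i, 1), dims[1]); j <- pmin(pmax(j, 1), dims[2])
    k <- pmin(pmax(k, 1), dims[3])
    i0 <- pmin(floor(i), dims[1] - 1); j0 <- pmin(floor(j), dims[2] - 1)
    k0 <- pmin(floor(k), dims[3] - 1)
    fi <- i - i0; fj <- j - j0; fk <- k - k0
    val <- 0
    for (ci in 0:1) for (cj in 0:1) for (ck in 0:1) {
      w <- (if (ci) fi else 1 - fi) * (if (cj) fj else 1 - fj) *
        (if (ck) fk else 1 - fk)
      val <- val + w * eval[cbind(i0 + ci, j0 + cj, k0 + ck)]
    }
    val
  }
  g2 <- rep(Inf, nrow(idx))
  for (o in seq_len(nrow(offs))) {
    ev <- interp(idx[, 1] + offs$ry[o] / spacing[1],
                 idx[, 2] + offs$rx[o] / spacing[2],
                 idx[, 3] + offs$rz[o] / spacing[3])
    cand <- (ev - ref[idx])^2 / dd_abs^2 + offs$r2[o] / dta^2
    g2 <- pmin(g2, cand)
  }
  100 * mean(sqrt(g2) <= 1)
}
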