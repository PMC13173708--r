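rand_case <- function(seed, dims = c(8, 8, 8)) {
  set.seed(seed)
  list(p = array(runif(prod(dims)), dims),
       r = array(runif(prod(dims)), dims),
       body = array(1, dims),
       union = array(rbinom(prod(dims), 1, 0.5), dims))
}

test_that("every loss term is zero on identical inputs and non-negative", {
  cs <- rand_case(1)
  masks <- list(A = cs$union, B = cs$body)
  expect_equal(loss_body(cs$p, cs$p, cs$body), 0)
  expect_equal(loss_band(cs$p, cs$p, cs$union), 0)
  expect_equal(loss_grad(cs$p, cs$p, cs$union), 0)
  expect_equal(loss_dvh(cs$p, cs$p, masks), 0)
  expect_gte(loss_body(cs$p, cs$r, cs$body), 0)
  expect_gte(loss_grad(cs$p, cs$r, cs$union), 0)
  expect_gte(loss_dvh(cs$p, cs$r, masks), 0)
})

test_that("losses match closed forms on constant offsets and ramps", {
  cs <- rand_case(2)
  # constant offset c: MAE terms give c, the gradient term gives 0
  off <- cs$p + 0.25
  expect_equal(loss_body(off, cs$p, cs$body), 0.25, tolerance = 1e-12)
  expect_equal(loss_band(off, cs$p, cs$union), 0.25, tolerance = 1e-12)
  expect_equal(loss_grad(off, cs$p, cs$union), 0, tolerance = 1e-12)
  # MAE matches a naive loop oracle
  acc <- 0
  for (v in seq_along(cs$p)) acc <- acc + abs(cs$p[v] - cs$r[v])
  expect_equal(loss_body(cs$p, cs$r, cs$body), acc / length(cs$p),
               tolerance = 1e-12)
  # error concentrated outside the union contributes nothing to L_band
  outside <- cs$p
  outside[cs$union == 0] <- outside[cs$union == 0] + 5
  expect_equal(loss_band(outside, cs$p, cs$union), 0)
  # union == body makes L_band coincide with L_body
  expect_equal(loss_band(cs$p, cs$r, cs$body), loss_body(cs$p, cs$r, cs$body))
  # linear ramp vs flat: gradient magnitude = slope along that axis
  dims <- c(8, 8, 8); h <- c(2, 3, 4)
  ramp <- array(rep(0.05 * (1:8), times = 64), dims) # slope 0.05 per voxel axis 1
  flat <- array(0, dims)
  interior <- array(0, dims); interior[2:7, 2:7, 2:7] <- 1
  got <- loss_grad(ramp, flat, interior, spacing = h)
  expect_equal(got, 0.05 / h[1], tolerance = 1e-12)
})

test_that("temperature -> 0 recovers the hard DVH distance on a toy case", {
  dims <- c(4, 4, 2)
  p <- array(0, dims); r <- array(0, dims)
  p[1:2] <- c(0.40, 0.50); r[1:2] <- c(0.45, 0.55)
  roi <- array(0, dims); roi[1:2] <- 1
  bins <- seq(0, 1, by = 0.01)
  soft <- loss_dvh(p, r, list(ROI = roi), temperature = 1e-3, bin_grid = bins)
  # hard cumulative curves: mean over bins of |mean(p >= b) - mean(r >= b)|
  hp <- vapply(bins, function(b) mean(p[roi > 0] >= b), numeric(1))
  hr <- vapply(bins, function(b) mean(r[roi > 0] >= b), numeric(1))
  expect_equal(soft, mean(abs(hp - hr)), tolerance = 1e-3)
})

test_that("analytic gradients of all loss terms pass finite differences", {
  cs <- rand_case(3)
  masks <- list(A = cs$union, B = cs$body)
  spacing <- c(2, 2, 4)
  checks <- list(
    list(f = function(p) loss_body(p, cs$r, cs$body),
         g = arcdose:::grad_loss_body(cs$p, cs$r, cs$body)),
    list(f = function(p) loss_band(p, cs$r, cs$union),
         g = arcdose:::grad_loss_band(cs$p, cs$r, cs$union)),
    list(f = function(p) loss_grad(p, cs$r, cs$union, spacing),
         g = arcdose:::grad_loss_grad(cs$p, cs$r, cs$union, spacing)),
    list(f = function(p) loss_dvh(p, cs$r, masks, temperature = 0.05),
         g = arcdose:::grad_loss_dvh(cs$p, cs$r, masks, temperature = 0.05)))
  set.seed(4)
  for (ch in checks) {
    idx <- sample(length(cs$p), 12)
    eps <- 1e-6
    for (v in idx) {
      pp <- cs$p; pp[v] <- pp[v] + eps
      pm <- cs$p; pm[v] <- pm[v] - eps
      num <- (ch$f(pp) - ch$f(pm)) / (2 * eps)
      ana <- ch$g[v]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-4)
    }
  }
})

test_that("the composite objective is a weighted sum, linear in each lambda", {
  ph <- small_phantom()
  dims <- dim(ph$ct$values)
  set.seed(5)
  pred <- volume_grid(array(runif(prod(dims), 0, 50), dims) *
                        ph$structures$masks$Body$values,
                      spacing = ph$ct$spacing, kind = "dose")
  ref <- forward_dose(ph$structures, rep(2, 4), c(0, 45, 90, 135))
  bands <- make_band_set(ph$structures$masks$PTV, k = 4)
  body <- ph$structures$masks$Body
  lb1 <- total_loss(pred, ref, body, bands, ph$structures,
                    loss_weights(1, 0, 0, 0))
  expect_equal(lb1$l_total, lb1$l_body)
  lb <- total_loss(pred, ref, body, bands, ph$structures,
                   loss_weights(0.5, 2, 3, 0.25))
  expect_equal(lb$l_total,
               0.5 * lb$l_body + 2 * lb$l_band + 3 * lb$l_grad + 0.25 * lb$l_dvh,
               tolerance = 1e-12)
  # doubling one lambda moves the total by exactly that component
  lb2 <- total_loss(pred, ref, body, bands, ph$structures,
                    loss_weights(0.5, 2, 6, 0.25))
  expect_equal(lb2$l_total - lb$l_total, 3 * lb$l_grad, tolerance = 1e-12)
  # identical inputs: zero for any weights
  z <- total_loss(ref, ref, body, bands, ph$structures,
                  loss_weights(1, 2, 3, 4))
  expect_equal(z$l_total, 0)
  expect_error(loss_weights(0, 0, 0, 0), "at least one")
  expect_error(loss_weights(-1, 1, 1, 1), ">= 0")
})

test_that("the composite gradient matches finite differences", {
  dims <- c(8, 8, 8)
  cs <- rand_case(6, dims)
  structures <- list(A = cs$union, B = cs$body)
  bands <- cs$union
  w <- loss_weights(1, 1, 1, 1)
  lb <- total_loss(cs$p, cs$r, cs$body, bands, structures, w,
                   prescription = 1, spacing = c(1, 1, 1), gradient = TRUE)
  set.seed(7)
  f <- function(p) total_loss(p, cs$r, cs$body, bands, structures, w,
                              prescription = 1, spacing = c(1, 1, 1))$l_total
  for (v in sample(length(cs$p), 8)) {
    eps <- 1e-6
    pp <- cs$p; pp[v] <- pp[v] + eps
    pm <- cs$p; pm[v] <- pm[v] - eps
    num <- (f(pp) - f(pm)) / (2 * eps)
    expect_lt(abs(num - lb$gradient[v]) / max(abs(num), 1e-6), 1e-4)
  }
})
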