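tiny_cfg <- function(seed = 1L) train_config(epochs = 2, width = 4, seed = seed)

test_that("networks obey their shape and determinism contracts", {
  cfg <- tiny_cfg()
  dims <- c(16, 16, 8); N <- prod(dims)
  net1 <- build_net(cfg, 10, stage = 1)
  net1b <- build_net(cfg, 10, stage = 1)
  expect_identical(net1$layers, net1b$layers) # same seed, same init
  X <- matrix(rnorm(10 * N), 10, N)
  fw <- arcdose:::net_forward(net1, X, dims)
  expect_equal(dim(fw$z), c(1, N))
  expect_true(all(arcdose:::softplus(fw$z) >= 0))
  # repeated forward passes identical
  expect_identical(fw$z, arcdose:::net_forward(net1, X, dims)$z)
  # channel mismatch is caught explicitly
  expect_error(arcdose:::net_forward(net1, X[1:9, ], dims), "channel-count")
  # parameter count stable across builds
  expect_identical(net_num_params(net1), net_num_params(net1b))
})

test_that("non-divisible grids are rejected with a fix hint", {
  cfg <- tiny_cfg()
  net <- build_net(cfg, 10, stage = 1)
  X <- matrix(0, 10, 15 * 16 * 8)
  expect_error(arcdose:::net_forward(net, X, c(15, 16, 8)), "multiples of 4")
})

test_that("stage 2 starts exactly at the coarse dose (zero-init residual head)", {
  cfg <- tiny_cfg()
  dims <- c(16, 16, 8); N <- prod(dims)
  net2 <- build_net(cfg, 15, stage = 2)
  X <- matrix(rnorm(15 * N), 15, N)
  fw <- arcdose:::net_forward(net2, X, dims)
  expect_true(all(fw$z == 0)) # correction is identically zero at init
  coarse <- runif(N)
  refined <- pmax(coarse + as.numeric(fw$z), 0)
  expect_equal(refined, coarse)
})

test_that("backprop through both architectures matches finite differences", {
  cfg <- tiny_cfg(5L)
  dims <- c(8, 8, 4); N <- prod(dims)
  set.seed(7)
  for (stage in 1:2) {
    inch <- if (stage == 1) 10 else 15
    net <- build_net(cfg, inch, stage)
    fin <- net$layers$final # randomise the head so gradients flow everywhere
    net <- arcdose:::set_layer_wb(net, c("final", NA),
                                  matrix(rnorm(length(fin$W)), nrow(fin$W)),
                                  rnorm(1))
    X <- matrix(rnorm(inch * N), inch, N)
    R <- matrix(rnorm(N), 1, N)
    fw <- arcdose:::net_forward(net, X, dims)
    grads <- arcdose:::net_backward(net, fw, R)
    blocks <- list(c("enc1", "a"), c("enc2", "b"), c("bott", "a"),
                   c("dec2", "b"), c("dec1", "a"), c("final", NA))
    if (stage == 2) blocks <- c(blocks, list(c("dec2", "proj")))
    for (id in blocks) {
      ly <- arcdose:::get_layer(net, id)
      gr <- arcdose:::get_grad(grads, id)
      set.seed(11)
      for (rep in 1:3) {
        i <- sample(nrow(ly$W), 1); j <- sample(ncol(ly$W), 1)
        eps <- 1e-6
        f <- function(w) {
          n2 <- arcdose:::set_layer_wb(net, id, `[<-`(ly$W, i, j, w), ly$b)
          sum(arcdose:::net_forward(n2, X, dims)$z * R)
        }
        num <- (f(ly$W[i, j] + eps) - f(ly$W[i, j] - eps)) / (2 * eps)
        expect_lt(abs(num - gr$GW[i, j]) / max(abs(num), abs(gr$GW[i, j]), 1e-8),
                  1e-5)
      }
    }
  }
})

test_that("short training runs are deterministic and reduce the loss", {
  dir <- file.path(tempdir(), "cohort-tiny")
  if (!file.exists(file.path(dir, "manifest.json"))) {
    cfg <- phantom_config(shape = c(16, 16, 16), spacing = c(10, 10, 10),
                          seed = 21)
    generate_cohort(3, cfg, dir)
  }
  tc <- train_config(epochs = 3, width = 4, seed = 2)
  ck <- train_stage1(dir, tc, quiet = TRUE)
  ck_b <- train_stage1(dir, tc, quiet = TRUE)
  expect_identical(ck$history, ck_b$history) # same seed, same trajectory
  expect_lt(ck$history$train_mae_gy[3], ck$history$train_mae_gy[1])
  # stage 2 runs and keeps the checkpoint contract
  tc2 <- train_config(epochs = 2, width = 4, seed = 2)
  ck2 <- train_stage2(dir, ck, tc2, quiet = TRUE)
  expect_s3_class(ck2, "checkpoint")
  expect_identical(ck2$stage, 2L)
  # checkpoint round trip gives identical predictions
  cs <- read_case(dir, "case001")
  f <- tempfile(fileext = ".ckpt")
  write_checkpoint(ck2, f)
  ck2r <- read_checkpoint(f)
  p1 <- predict_dose(cs, ck, ck2)
  p2 <- predict_dose(cs, ck, ck2r)
  expect_identical(p1$refined$values, p2$refined$values)
  # prediction contracts: grid preserved, zero outside body, deterministic
  expect_identical(dim(p1$refined$values), dim(cs$ct$values))
  body <- cs$structures$masks$Body$values
  expect_true(all(p1$refined$values[body == 0] == 0))
  expect_true(all(p1$coarse$values >= 0))
  p3 <- predict_dose(cs, ck, ck2)
  expect_identical(p1$refined$values, p3$refined$values)
})

test_that("stage-2 training with only the body term reduces to MAE refinement", {
  dir <- file.path(tempdir(), "cohort-tiny")
  tc <- train_config(epochs = 1, width = 4, seed = 3,
                     weights = loss_weights(1, 0, 0, 0))
  ck1 <- train_stage1(dir, train_config(epochs = 1, width = 4, seed = 3),
                      quiet = TRUE)
  ck2 <- train_stage2(dir, ck1, tc, quiet = TRUE)
  # the logged training loss must equal the pure body-MAE component
  cs <- arcdose:::load_training_case(dir, "case001", tc)
  coarse <- matrix(as.numeric(arcdose:::predict_case_norm(ck1, cs$X1, cs$dims)), 1)
  X2 <- stack_channels(cs$ct, cs$structures, coarse_norm = coarse,
                       bands = cs$bands)
  fw <- arcdose:::net_forward(ck2$net, X2, cs$dims)
  refined <- pmax(as.numeric(coarse) + as.numeric(fw$z), 0)
  lb <- total_loss(array(refined, cs$dims), array(cs$ref_norm, cs$dims),
                   cs$body, cs$bands, cs$structures, tc$weights,
                   prescription = 1, spacing = cs$spacing)
  expect_equal(lb$l_total, lb$l_body)
  expect_equal(lb$l_band + lb$l_grad + lb$l_dvh, 0)
})
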