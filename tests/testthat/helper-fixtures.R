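# Shared fixtures, built once per test session and cached in a session
# tempdir. All fixtures are generated in code; nothing is stored on disk in
# the repository.

.fixture_env <- new.env(parent = emptyenv())

fixture_dir <- function() {
  if (is.null(.fixture_env$dir)) {
    .fixture_env$dir <- file.path(tempdir(), "arcdose-fixtures")
    dir.create(.fixture_env$dir, showWarnings = FALSE, recursive = TRUE)
  }
  .fixture_env$dir
}

# desk-scale study grid: 32x32x16 voxels at (5, 5, 10) mm
small_config <- function(seed = 11L) {
  phantom_config(shape = c(32, 32, 16), spacing = c(5, 5, 10), seed = seed)
}

small_phantom <- function(seed = 11L) {
  key <- paste0("phantom", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_phantom(small_config(seed))
  .fixture_env[[key]]
}

# 10-case cohort with reference plans; used by the training tests
small_cohort <- function() {
  dir <- file.path(fixture_dir(), "cohort10")
  if (!file.exists(file.path(dir, "manifest.json")))
    generate_cohort(10, small_config(11L), dir)
  dir
}

# Stage-1 checkpoint trained for 20 epochs on the small cohort, per seed
stage1_checkpoint <- function(seed = 1L, epochs = 20L) {
  key <- paste0("ck1_", seed, "_", epochs)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- train_stage1(
      small_cohort(), train_config(epochs = epochs, width = 8, seed = seed),
      quiet = TRUE)
  .fixture_env[[key]]
}

# loss-term ablation over 3 seeds (Stage-1 20 epochs, Stage-2 8 epochs,
# width 8), shared by the cascade-learning checks
cascade_ablation <- function() {
  if (is.null(.fixture_env$ablation))
    .fixture_env$ablation <- ablate_losses(
      small_cohort(), train_config(epochs = 8, width = 8),
      seeds = 1:3, stage1_epochs = 20, quiet = TRUE)
  .fixture_env$ablation
}

# random smooth dose pair for gamma tests: sum of Gaussian blobs
random_smooth_dose_pair <- function(seed, dims = c(14, 14, 8),
                                    spacing = c(4, 4, 6)) {
  set.seed(seed)
  co <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                    k = seq_len(dims[3]))
  mk <- function(nblob, amp_sd) {
    v <- numeric(nrow(co))
    for (b in seq_len(nblob)) {
      c0 <- c(runif(1, 4, dims[1] - 3), runif(1, 4, dims[2] - 3),
              runif(1, 2, dims[3] - 1))
      sig <- runif(1, 2, 4)
      v <- v + runif(1, 20, 50) *
        exp(-((co$i - c0[1])^2 + (co$j - c0[2])^2 + (co$k - c0[3])^2) /
              (2 * sig^2))
    }
    array(v, dim = dims)
  }
  ref <- mk(3)
  eval <- ref * (1 + 0.02 * array(sin(co$i / 2) * cos(co$j / 3), dims)) +
    0.6 * mk(2) / 10
  list(ref = volume_grid(ref, spacing = spacing, kind = "dose"),
       eval = volume_grid(pmax(eval, 0), spacing = spacing, kind = "dose"))
}

random_mask_slice <- function(seed, n = 24) {
  set.seed(seed)
  m <- matrix(0, n, n)
  cy <- runif(1, 8, n - 8); cx <- runif(1, 8, n - 8)
  ry <- runif(1, 2, 6); rx <- runif(1, 2, 6); th <- runif(1, 0, pi)
  for (i in 1:n) for (j in 1:n) {
    u <- (i - cy) * cos(th) + (j - cx) * sin(th)
    v <- -(i - cy) * sin(th) + (j - cx) * cos(th)
    if ((u / ry)^2 + (v / rx)^2 <= 1) m[i, j] <- 1
  }
  m
}
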