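#' Training configuration for the cascaded dose networks
#'
#' Both stages share one encoder-decoder topology: depth 3 (two 2x2x2
#' average-pooling levels) with 3x3x3 convolutions and skip connections.
#' Stage 1 maps 10 input channels (CT + 9 structure masks) to a coarse
#' normalized dose through a softplus output; Stage 2 consumes 15 channels
#' (CT + masks + coarse dose + 4 band masks), uses residual blocks, and
#' predicts a correction added to the coarse dose (clipped at zero), so a
#' zero-initialised final layer starts exactly at the coarse dose.
#'
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param seed integer seed fixing initialisation and data order.
#' @param width base channel width (doubles at each depth level).
#' @param depth encoder depth; only 3 is implemented.
#' @param k_bands number of band-mask channels for Stage 2.
#' @param weights a [loss_weights()] for the Stage-2 composite objective.
#' @param temperature,bin_grid soft-DVH parameters (see [loss_dvh()]).
#' @param prescription dose normalisation constant (Gy).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 20, lr = 1e-3, seed = 1L, width = 16,
                         depth = 3, k_bands = 4, weights = loss_weights(),
                         temperature = 0.02,
                         bin_grid = seq(0, 1.2, length.out = 25),
                         prescription = 45) {
  if (depth != 3) stop("only depth 3 is implemented", call. = FALSE)
  if (width < 2) stop("width must be >= 2", call. = FALSE)
  structure(list(epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
                 width = as.integer(width), depth = 3L,
                 k_bands = as.integer(k_bands), weights = weights,
                 temperature = temperature, bin_grid = bin_grid,
                 prescription = prescription),
            class = "train_config")
}

check_grid_divisible <- function(dims) {
  if (any(dims %% 4 != 0))
    stop("grid dims (", paste(dims, collapse = "x"), ") must be multiples of 4 ",
         "for the two pooling levels; pad or resample the volume ",
         "(e.g. resample_volume()) to multiples of 4", call. = FALSE)
}

he_init <- function(c_out, c_in, k = 27) {
  matrix(stats::rnorm(c_out * k * c_in, 0, sqrt(2 / (k * c_in))), c_out, k * c_in)
}

conv_layer <- function(c_in, c_out, zero = FALSE, k = 27) {
  list(W = if (zero) matrix(0, c_out, k * c_in) else he_init(c_out, c_in, k),
       b = numeric(c_out), c_in = c_in, c_out = c_out, k = k)
}

# block = two 3x3x3 convs (+ optional 1x1 projection shortcut for residual)
make_block <- function(c_in, c_out, res) {
  bl <- list(a = conv_layer(c_in, c_out), b = conv_layer(c_out, c_out))
  if (res && c_in != c_out) bl$proj <- conv_layer(c_in, c_out, k = 1)
  bl
}

#' Build a dose-prediction network
#'
#' @param config a [train_config()].
#' @param in_channels number of input channels (10 for Stage 1, 15 for
#'   Stage 2).
#' @param stage 1 (plain U-Net, softplus dose output) or 2 (residual
#'   blocks, zero-initialised linear correction output).
#' @return a `dose_net` list of parameters; two builds under the same seed
#'   are identical.
#' @export
build_net <- function(config, in_channels, stage = 1) {
  w <- config$width
  res <- stage == 2
  with_seed(config$seed, {
    net <- list(
      enc1 = make_block(in_channels, w, res),
      enc2 = make_block(w, 2 * w, res),
      bott = make_block(2 * w, 4 * w, res),
      dec2 = make_block(6 * w, 2 * w, res),
      dec1 = make_block(3 * w, w, res),
      final = conv_layer(w, 1, zero = res, k = 1))
    structure(list(layers = net, in_channels = in_channels, width = w,
                   stage = stage, res = res), class = "dose_net")
  })
}

#' @param config a [train_config()].
#' @rdname build_net
#' @export
build_stage1 <- function(config) build_net(config, in_channels = 10, stage = 1)

#' @rdname build_net
#' @export
build_stage2 <- function(config)
  build_net(config, in_channels = 11L + config$k_bands, stage = 2)

#' @export
print.dose_net <- function(x, ...) {
  cat(sprintf("<dose_net> stage %d, %d input channels, width %d, %d parameters\n",
              x$stage, x$in_channels, x$width, net_num_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net a `dose_net`.
#' @export
net_num_params <- function(net) {
  sum(unlist(rapply(net$layers, function(z) length(z), classes = c("matrix", "numeric"),
                    how = "unlist")))
}

conv_f <- function(X, ly, dims) {
  if (nrow(X) != ly$c_in)
    stop("channel-count mismatch: layer expects ", ly$c_in, " channels, got ",
         nrow(X), call. = FALSE)
  if (ly$k == 1) ly$W %*% X + ly$b
  else cpp_conv3d_forward(X, ly$W, ly$b, dims[1], dims[2], dims[3])
}

conv_b <- function(X, ly, GY, dims) {
  if (ly$k == 1) {
    list(GX = crossprod(ly$W, GY), GW = tcrossprod(GY, X), Gb = rowSums(GY))
  } else {
    gp <- cpp_conv3d_bwd_params(X, GY, dims[1], dims[2], dims[3])
    list(GX = cpp_conv3d_bwd_input(ly$W, GY, dims[1], dims[2], dims[3], ly$c_in),
         GW = gp$GW, Gb = as.numeric(gp$Gb))
  }
}

relu <- function(x) { x[x < 0] <- 0; x }

block_f <- function(X, bl, dims, res) {
  if (!res) {
    H1 <- relu(conv_f(X, bl$a, dims))
    Y <- relu(conv_f(H1, bl$b, dims))
    list(Y = Y, X = X, H1 = H1)
  } else {
    H1 <- relu(conv_f(X, bl$a, dims))
    H2 <- conv_f(H1, bl$b, dims)
    S <- if (!is.null(bl$proj)) conv_f(X, bl$proj, dims) else X
    Y <- relu(H2 + S)
    list(Y = Y, X = X, H1 = H1)
  }
}

block_b <- function(cache, bl, GY, dims, res) {
  GY <- GY * (cache$Y > 0)
  g <- list()
  if (!res) {
    bb <- conv_b(cache$H1, bl$b, GY, dims)
    g$b <- bb[c("GW", "Gb")]
    GH1 <- bb$GX * (cache$H1 > 0)
    ba <- conv_b(cache$X, bl$a, GH1, dims)
    g$a <- ba[c("GW", "Gb")]
    GX <- ba$GX
  } else {
    bb <- conv_b(cache$H1, bl$b, GY, dims)
    g$b <- bb[c("GW", "Gb")]
    GH1 <- bb$GX * (cache$H1 > 0)
    ba <- conv_b(cache$X, bl$a, GH1, dims)
    g$a <- ba[c("GW", "Gb")]
    if (!is.null(bl$proj)) {
      bp <- conv_b(cache$X, bl$proj, GY, dims)
      g$proj <- bp[c("GW", "Gb")]
      GX <- ba$GX + bp$GX
    } else GX <- ba$GX + GY
  }
  g$GX <- GX
  g
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Full forward pass. X: C x N matrix; dims: grid shape.
# Returns the 1 x N network head output z plus all caches.
net_forward <- function(net, X, dims) {
  check_grid_divisible(dims)
  L <- net$layers; res <- net$res
  d1 <- dims; d2 <- dims / 2; d3 <- dims / 4
  c_e1 <- block_f(X, L$enc1, d1, res)
  P1 <- cpp_avgpool(c_e1$Y, d1[1], d1[2], d1[3])
  c_e2 <- block_f(P1, L$enc2, d2, res)
  P2 <- cpp_avgpool(c_e2$Y, d2[1], d2[2], d2[3])
  c_bt <- block_f(P2, L$bott, d3, res)
  U2 <- cpp_upsample(c_bt$Y, d3[1], d3[2], d3[3])
  c_d2 <- block_f(rbind(U2, c_e2$Y), L$dec2, d2, res)
  U1 <- cpp_upsample(c_d2$Y, d2[1], d2[2], d2[3])
  c_d1 <- block_f(rbind(U1, c_e1$Y), L$dec1, d1, res)
  z <- conv_f(c_d1$Y, L$final, d1)
  list(z = z, caches = list(e1 = c_e1, e2 = c_e2, bt = c_bt, d2 = c_d2,
                            d1 = c_d1), dims = dims)
}

# Backward from gradient at the head output z; returns per-layer grads.
net_backward <- function(net, fw, Gz) {
  L <- net$layers; res <- net$res
  dims <- fw$dims; d1 <- dims; d2 <- dims / 2; d3 <- dims / 4
  ca <- fw$caches
  g <- list()
  bf <- conv_b(ca$d1$Y, L$final, Gz, d1)
  g$final <- bf[c("GW", "Gb")]
  bd1 <- block_b(ca$d1, L$dec1, bf$GX, d1, res)
  g$dec1 <- bd1[c("a", "b", "proj")]
  nu1 <- nrow(ca$d2$Y) # channels of U1 == channels of dec2 output
  GU1 <- bd1$GX[seq_len(nu1), , drop = FALSE]
  GE1_skip <- bd1$GX[-seq_len(nu1), , drop = FALSE]
  GD2 <- cpp_upsample_bwd(GU1, d2[1], d2[2], d2[3])
  bd2 <- block_b(ca$d2, L$dec2, GD2, d2, res)
  g$dec2 <- bd2[c("a", "b", "proj")]
  nu2 <- nrow(ca$bt$Y)
  GU2 <- bd2$GX[seq_len(nu2), , drop = FALSE]
  GE2_skip <- bd2$GX[-seq_len(nu2), , drop = FALSE]
  GB <- cpp_upsample_bwd(GU2, d3[1], d3[2], d3[3])
  bbt <- block_b(ca$bt, L$bott, GB, d3, res)
  g$bott <- bbt[c("a", "b", "proj")]
  GP2 <- cpp_avgpool_bwd(bbt$GX, d2[1], d2[2], d2[3])
  be2 <- block_b(ca$e2, L$enc2, GP2 + GE2_skip, d2, res)
  g$enc2 <- be2[c("a", "b", "proj")]
  GP1 <- cpp_avgpool_bwd(be2$GX, d1[1], d1[2], d1[3])
  be1 <- block_b(ca$e1, L$enc1, GP1 + GE1_skip, d1, res)
  g$enc1 <- be1[c("a", "b", "proj")]
  g
}

# flatten/unflatten parameter lists for the optimizer
param_names <- function(net) {
  out <- list()
  for (bn in names(net$layers)) {
    bl <- net$layers[[bn]]
    if (bn == "final") { out[[length(out) + 1]] <- c(bn, NA) ; next }
    for (cn in intersect(c("a", "b", "proj"), names(bl)))
      out[[length(out) + 1]] <- c(bn, cn)
  }
  out
}

get_layer <- function(net, id)
  if (is.na(id[2])) net$layers[[id[1]]] else net$layers[[id[1]]][[id[2]]]

get_grad <- function(grads, id)
  if (is.na(id[2])) grads[[id[1]]] else grads[[id[1]]][[id[2]]]

set_layer_wb <- function(net, id, W, b) {
  if (is.na(id[2])) { net$layers[[id[1]]]$W <- W; net$layers[[id[1]]]$b <- b }
  else { net$layers[[id[1]]][[id[2]]]$W <- W; net$layers[[id[1]]][[id[2]]]$b <- b }
  net
}

adam_init <- function(net) {
  st <- list(t = 0)
  for (id in param_names(net)) {
    ly <- get_layer(net, id)
    key <- paste(id[1], id[2], sep = ".")
    st[[key]] <- list(mW = ly$W * 0, vW = ly$W * 0,
                      mb = ly$b * 0, vb = ly$b * 0)
  }
  st
}

adam_step <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (id in param_names(net)) {
    key <- paste(id[1], id[2], sep = ".")
    ly <- get_layer(net, id); gr <- get_grad(grads, id)
    if (is.null(gr)) next
    s <- st[[key]]
    s$mW <- beta1 * s$mW + (1 - beta1) * gr$GW
    s$vW <- beta2 * s$vW + (1 - beta2) * gr$GW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * gr$Gb
    s$vb <- beta2 * s$vb + (1 - beta2) * gr$Gb^2
    W <- ly$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    b <- ly$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    st[[key]] <- s
    net <- set_layer_wb(net, id, W, b)
  }
  list(net = net, state = st)
}

# ---- case tensors -----------------------------------------------------------

ct_normalize <- function(ct_vals) (pmin(pmax(ct_vals, -1000), 1000) + 1000) / 2000

#' Assemble the multi-channel network input for one case
#'
#' Stage 1: CT (clipped to \[-1000, 1000\] HU and scaled to \[0, 1\]) plus
#' the nine structure masks, 10 channels. Stage 2 appends the
#' prescription-normalized coarse dose and the k band masks (15 channels at
#' the default k = 4).
#'
#' @param ct CT `volume_grid`.
#' @param structures a [structure_set()].
#' @param coarse_norm optional normalized coarse-dose array (Stage 2).
#' @param bands optional `band_mask_set` (Stage 2).
#' @return channels-by-voxels matrix.
#' @export
stack_channels <- function(ct, structures, coarse_norm = NULL, bands = NULL) {
  N <- prod(dim(ct$values))
  chans <- list(as.numeric(ct_normalize(ct$values)))
  for (nm in canonical_rois())
    chans[[length(chans) + 1]] <- as.numeric(structures$masks[[nm]]$values)
  if (!is.null(coarse_norm)) {
    chans[[length(chans) + 1]] <- as.numeric(coarse_norm)
    for (b in bands$bands) chans[[length(chans) + 1]] <- as.numeric(b$values)
  }
  t(matrix(unlist(chans), N, length(chans)))
}

load_training_case <- function(dir, id, config) {
  cs <- read_case(dir, id)
  dims <- dim(cs$ct$values)
  bands <- make_band_set(cs$structures$masks$PTV, k = config$k_bands)
  list(id = id, dims = dims, spacing = cs$ct$spacing,
       ct = cs$ct, structures = cs$structures,
       X1 = stack_channels(cs$ct, cs$structures),
       ref = cs$dose, ref_norm = cs$dose$values / config$prescription,
       body = cs$structures$masks$Body, bands = bands)
}

#' Train the Stage-1 coarse dose network
#'
#' Minimises the body-restricted MAE on prescription-normalized dose with
#' Adam (batch size 1, shuffled case order per epoch, all randomness under
#' `config$seed`). The checkpoint with the best validation MAE is retained.
#'
#' @param cohort_dir cohort directory from [generate_cohort()].
#' @param config a [train_config()].
#' @param quiet suppress per-epoch logging.
#' @return a `checkpoint` list: `net`, `config`, `stage`, `history`
#'   (per-epoch train/val MAE in Gy), `best_epoch`.
#' @export
train_stage1 <- function(cohort_dir, config = train_config(), quiet = FALSE) {
  man <- read_manifest(cohort_dir)
  ids_tr <- man$cases$id[man$cases$split == "train"]
  ids_va <- man$cases$id[man$cases$split == "val"]
  if (length(ids_tr) == 0 || length(ids_va) == 0)
    stop("cohort needs non-empty train and val splits", call. = FALSE)
  cases_tr <- lapply(ids_tr, load_training_case, dir = cohort_dir, config = config)
  cases_va <- lapply(ids_va, load_training_case, dir = cohort_dir, config = config)
  net <- build_net(config, in_channels = 10, stage = 1)
  opt <- adam_init(net)
  rx <- config$prescription
  history <- data.frame()
  best <- list(val = Inf, net = net, epoch = 0L)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(cases_tr))
      tr_mae <- 0
      for (ci in ord) {
        cs <- cases_tr[[ci]]
        fw <- net_forward(net, cs$X1, cs$dims)
        pred <- softplus(fw$z)
        bvec <- as.numeric(cs$body$values) > 0
        err <- as.numeric(pred) - as.numeric(cs$ref_norm)
        l <- mean(abs(err[bvec]))
        if (!is.finite(l))
          stop("NaN/Inf loss at epoch ", ep, ", case ", cs$id,
               "; lower the learning rate", call. = FALSE)
        tr_mae <- tr_mae + l
        gpred <- matrix(0, 1, length(err))
        gpred[1, bvec] <- sign(err[bvec]) / sum(bvec)
        gz <- gpred * stats::plogis(fw$z) # softplus chain
        grads <- net_backward(net, fw, gz)
        upd <- adam_step(net, grads, opt, config$lr)
        net <- upd$net; opt <- upd$state
      }
      va_mae <- mean(vapply(cases_va, function(cs) {
        fw <- net_forward(net, cs$X1, cs$dims)
        pred <- as.numeric(softplus(fw$z))
        bvec <- as.numeric(cs$body$values) > 0
        mean(abs(pred[bvec] - as.numeric(cs$ref_norm)[bvec]))
      }, numeric(1)))
      history <- rbind(history, data.frame(
        epoch = ep, train_mae_gy = rx * tr_mae / length(cases_tr),
        val_mae_gy = rx * va_mae))
      if (va_mae < best$val) best <- list(val = va_mae, net = net, epoch = ep)
      if (!quiet)
        message(sprintf("stage1 epoch %2d  train MAE %.3f Gy  val MAE %.3f Gy",
                        ep, rx * tr_mae / length(cases_tr), rx * va_mae))
    }
  })
  structure(list(net = best$net, config = config, stage = 1L,
                 history = history, best_epoch = best$epoch),
            class = "checkpoint")
}

predict_case_norm <- function(ckpt, X, dims) {
  fw <- net_forward(ckpt$net, X, dims)
  if (ckpt$stage == 1) softplus(fw$z) else fw$z
}

#' Train the Stage-2 refinement network
#'
#' The Stage-1 network stays frozen; its coarse predictions (and the band
#' masks, computed once per case) condition a residual ResU-Net trained
#' with the composite objective of [total_loss()]. Setting all weights but
#' `lambda_body` to zero reduces training to plain MAE refinement.
#'
#' @param cohort_dir cohort directory.
#' @param stage1_ckpt Stage-1 `checkpoint`.
#' @param config a [train_config()]; `config$weights` selects the ablation
#'   arm.
#' @param quiet suppress per-epoch logging.
#' @return a `checkpoint` with the best-validation Stage-2 network.
#' @export
train_stage2 <- function(cohort_dir, stage1_ckpt, config = train_config(),
                         quiet = FALSE) {
  stopifnot(inherits(stage1_ckpt, "checkpoint"), stage1_ckpt$stage == 1L)
  man <- read_manifest(cohort_dir)
  ids_tr <- man$cases$id[man$cases$split == "train"]
  ids_va <- man$cases$id[man$cases$split == "val"]
  prep <- function(id) {
    cs <- load_training_case(cohort_dir, id, config)
    cs$coarse <- matrix(as.numeric(predict_case_norm(stage1_ckpt, cs$X1, cs$dims)),
                        1)
    cs$X2 <- stack_channels(cs$ct, cs$structures, coarse_norm = cs$coarse,
                            bands = cs$bands)
    cs
  }
  cases_tr <- lapply(ids_tr, prep)
  cases_va <- lapply(ids_va, prep)
  net <- build_net(config, in_channels = 11L + config$k_bands, stage = 2)
  opt <- adam_init(net)
  rx <- config$prescription
  history <- data.frame()
  best <- list(val = Inf, net = net, epoch = 0L)
  case_loss <- function(cs, net, gradient = FALSE) {
    fw <- net_forward(net, cs$X2, cs$dims)
    pre <- as.numeric(cs$coarse) + as.numeric(fw$z)
    refined <- pmax(pre, 0)
    lb <- total_loss(array(refined, cs$dims), array(cs$ref_norm, cs$dims),
                     cs$body, cs$bands, cs$structures, config$weights,
                     prescription = 1, spacing = cs$spacing,
                     temperature = config$temperature,
                     bin_grid = config$bin_grid, gradient = gradient)
    if (gradient) {
      gz <- matrix(as.numeric(lb$gradient) * (pre > 0), 1)
      list(loss = lb$l_total, fw = fw, gz = gz)
    } else lb$l_total
  }
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(cases_tr))
      tr_loss <- 0
      for (ci in ord) {
        cs <- cases_tr[[ci]]
        cl <- case_loss(cs, net, gradient = TRUE)
        if (!is.finite(cl$loss))
          stop("NaN/Inf loss at epoch ", ep, ", case ", cs$id, call. = FALSE)
        tr_loss <- tr_loss + cl$loss
        grads <- net_backward(net, cl$fw, cl$gz)
        upd <- adam_step(net, grads, opt, config$lr)
        net <- upd$net; opt <- upd$state
      }
      va_loss <- mean(vapply(cases_va, case_loss, numeric(1), net = net))
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = tr_loss / length(cases_tr), val_loss = va_loss))
      if (va_loss < best$val) best <- list(val = va_loss, net = net, epoch = ep)
      if (!quiet)
        message(sprintf("stage2 epoch %2d  train loss %.5f  val loss %.5f",
                        ep, tr_loss / length(cases_tr), va_loss))
    }
  })
  structure(list(net = best$net, config = config, stage = 2L,
                 history = history, best_epoch = best$epoch),
            class = "checkpoint")
}

#' @export
print.checkpoint <- function(x, ...) {
  cat(sprintf("<checkpoint> stage %d, best epoch %d/%d, %d parameters\n",
              x$stage, x$best_epoch, nrow(x$history), net_num_params(x$net)))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' Single-file archive with the embedded training configuration.
#'
#' @param ckpt a `checkpoint`.
#' @param path file path.
#' @export
write_checkpoint <- function(ckpt, path) { saveRDS(ckpt, path); invisible(path) }

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)

#' Predict coarse and refined dose for one case
#'
#' Runs the frozen Stage-1 network, then (when a Stage-2 checkpoint is
#' given) the refinement network conditioned on the band masks. Doses are
#' returned de-normalized in Gy and zeroed outside the body. Inference is
#' deterministic.
#'
#' @param case list with `ct`, `structures` (and optionally `dose`), e.g.
#'   from [read_case()].
#' @param stage1_ckpt Stage-1 `checkpoint`.
#' @param stage2_ckpt optional Stage-2 `checkpoint`.
#' @return list with `coarse` and (if refined) `refined` dose
#'   `volume_grid`s.
#' @export
predict_dose <- function(case, stage1_ckpt, stage2_ckpt = NULL) {
  ct <- case$ct; structures <- case$structures
  dims <- dim(ct$values)
  rx <- stage1_ckpt$config$prescription
  X1 <- stack_channels(ct, structures)
  coarse_n <- as.numeric(predict_case_norm(stage1_ckpt, X1, dims))
  body <- as.numeric(structures$masks$Body$values) > 0
  mk_dose <- function(v) {
    v[!body] <- 0
    volume_grid(array(v, dims), spacing = ct$spacing, origin = ct$origin,
                kind = "dose")
  }
  out <- list(coarse = mk_dose(coarse_n * rx))
  if (!is.null(stage2_ckpt)) {
    cfg2 <- stage2_ckpt$config
    bands <- make_band_set(structures$masks$PTV, k = cfg2$k_bands)
    X2 <- stack_channels(ct, structures, coarse_norm = coarse_n, bands = bands)
    z <- as.numeric(predict_case_norm(stage2_ckpt, X2, dims))
    refined_n <- pmax(coarse_n + z, 0)
    out$refined <- mk_dose(refined_n * cfg2$prescription)
  }
  out
}
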