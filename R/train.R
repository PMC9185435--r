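## Mask-free self-supervised training.

#' Training configuration
#'
#' Defaults follow the published protocol where one is stated — batch size
#' 64, initial learning rate 0.03, rectified-Adam optimization with
#' exponential learning-rate decay, adaptive loss with `lambda = 10`,
#' rotation/mirror augmentation — and engineering choices elsewhere (patch
#' size 64, decay rate 0.9 every 2000 steps); every field is recorded in the
#' checkpoint for provenance.
#'
#' @param steps Number of optimization steps.
#' @param batch_size Patches per step.
#' @param patch_size Square patch side in pixels.
#' @param initial_lr Initial learning rate.
#' @param decay_rate,decay_interval Exponential decay:
#'   `lr(step) = initial_lr * decay_rate^(step / decay_interval)` with a
#'   continuous exponent.
#' @param loss A [loss_spec()].
#' @param augment Apply a random dihedral transform to every sampled patch.
#' @param mode `"self_supervised"` (targets are the noisy patches
#'   themselves) or `"supervised_baseline"` (targets are clean patches; use
#'   with a full-kernel [net_spec()] for the supervised reference).
#' @param seed Seed controlling initialization order of the patch stream.
#' @return A `train_config` list.
#' @export
train_config <- function(steps = 2000L, batch_size = 64L, patch_size = 64L,
                         initial_lr = 0.03, decay_rate = 0.9,
                         decay_interval = 2000L,
                         loss = loss_spec("adss", lambda = 10),
                         augment = TRUE,
                         mode = c("self_supervised", "supervised_baseline"),
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(steps >= 0L, batch_size >= 1L, patch_size >= 1L,
            initial_lr > 0, decay_rate > 0, decay_interval >= 1L,
            inherits(loss, "loss_spec"))
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size), initial_lr = initial_lr,
                 decay_rate = decay_rate,
                 decay_interval = as.integer(decay_interval),
                 loss = loss, augment = isTRUE(augment), mode = mode,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a step
#'
#' Continuous exponential decay
#' `initial_lr * rate^(step / interval)`.
#'
#' @param step Step counter >= 0.
#' @param initial_lr Initial learning rate.
#' @param decay_rate,decay_interval Decay constants.
#' @return Learning rate.
#' @export
lr_at <- function(step, initial_lr = 0.03, decay_rate = 0.9,
                  decay_interval = 2000L) {
  stopifnot(step >= 0)
  initial_lr * decay_rate^(step / decay_interval)
}

#' Random patch stream with dihedral augmentation
#'
#' Returns a closure; each call produces one batch as a list of
#' `(patch_size, patch_size, batch_size, 1)` arrays `noisy` and `clean`
#' (aligned crops, so the supervised baseline can reuse the stream). Each
#' patch is an independent uniform crop of a random image; when `augment`
#' is on, one of the 8 dihedral transforms (uniformly chosen) is applied to
#' both members of the pair. The stream keeps its own RNG state, so batches
#' are reproducible from `seed` and insensitive to other randomness in the
#' session.
#'
#' @param noisy_images List of noisy image matrices.
#' @param clean_images Optional list of aligned clean matrices (defaults to
#'   the noisy list, which self-supervised training never reads).
#' @param patch_size,batch_size Patch geometry.
#' @param augment Apply random dihedral transforms.
#' @param seed Stream seed.
#' @return Function of no arguments returning
#'   `list(noisy = array, clean = array)`.
#' @export
make_patch_stream <- function(noisy_images, clean_images = NULL, patch_size,
                              batch_size, augment = TRUE, seed = 1L) {
  if (!is.list(noisy_images)) noisy_images <- list(noisy_images)
  if (is.null(clean_images)) clean_images <- noisy_images
  if (!is.list(clean_images)) clean_images <- list(clean_images)
  stopifnot(length(clean_images) == length(noisy_images))
  for (i in seq_along(noisy_images)) {
    if (nrow(noisy_images[[i]]) < patch_size ||
        ncol(noisy_images[[i]]) < patch_size) {
      stop(sprintf("image %d (%d x %d) is smaller than patch_size %d",
                   i, nrow(noisy_images[[i]]), ncol(noisy_images[[i]]),
                   patch_size), call. = FALSE)
    }
  }
  rng_state <- with_preserved_rng({
    set.seed(as.integer(seed))
    get(".Random.seed", envir = globalenv())
  })
  function() {
    with_preserved_rng({
      assign(".Random.seed", rng_state, envir = globalenv())
      noisy <- array(0, c(patch_size, patch_size, batch_size, 1L))
      clean <- array(0, c(patch_size, patch_size, batch_size, 1L))
      for (b in seq_len(batch_size)) {
        i <- sample.int(length(noisy_images), 1L)
        H <- nrow(noisy_images[[i]]); W <- ncol(noisy_images[[i]])
        y0 <- sample.int(H - patch_size + 1L, 1L)
        x0 <- sample.int(W - patch_size + 1L, 1L)
        pn <- noisy_images[[i]][y0:(y0 + patch_size - 1L),
                                x0:(x0 + patch_size - 1L)]
        pc <- clean_images[[i]][y0:(y0 + patch_size - 1L),
                                x0:(x0 + patch_size - 1L)]
        if (augment) {
          k <- sample.int(8L, 1L) - 1L
          pn <- apply_dihedral(pn, k)
          pc <- apply_dihedral(pc, k)
        }
        noisy[, , b, 1L] <- pn
        clean[, , b, 1L] <- pc
      }
      rng_state <<- get(".Random.seed", envir = globalenv())
      list(noisy = noisy, clean = clean)
    })
  }
}

## ---- rectified Adam --------------------------------------------------------
## Standard rectified-adaptive-moment update: bias-corrected first moment
## always; the adaptive (second-moment) rescaling is switched on only once
## the variance-rectification term is defined (rho_t > 4), with the
## closed-form rectification factor r_t.

radam_init <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
       rho_inf = 2 / (1 - 0.999) - 1)
}

radam_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1L
  t <- state$t
  b1 <- state$beta1; b2 <- state$beta2
  rho_t <- state$rho_inf - 2 * t * b2^t / (1 - b2^t)
  use_adaptive <- rho_t > 4
  r_t <- if (use_adaptive) {
    sqrt(((rho_t - 4) * (rho_t - 2) * state$rho_inf) /
           ((state$rho_inf - 4) * (state$rho_inf - 2) * rho_t))
  } else NA_real_
  for (nm in names(params)) {
    for (slot in c("W", "b")) {
      gslot <- if (slot == "W") grads[[nm]]$dW else grads[[nm]]$db
      m <- b1 * state$m[[nm]][[slot]] + (1 - b1) * gslot
      v <- b2 * state$v[[nm]][[slot]] + (1 - b2) * gslot^2
      state$m[[nm]][[slot]] <- m
      state$v[[nm]][[slot]] <- v
      mhat <- m / (1 - b1^t)
      upd <- if (use_adaptive) {
        vhat <- sqrt(v / (1 - b2^t)) + state$eps
        lr * r_t * mhat / vhat
      } else {
        lr * mhat
      }
      params[[nm]][[slot]] <- params[[nm]][[slot]] - upd
    }
  }
  list(state = state, params = params)
}

net_params <- function(net) lapply(net$layers, function(l) l[c("W", "b")])
net_set_params <- function(net, params) {
  for (nm in names(params)) {
    net$layers[[nm]]$W <- params[[nm]]$W
    net$layers[[nm]]$b <- params[[nm]]$b
  }
  net
}

#' Train a denoiser
#'
#' Runs `config$steps` optimization steps of the configured loss on random
#' augmented patches. In self-supervised mode the target of every step is
#' the noisy batch itself — no masking, no clean data; the architecture's
#' J-invariance is what prevents collapse to the identity map. In
#' supervised-baseline mode the aligned clean patches are the targets. The
#' run aborts with a diagnostic if the loss becomes non-finite. Fixed seeds
#' give a bit-stable loss trace on one machine.
#'
#' @param net A `denoiser` from [build_network()].
#' @param config A [train_config()].
#' @param noisy_images List of noisy training matrices.
#' @param clean_images Aligned clean matrices; required for
#'   `mode = "supervised_baseline"`, ignored otherwise.
#' @return A `checkpoint`: list with the trained `net`, `config`, `step`,
#'   and the per-step `loss_trace`.
#' @export
train <- function(net, config, noisy_images, clean_images = NULL) {
  stopifnot(inherits(net, "denoiser"), inherits(config, "train_config"))
  supervised <- config$mode == "supervised_baseline"
  if (supervised && is.null(clean_images)) {
    stop("supervised_baseline mode requires `clean_images`", call. = FALSE)
  }
  stream <- make_patch_stream(noisy_images, clean_images,
                              patch_size = config$patch_size,
                              batch_size = config$batch_size,
                              augment = config$augment,
                              seed = config$seed)
  params <- net_params(net)
  opt <- radam_init(params)
  trace <- numeric(config$steps)
  for (step in seq_len(config$steps)) {
    batch <- stream()
    target <- if (supervised) batch$clean else batch$noisy
    net <- net_set_params(net, params)
    fw <- net_forward(net, batch$noisy, cache = TRUE)
    lval <- loss_eval(fw$y, target, config$loss)
    if (!is.finite(lval)) {
      stop(sprintf("training diverged at step %d (loss = %g)", step, lval),
           call. = FALSE)
    }
    trace[step] <- lval
    gy <- loss_grad(fw$y, target, config$loss)
    bk <- net_backward(net, fw, gy)
    lr <- lr_at(step - 1L, config$initial_lr, config$decay_rate,
                config$decay_interval)
    res <- radam_step(opt, params, bk$grads, lr)
    opt <- res$state
    params <- res$params
  }
  net <- net_set_params(net, params)
  structure(list(net = net, config = config, step = config$steps,
                 loss_trace = trace, format_version = 1L),
            class = "checkpoint")
}

#' @export
print.checkpoint <- function(x, ...) {
  cat(sprintf("<checkpoint> step %d, final loss %s\n", x$step,
              if (x$step > 0) format(utils::tail(x$loss_trace, 1)) else "NA"))
  print(x$net$spec)
  invisible(x)
}

#' Save / load a checkpoint
#'
#' Checkpoints round-trip losslessly (architecture spec, parameters,
#' training configuration, step counter and loss trace) through RDS
#' serialization; the format version travels with the file.
#'
#' @param ckpt A `checkpoint`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "checkpoint")) stop("not a checkpoint file", call. = FALSE)
  ckpt
}
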