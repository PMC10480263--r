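#' Training configuration
#'
#' Optimisation constants of the adversarial training loop. The
#' generator objective is the conditional adversarial loss plus
#' `l1_weight` times the mean absolute error on the unit intensity
#' scale; both networks use Adam with momentum `beta1`. Batch size is 1.
#'
#' @param epochs number of passes over the training pairs (>= 1).
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decays.
#' @param l1_weight weight of the L1 reconstruction term (>= 0).
#' @param batch_size only 1 is supported.
#' @param seed integer seed governing initialisation, data order and
#'   dropout.
#' @param checkpoint_every,checkpoint_dir optional checkpointing: every
#'   `checkpoint_every` epochs the model is serialised into
#'   `checkpoint_dir`.
#' @param verbose print per-epoch losses.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 200, learning_rate = 2e-4, beta1 = 0.5,
                         beta2 = 0.999, l1_weight = 100, batch_size = 1,
                         seed = 1L, checkpoint_every = NULL,
                         checkpoint_dir = NULL, verbose = FALSE) {
  if (epochs < 1) stop("'epochs' must be >= 1")
  if (l1_weight < 0) stop("'l1_weight' must be >= 0")
  if (batch_size != 1) stop("only batch_size = 1 is supported")
  structure(as.list(environment()), class = "train_config")
}

#' Transfer-learning configuration
#'
#' @param n_trainable_param_layers number of final parameterised
#'   (weight-bearing) generator layers to retrain; default 2 (the last
#'   decoder normalisation and the terminal convolution).
#' @param epochs transfer epochs (>= 0; 0 returns the base weights
#'   untouched).
#' @inheritParams train_config
#' @return list of class `transfer_config`.
#' @export
transfer_config <- function(n_trainable_param_layers = 2L, epochs = 500,
                            learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                            l1_weight = 100, seed = 1L, verbose = FALSE) {
  if (epochs < 0) stop("'epochs' must be >= 0")
  if (n_trainable_param_layers < 1)
    stop("'n_trainable_param_layers' must be >= 1")
  structure(as.list(environment()), class = "transfer_config")
}

bce_with_logits <- function(z, target) {
  mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
}

check_pairs <- function(pairs) {
  if (length(pairs) == 0L) stop("at least one training pair is required")
  d <- dim(pairs[[1]]$input_img)
  for (p in pairs) {
    if (!identical(dim(p$input_img), d) || !identical(dim(p$target_img), d))
      stop("all pairs must share image dimensions")
  }
  d
}

as_chan <- function(m) array(m, c(nrow(m), ncol(m), 1L))

apply_out_act <- function(z, act) if (act == "tanh") tanh(z) else z

# One full adversarial training run over `pairs`, starting from the given
# generator/discriminator. Returns updated networks and per-epoch history.
gan_train <- function(G, D, pairs, epochs, lr, beta1, beta2, l1_weight,
                      seed, verbose = FALSE, checkpoint_every = NULL,
                      checkpoint_dir = NULL, label = "model") {
  set.seed(derive_seed(seed, "train"))
  act <- G$spec$output_activation %||% "tanh"
  n <- length(pairs)
  hist <- data.frame(epoch = integer(0), d_loss = numeric(0),
                     g_adv = numeric(0), g_l1 = numeric(0))
  norm_pairs <- lapply(pairs, function(p)
    list(x = as_chan(normalize_hu(p$input_img)),
         y = as_chan(normalize_hu(p$target_img))))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    dl <- ga <- gl <- 0
    for (k in ord) {
      x <- norm_pairs[[k]]$x
      y <- norm_pairs[[k]]$y
      d <- dim(x)
      fwG <- net_forward(G, x, training = TRUE)
      fake <- apply_out_act(fwG$out, act)

      # discriminator step: real pair up, fake pair down
      real_in <- array(c(x, y), c(d[1], d[2], 2L))
      fake_in <- array(c(x, fake), c(d[1], d[2], 2L))
      fwDr <- net_forward(D, real_in, training = TRUE)
      fwDf <- net_forward(D, fake_in, training = TRUE)
      zr <- fwDr$out; zf <- fwDf$out
      loss_d <- 0.5 * (bce_with_logits(zr, 1) + bce_with_logits(zf, 0))
      npat <- length(zr)
      bwr <- net_backward(D, fwDr, (1 / (1 + exp(-zr)) - 1) / npat)
      bwf <- net_backward(D, fwDf, (1 / (1 + exp(-zf))) / npat)
      D <- adam_update(D, combine_grads(bwr$grads, bwf$grads),
                       lr, beta1, beta2)

      # generator step against the updated discriminator
      fwDg <- net_forward(D, fake_in, training = TRUE)
      zg <- fwDg$out
      loss_adv <- bce_with_logits(zg, 1)
      bwDg <- net_backward(D, fwDg, (1 / (1 + exp(-zg)) - 1) / length(zg))
      dfake_adv <- array(bwDg$dx[, , 2], c(d[1], d[2], 1L))
      resid <- fake - y
      loss_l1 <- mean(abs(resid))
      dfake <- dfake_adv + l1_weight * sign(resid) / length(resid)
      dz <- if (act == "tanh") dfake * (1 - fake^2) else dfake
      bwG <- net_backward(G, fwG, dz)
      G <- adam_update(G, bwG$grads, lr, beta1, beta2)

      if (!is.finite(loss_d) || !is.finite(loss_adv) || !is.finite(loss_l1))
        stop(sprintf(paste0("non-finite loss at epoch %d (d=%.4g, adv=%.4g, ",
                            "l1=%.4g); lower the learning rate"),
                     ep, loss_d, loss_adv, loss_l1))
      dl <- dl + loss_d; ga <- ga + loss_adv; gl <- gl + loss_l1
    }
    hist <- rbind(hist, data.frame(epoch = ep, d_loss = dl / n,
                                   g_adv = ga / n, g_l1 = gl / n))
    if (verbose)
      message(sprintf("epoch %3d  d %.4f  g_adv %.4f  g_l1 %.4f",
                      ep, dl / n, ga / n, gl / n))
    if (!is.null(checkpoint_every) && !is.null(checkpoint_dir) &&
        ep %% checkpoint_every == 0) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(list(generator = G, discriminator = D, epoch = ep),
              file.path(checkpoint_dir,
                        sprintf("%s_epoch%04d.rds", label, ep)))
    }
  }
  list(G = G, D = D, history = hist)
}

#' Fit a conditional adversarial image-translation model
#'
#' Trains a pix2pix-style conditional GAN on paired slices: the
#' generator maps the input image (e.g. a partial, streaked CBCT slice)
#' to the target (e.g. the clean CT), while a patch discriminator judges
#' (input, candidate) pairs. Updates alternate one discriminator and one
#' generator Adam step per pair, with generator loss
#' `adversarial + l1_weight * L1` on the `[-1, 1]` intensity scale.
#' Runs are reproducible from `config$seed` (single-threaded).
#'
#' @param pairs list of `paired_sample` objects (or lists with
#'   `input_img` / `target_img` matrices of common size).
#' @param spec a [generator_spec()]; by default derived from the image
#'   size (desk profile below 256 px).
#' @param config a [train_config()].
#' @param label model label carried into reports.
#' @return object of class `pix2pix` with components `generator`,
#'   `discriminator`, `history`, `spec`, `config`, `label`. Methods:
#'   `print`, `summary`, `predict`, `plot`.
#' @export
pix2pix <- function(pairs, spec = NULL, config = train_config(),
                    label = "pix2pix") {
  d <- check_pairs(pairs)
  if (d[1] != d[2]) stop("training images must be square")
  if (is.null(spec)) {
    spec <- if (d[1] < 256) desk_generator_spec(d[1])
            else generator_spec(input_size = d[1])
  }
  if (spec$input_size != d[1])
    stop("generator spec input_size does not match the training images")
  G <- build_generator(spec, seed = config$seed)
  D <- build_discriminator(spec$input_size,
                           base_filters = max(8L, spec$base_filters %/% 2L),
                           seed = config$seed)
  fit <- gan_train(G, D, pairs, epochs = config$epochs,
                   lr = config$learning_rate, beta1 = config$beta1,
                   beta2 = config$beta2, l1_weight = config$l1_weight,
                   seed = config$seed, verbose = config$verbose,
                   checkpoint_every = config$checkpoint_every,
                   checkpoint_dir = config$checkpoint_dir, label = label)
  structure(list(generator = fit$G, discriminator = fit$D,
                 history = fit$history, spec = spec, config = config,
                 label = label),
            class = "pix2pix")
}

#' Patient-specific transfer learning
#'
#' Produces a variation of a trained base model by retraining only the
#' final `n_trainable_param_layers` parameterised generator layers (by
#' topological order; with the default 2, the last decoder batch
#' normalisation and the terminal convolution) on a single patient's
#' pairs. All other generator parameters are frozen and come out
#' bit-identical; the base model object is not modified. The patch
#' discriminator continues to adapt during the transfer run, as the
#' frozen layers belong to the generator network.
#'
#' @param base a fitted [pix2pix()] model.
#' @param pairs nonempty list of paired samples for the target patient.
#' @param config a [transfer_config()].
#' @param label label for the resulting model.
#' @return a new `pix2pix` object.
#' @export
transfer_learn <- function(base, pairs, config = transfer_config(),
                           label = "patient-specific model") {
  if (!inherits(base, "pix2pix")) stop("'base' must be a pix2pix model")
  check_pairs(pairs)
  G <- set_trainable_last(base$generator, config$n_trainable_param_layers)
  G$opt <- NULL  # fresh optimiser state for the transfer run
  D <- base$discriminator
  D$opt <- NULL
  if (config$epochs == 0) {
    fit <- list(G = G, D = D,
                history = data.frame(epoch = integer(0), d_loss = numeric(0),
                                     g_adv = numeric(0), g_l1 = numeric(0)))
  } else {
    fit <- gan_train(G, D, pairs, epochs = config$epochs,
                     lr = config$learning_rate, beta1 = config$beta1,
                     beta2 = config$beta2, l1_weight = config$l1_weight,
                     seed = config$seed, verbose = config$verbose,
                     label = label)
  }
  structure(list(generator = fit$G, discriminator = fit$D,
                 history = fit$history, spec = base$spec, config = config,
                 label = label),
            class = "pix2pix")
}

infer_slice <- function(model, img) {
  act <- model$spec$output_activation %||% "tanh"
  fw <- net_forward(model$generator, as_chan(normalize_hu(img)),
                    training = FALSE)
  out <- apply_out_act(fw$out, act)
  .clamp_hu(denormalize_hu(matrix(out, nrow(img), ncol(img))))
}

#' Run a fitted model on new slices or volumes
#'
#' Normalises intensities, runs the generator (dropout off), maps back
#' to HU and clamps to `[-1024, 3071]`. Dimensions are preserved;
#' volumes are processed slice-wise in order.
#'
#' @param object a `pix2pix` model.
#' @param newdata a matrix (one slice), a list of matrices, or a
#'   [ct_volume()].
#' @param ... unused.
#' @return same shape as `newdata` (a `ct_volume` in, a `ct_volume` out).
#' @export
predict.pix2pix <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(infer_slice(object, newdata))
  if (inherits(newdata, "ct_volume")) {
    out <- lapply(newdata$slices, infer_slice, model = object)
    return(ct_volume(out, slice_thickness = newdata$slice_thickness,
                     patient_id = paste0(newdata$patient_id, "-sct")))
  }
  if (is.list(newdata)) return(lapply(newdata, infer_slice, model = object))
  stop("'newdata' must be a matrix, list of matrices, or ct_volume")
}

#' @export
print.pix2pix <- function(x, ...) {
  cat(sprintf("<pix2pix> %s\n", x$label))
  cat(sprintf("  generator: %d layers (%d parameterised, %d trainable), input %dx%d\n",
              length(x$generator$layers),
              length(param_layer_indices(x$generator)),
              length(trainable_param_layers(x$generator)),
              x$spec$input_size, x$spec$input_size))
  if (nrow(x$history))
    cat(sprintf("  trained %d epoch(s); final losses d %.4f, g_adv %.4f, g_l1 %.4f\n",
                max(x$history$epoch), utils::tail(x$history$d_loss, 1),
                utils::tail(x$history$g_adv, 1),
                utils::tail(x$history$g_l1, 1)))
  invisible(x)
}

#' @export
summary.pix2pix <- function(object, ...) {
  net <- object$generator
  idx <- seq_along(net$layers)
  kinds <- generator_layer_kinds(net)
  nparam <- vapply(net$layers, function(ly) {
    if (!is_param_layer(ly)) return(0L)
    if (ly$kind == "batchnorm") 2L * length(ly$gamma)
    else length(ly$w) + length(ly$b)
  }, integer(1))
  trainable <- vapply(net$layers, function(ly)
    isTRUE(ly$trainable), logical(1))
  out <- data.frame(layer = idx, kind = kinds, n_params = nparam,
                    trainable = ifelse(nparam > 0, trainable, NA))
  class(out) <- c("summary.pix2pix", "data.frame")
  out
}

#' @export
plot.pix2pix <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::matplot(h$epoch, cbind(h$d_loss, h$g_adv, h$g_l1), type = "l",
                    lty = 1, xlab = "epoch", ylab = "loss",
                    main = x$label, ...)
  graphics::legend("topright", c("discriminator", "generator adv",
                                 "generator L1"), col = 1:3, lty = 1)
  invisible(x)
}
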