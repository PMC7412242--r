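#' Architecture descriptors for the 1D convolutional autoencoders
#'
#' Two families map a 640-sample PPG window to a 640-sample ABP window:
#' \describe{
#'   \item{LDCAE}{LeNet-5-style encoder/decoder without skip connections;
#'     encoder filter ladder 16 -> 32 -> 64.}
#'   \item{UDCAE}{U-Net-style network whose decoder concatenates each
#'     encoder level's feature map before convolving; ladder
#'     32 -> 64 -> 128 -> 256.}
#' }
#' Every hidden convolution uses same padding and ReLU activation
#' (\eqn{f(X)=\max(0,X)}); each encoder level except the bottleneck is
#' followed by factor-2 max pooling, mirrored by factor-2 nearest-neighbour
#' upsampling in the decoder; the output head is a single-filter linear
#' convolution. Kernel sizes (11 for LDCAE, 3 for UDCAE) were chosen so the
#' realized parameter counts (56,833 and 323,457) land in the intended
#' "about sixty thousand" / "about three hundred thousand" bands.
#'
#' @param family \code{"ldcae"} or \code{"udcae"}.
#' @param input_len window length in samples; must be divisible by
#'   \code{pool_factor^(levels-1)}.
#' @return an object of class \code{dcae_spec}.
#' @export
model_spec <- function(family = c("ldcae", "udcae"), input_len = 640) {
  family <- match.arg(family)
  if (family == "ldcae")
    dcae_spec(encoder_filters = c(16L, 32L, 64L), kernel_size = 11L,
              skip_connections = FALSE, input_len = input_len,
              family = "ldcae")
  else
    dcae_spec(encoder_filters = c(32L, 64L, 128L, 256L), kernel_size = 3L,
              skip_connections = TRUE, input_len = input_len,
              family = "udcae")
}

#' @rdname model_spec
#' @export
ldcae_spec <- function(input_len = 640) model_spec("ldcae", input_len)

#' @rdname model_spec
#' @export
udcae_spec <- function(input_len = 640) model_spec("udcae", input_len)

#' Low-level autoencoder spec with an arbitrary filter ladder
#'
#' Used by [model_spec()] for the two canonical families; exposed so scaled-
#' down architectures can be built for quick experiments.
#'
#' @param encoder_filters increasing integer vector; the last entry is the
#'   bottleneck width, the decoder mirrors the rest.
#' @param kernel_size odd convolution width in samples.
#' @param skip_connections concatenate encoder feature maps into the decoder?
#' @param input_len window length in samples.
#' @param pool_factor subsampling factor (2 supported).
#' @param final_activation \code{"linear"} (default) or \code{"relu"}.
#' @param family label carried along for reporting.
#' @export
dcae_spec <- function(encoder_filters, kernel_size, skip_connections,
                      input_len = 640, pool_factor = 2,
                      final_activation = "linear", family = "custom") {
  if (pool_factor != 2) stop("only pool_factor = 2 is supported",
                             call. = FALSE)
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd", call. = FALSE)
  levels <- length(encoder_filters)
  if (levels < 2) stop("need at least two encoder levels", call. = FALSE)
  if (input_len %% pool_factor^(levels - 1) != 0)
    stop(sprintf("input_len must be divisible by %d",
                 pool_factor^(levels - 1)), call. = FALSE)
  if (family == "ldcae" &&
      (encoder_filters[1] != 16 || tail(encoder_filters, 1) != 64 ||
       skip_connections))
    stop("ldcae: filter ladder must run 16..64 without skips", call. = FALSE)
  if (family == "udcae" &&
      (encoder_filters[1] != 32 || tail(encoder_filters, 1) != 256 ||
       !skip_connections))
    stop("udcae: filter ladder must run 32..256 with skips", call. = FALSE)
  structure(list(family = family,
                 encoder_filters = as.integer(encoder_filters),
                 decoder_filters = rev(head(as.integer(encoder_filters), -1)),
                 kernel_size = as.integer(kernel_size),
                 skip_connections = isTRUE(skip_connections),
                 input_len = as.integer(input_len),
                 pool_factor = as.integer(pool_factor),
                 final_activation = final_activation),
            class = "dcae_spec")
}

# (in_channels, out_channels, spatial_len) for every conv layer, in order
layer_dims <- function(spec) {
  f <- spec$encoder_filters
  L <- length(f)
  len <- spec$input_len
  dims <- list()
  prev <- 1L
  for (i in seq_len(L)) {
    dims[[length(dims) + 1]] <- c(infilt = prev, outfilt = f[i], len = len)
    prev <- f[i]
    if (i < L) len <- len %/% 2L
  }
  for (i in seq.int(L - 1, 1)) {
    len <- len * 2L
    cin <- f[i + 1] + if (spec$skip_connections) f[i] else 0L
    dims[[length(dims) + 1]] <- c(infilt = cin, outfilt = f[i], len = len)
  }
  dims[[length(dims) + 1]] <- c(infilt = f[1], outfilt = 1L, len = len)
  dims
}

#' Number of trainable parameters implied by a spec
#' @param spec a \code{dcae_spec}.
#' @export
count_params <- function(spec) {
  sum(vapply(layer_dims(spec), function(d)
    spec$kernel_size * d[["infilt"]] * d[["outfilt"]] + d[["outfilt"]], 0))
}

#' Build an (untrained) autoencoder from a spec
#'
#' Weights are He-initialized for the ReLU hidden convolutions and
#' Glorot-scaled for the linear output head; the draw is fully determined by
#' \code{seed}.
#'
#' @param spec a \code{dcae_spec}.
#' @param seed integer seed for the weight draw.
#' @return an object of class \code{dcae_model} with elements \code{spec},
#'   \code{weights}, \code{n_params}, \code{trained}, and after training
#'   \code{history}, \code{normalizer}, \code{target_center},
#'   \code{target_scale}.
#' @export
build_model <- function(spec, seed = 1L) {
  dims <- layer_dims(spec)
  nl <- length(dims)
  weights <- withr::with_seed(seed, lapply(seq_len(nl), function(i) {
    d <- dims[[i]]
    fan_in <- spec$kernel_size * d[["infilt"]]
    sdv <- if (i == nl) sqrt(1 / fan_in) else sqrt(2 / fan_in)
    list(W = matrix(rnorm(fan_in * d[["outfilt"]], 0, sdv),
                    nrow = fan_in, ncol = d[["outfilt"]]),
         b = numeric(d[["outfilt"]]))
  }))
  structure(list(spec = spec, weights = weights,
                 n_params = count_params(spec), trained = FALSE,
                 history = NULL, normalizer = NULL,
                 target_center = NA_real_, target_scale = NA_real_,
                 best_epoch = NA_integer_),
            class = "dcae_model")
}

#' @export
print.dcae_model <- function(x, ...) {
  cat(sprintf("<dcae_model> %s (%s): %d parameters, input %d samples%s\n",
              toupper(x$spec$family),
              if (x$spec$skip_connections) "skip connections" else "no skips",
              x$n_params, x$spec$input_len,
              if (x$trained) sprintf(", trained (best epoch %d)", x$best_epoch)
              else ", untrained"))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the full-scale protocol: 200 epochs, batch size 16, Adam
#' with learning rate 1e-3, shuffled training order, and checkpointing on a
#' 10% validation carve of the training windows (the frozen test set is
#' never used for checkpoint selection).
#'
#' @param epochs,batch_size training schedule.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param shuffle reshuffle the training order each epoch?
#' @param validation_fraction share of training windows held out to monitor
#'   the checkpoint.
#' @param seed integer seed controlling the validation carve and shuffling.
#' @export
train_config <- function(epochs = 200, batch_size = 16,
                         learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, shuffle = TRUE,
                         validation_fraction = 0.1, seed = 1L) {
  if (epochs < 1 || batch_size < 1)
    stop("epochs and batch_size must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, shuffle = isTRUE(shuffle),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train an autoencoder on a dataset split
#'
#' Fits the PPG min-max normalizer on the training windows, standardizes the
#' ABP targets internally (the inverse affine map is part of the model, so
#' predictions come back in mmHg), carves a validation subset for checkpoint
#' monitoring, and runs mini-batch Adam on the mean-squared reconstruction
#' error. The returned model carries the checkpoint-best weights and the
#' full per-epoch train/validation loss history (in mmHg^2).
#'
#' @param model an untrained \code{dcae_model} from [build_model()].
#' @param split a \code{dataset_split}; only its training windows are used.
#' @param config a [train_config()].
#' @return the trained \code{dcae_model}.
#' @export
train_model <- function(model, split, config = train_config()) {
  train_ws <- clean_windows(split$train)
  n <- n_windows(train_ws)
  if (n < 1) stop("empty training set", call. = FALSE)
  norm <- fit_normalizer(train_ws)
  X <- normalize_windows(train_ws$ppg, norm)
  ctr <- mean(train_ws$abp)
  scl <- sd(as.numeric(train_ws$abp))
  if (!is.finite(scl) || scl <= 0) scl <- 1
  Y <- (train_ws$abp - ctr) / scl

  n_val <- if (n >= 10) max(1L, floor(n * config$validation_fraction)) else 0L
  val_idx <- if (n_val > 0)
    withr::with_seed(config$seed, sort(sample.int(n, n_val))) else integer()
  tr_idx <- setdiff(seq_len(n), val_idx)

  fit <- cpp_dcae_train(model$spec, model$weights,
                        X[tr_idx, , drop = FALSE], Y[tr_idx, , drop = FALSE],
                        X[val_idx, , drop = FALSE],
                        Y[val_idx, , drop = FALSE],
                        config$epochs, config$batch_size,
                        config$learning_rate, config$beta1, config$beta2,
                        config$epsilon, config$shuffle, config$seed)
  model$weights <- fit$weights
  model$final_weights <- fit$final_weights
  model$history <- data.frame(epoch = seq_len(nrow(fit$history)),
                              train_loss = fit$history[, 1] * scl^2,
                              val_loss = fit$history[, 2] * scl^2)
  model$best_epoch <- fit$best_epoch
  model$normalizer <- norm
  model$target_center <- ctr
  model$target_scale <- scl
  model$trained <- TRUE
  model
}

#' Predict ABP windows from PPG windows
#'
#' @param object a trained \code{dcae_model}.
#' @param ppg numeric matrix of raw PPG windows (one per row) or a
#'   \code{window_set}; normalization with the training statistics is applied
#'   internally.
#' @param ... unused.
#' @return matrix of predicted ABP windows in mmHg, same shape as the input.
#' @export
predict.dcae_model <- function(object, ppg, ...) {
  if (!object$trained) stop("model is not trained", call. = FALSE)
  if (inherits(ppg, "window_set")) ppg <- ppg$ppg
  if (!is.matrix(ppg)) ppg <- matrix(ppg, nrow = 1)
  if (ncol(ppg) != object$spec$input_len)
    stop(sprintf("windows must have %d samples", object$spec$input_len),
         call. = FALSE)
  Xn <- normalize_windows(ppg, object$normalizer)
  out <- cpp_dcae_predict(object$spec, object$weights, Xn)
  out * object$target_scale + object$target_center
}
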