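#' Encoder architecture configuration
#'
#' Three convolutional layers with 16, 32, and 64 filters (3x3 kernels,
#' stride-2 downsampling: 32 -> 16 -> 8 -> 4), LeakyReLU activations, a
#' dropout layer, and a dense projection to the latent space.
#'
#' @param conv_filters Filter counts for the three layers; fixed at
#'   `c(16, 32, 64)`.
#' @param latent_dim Latent dimensionality (default 64).
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.01).
#' @param dropout Dropout probability before the latent projection.
#' @return List of class `encoder_config`.
#' @export
encoder_config <- function(conv_filters = c(16L, 32L, 64L), latent_dim = 64L,
                           leaky_slope = 0.01, dropout = 0.2) {
  if (!identical(as.integer(conv_filters), c(16L, 32L, 64L))) {
    stop("encoder uses exactly three conv layers with 16, 32, 64 filters",
         call. = FALSE)
  }
  structure(list(conv_filters = as.integer(conv_filters),
                 latent_dim = as.integer(latent_dim),
                 leaky_slope = leaky_slope, dropout = dropout),
            class = "encoder_config")
}

#' Decoder architecture configuration
#'
#' Mirror of the encoder: a dense expansion followed by three
#' transposed-convolution layers with 64, 32, and 16 filters and ReLU
#' activations, then a 1x1 convolution with a sigmoid so reconstructions
#' land in `[0, 1]`.
#'
#' @param deconv_filters Filter counts; fixed at `c(64, 32, 16)`.
#' @return List of class `decoder_config`.
#' @export
decoder_config <- function(deconv_filters = c(64L, 32L, 16L)) {
  if (!identical(as.integer(deconv_filters), c(64L, 32L, 16L))) {
    stop("decoder uses exactly three deconv layers with 64, 32, 16 filters",
         call. = FALSE)
  }
  structure(list(deconv_filters = as.integer(deconv_filters)),
            class = "decoder_config")
}

#' Autoencoder training configuration
#'
#' @param batch_train,batch_val Minibatch sizes (defaults 20 and 10).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Maximum epochs (default 50).
#' @param patience Early-stopping patience on validation loss (default 10).
#' @param threshold_k Multiplier k for the mean + k*sd anomaly threshold.
#' @param seed Seed controlling initialization, shuffling, dropout.
#' @return List of class `ae_config`.
#' @export
ae_config <- function(batch_train = 20L, batch_val = 10L,
                      learning_rate = 0.001, epochs = 50L, patience = 10L,
                      threshold_k = 2.0, seed = 1L) {
  structure(list(batch_train = as.integer(batch_train),
                 batch_val = as.integer(batch_val),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 patience = as.integer(patience), threshold_k = threshold_k,
                 seed = as.integer(seed)),
            class = "ae_config")
}

# Encoder layer names, in order; the "last two" (fine-tuned) are the
# final conv layer and the dense latent projection.
encoder_layer_names <- function() c("enc_conv1", "enc_conv2", "enc_conv3",
                                    "enc_dropout", "enc_latent")
encoder_last_two <- function() c("enc_conv3", "enc_latent")

build_encoder_layers <- function(cfg) {
  g1 <- conv_geom(32L, 32L, 1L)
  g2 <- conv_geom(16L, 16L, 16L)
  g3 <- conv_geom(8L, 8L, 32L)
  list(
    nn_conv("enc_conv1", g1, 16L, "lrelu"),
    nn_conv("enc_conv2", g2, 32L, "lrelu"),
    nn_conv("enc_conv3", g3, 64L, "lrelu"),
    nn_dropout("enc_dropout", cfg$dropout),
    nn_dense("enc_latent", 4L * 4L * 64L, cfg$latent_dim, "linear")
  )
}

build_decoder_layers <- function(enc_cfg) {
  # geometries are the adjoints of stride-2 convs: 4->8, 8->16, 16->32
  list(
    nn_dense("dec_dense", enc_cfg$latent_dim, 4L * 4L * 64L, "relu"),
    nn_tconv("dec_tconv1", conv_geom(8L, 8L, 64L), 64L, "relu"),
    nn_tconv("dec_tconv2", conv_geom(16L, 16L, 32L), 64L, "relu"),
    nn_tconv("dec_tconv3", conv_geom(32L, 32L, 16L), 32L, "relu"),
    nn_conv("dec_out", conv_geom(32L, 32L, 16L, k = 1L, s = 1L, p = 0L),
            1L, "sigmoid")
  )
}

#' Build a convolutional autoencoder
#'
#' Maps a 32x32 image through the encoder to a latent vector and back to
#' a 32x32 reconstruction. Parameter initialization is deterministic
#' under `seed`.
#'
#' @param enc_cfg An [encoder_config()].
#' @param dec_cfg A [decoder_config()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `karyo_autoencoder` with elements `encoder`
#'   and `decoder` (layer lists), `enc_cfg`, `seed`, and (after training)
#'   `history` and `report`.
#' @export
build_autoencoder <- function(enc_cfg = encoder_config(),
                              dec_cfg = decoder_config(), seed = 1L) {
  stopifnot(inherits(enc_cfg, "encoder_config"), inherits(dec_cfg, "decoder_config"))
  layers <- with_seed(seed, {
    enc <- nn_init(build_encoder_layers(enc_cfg))
    dec <- nn_init(build_decoder_layers(enc_cfg))
    list(enc = enc, dec = dec)
  })
  structure(list(encoder = layers$enc, decoder = layers$dec,
                 enc_cfg = enc_cfg, seed = seed, trained = FALSE),
            class = "karyo_autoencoder")
}

#' Mean squared error between two images or batches
#'
#' @param y,y_hat Numeric arrays of identical shape.
#' @return Mean of squared elementwise differences.
#' @export
mse <- function(y, y_hat) {
  if (!identical(dim(y) %||% length(y), dim(y_hat) %||% length(y_hat))) {
    stop("shape mismatch in mse()", call. = FALSE)
  }
  mean((y - y_hat)^2)
}

ae_forward <- function(model, X, train = FALSE) {
  e <- net_fwd(model$encoder, X, train = train)
  d <- net_fwd(model$decoder, e$out, train = train)
  list(recon = d$out, latent = e$out, enc_caches = e$caches, dec_caches = d$caches)
}

#' Reconstruct images and report per-image reconstruction error
#'
#' @param model A `karyo_autoencoder`.
#' @param images List of standardized `chromo_image` or a 1024 x N matrix.
#' @return Numeric vector of per-image MSE reconstruction errors.
#' @export
reconstruction_errors <- function(model, images) {
  X <- images_to_matrix(images)
  R <- ae_forward(model, X, train = FALSE)$recon
  colMeans((X - R)^2)
}

#' Reconstruction-error anomaly threshold
#'
#' Threshold above which a reconstruction error is flagged anomalous:
#' `mean + k * sd` of the errors observed on normal validation images.
#'
#' @param errors_normal_val Nonempty numeric vector of errors on normal
#'   validation images.
#' @param k Nonnegative multiplier (default 2).
#' @return The threshold (sd of a single observation is taken as 0).
#' @export
anomaly_threshold <- function(errors_normal_val, k = 2.0) {
  if (length(errors_normal_val) == 0) stop("no validation errors given", call. = FALSE)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  s <- if (length(errors_normal_val) > 1) sd(errors_normal_val) else 0
  mean(errors_normal_val) + k * s
}

#' Train the autoencoder on unlabeled normal images
#'
#' Minimizes mean squared reconstruction error with Adam on minibatches
#' of normal images only. Validation loss (over a mixed normal/abnormal
#' validation set) is logged each epoch and drives early stopping: the
#' weights with the best validation loss are kept.
#'
#' @param model A `karyo_autoencoder` from [build_autoencoder()].
#' @param unlabeled_normals List of standardized normal images (or a
#'   1024 x N matrix).
#' @param val_set Validation images (normal and abnormal); may be `NULL`,
#'   in which case a tail of the training set is held out.
#' @param cfg An [ae_config()].
#' @return The trained model, with `history` (per-epoch train/val MSE)
#'   and `report` (per-image validation errors, split means, threshold).
#' @export
train_autoencoder <- function(model, unlabeled_normals, val_set = NULL,
                              cfg = ae_config()) {
  stopifnot(inherits(model, "karyo_autoencoder"), inherits(cfg, "ae_config"))
  X <- images_to_matrix(unlabeled_normals)
  if (ncol(X) == 0) stop("empty training set", call. = FALSE)
  if (is.null(val_set)) {
    nv <- max(1L, ncol(X) %/% 10L)
    Xval <- X[, (ncol(X) - nv + 1L):ncol(X), drop = FALSE]
    val_abn <- rep(FALSE, nv)
  } else {
    Xval <- images_to_matrix(val_set)
    val_abn <- if (is.matrix(val_set)) rep(FALSE, ncol(Xval)) else image_labels(val_set)
  }
  layers <- c(model$encoder, model$decoder)
  n_enc <- length(model$encoder)
  state <- adam_init(layers)
  trainable <- rep(TRUE, length(layers))
  n <- ncol(X)
  history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                        val_mse = numeric(0))
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  step <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = cfg$batch_train)) {
        idx <- ord[start:min(start + cfg$batch_train - 1L, n)]
        Xb <- X[, idx, drop = FALSE]
        f <- net_fwd(layers, Xb, train = TRUE)
        diffm <- f$out - Xb
        loss <- mean(diffm^2)
        tot <- tot + loss * length(idx)
        dOut <- 2 * diffm / length(diffm)
        b <- net_bwd(layers, f$caches, dOut)
        step <- step + 1L
        upd <- adam_step(layers, b$grads, state, cfg$learning_rate, step, trainable)
        layers <- upd$layers
        state <- upd$state
      }
      val_out <- net_fwd(layers, Xval, train = FALSE)$out
      val_loss <- mean((val_out - Xval)^2)
      history <- rbind(history, data.frame(epoch = epoch, train_mse = tot / n,
                                           val_mse = val_loss))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, layers = layers, epoch = epoch)
      } else if (epoch - best$epoch >= cfg$patience) {
        break
      }
    }
  })
  model$encoder <- best$layers[seq_len(n_enc)]
  model$decoder <- best$layers[(n_enc + 1L):length(best$layers)]
  model$trained <- TRUE
  model$history <- history
  errs <- reconstruction_errors(model, Xval)
  thr <- anomaly_threshold(errs[!val_abn], cfg$threshold_k)
  model$report <- list(
    val_errors = errs, val_abnormal = val_abn,
    mean_error_normal = mean(errs[!val_abn]),
    mean_error_abnormal = if (any(val_abn)) mean(errs[val_abn]) else NA_real_,
    threshold = thr, threshold_k = cfg$threshold_k
  )
  model
}

#' @export
print.karyo_autoencoder <- function(x, ...) {
  cat("<karyo_autoencoder> conv filters 16/32/64, latent dim",
      x$enc_cfg$latent_dim, "\n")
  if (isTRUE(x$trained)) {
    h <- x$history
    cat("  trained", nrow(h), "epochs; final train MSE",
        signif(h$train_mse[nrow(h)], 4), "| best val MSE",
        signif(min(h$val_mse), 4), "\n")
    cat("  anomaly threshold (mean + ", x$report$threshold_k, " sd): ",
        signif(x$report$threshold, 4), "\n", sep = "")
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
residuals.karyo_autoencoder <- function(object, images, ...) {
  reconstruction_errors(object, images)
}

#' @export
plot.karyo_autoencoder <- function(x, ...) {
  if (!isTRUE(x$trained)) stop("model is untrained", call. = FALSE)
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "MSE", ...)
  graphics::legend("topright", c("train", "validation"),
                   col = c("black", "red3"), lty = 1, bty = "n")
  invisible(x)
}
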