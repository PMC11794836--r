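#' Classifier training configuration
#'
#' Stage-3 (frozen encoder) and stage-4 (fine-tuning) share this
#' configuration; stage 3 uses unweighted cross-entropy, stage 4 uses
#' class-weighted cross-entropy with, by default, inverse-class-frequency
#' weights normalized to mean 1.
#'
#' @param batch_train,batch_val Minibatch sizes (defaults 20 and 10).
#' @param learning_rate Adam learning rate (default 0.0001).
#' @param epochs Training epochs (default 20).
#' @param class_weights Positive weights `c(normal, abnormal)`, or `NULL`
#'   for inverse class frequency (stage 4) / equal weights (stage 3).
#' @param hidden Width of the single hidden layer of the head.
#' @param dropout Dropout probability in the head.
#' @param seed Seed controlling initialization, shuffling, dropout.
#' @return List of class `clf_config`.
#' @export
clf_config <- function(batch_train = 20L, batch_val = 10L,
                       learning_rate = 1e-4, epochs = 20L,
                       class_weights = NULL, hidden = 32L, dropout = 0.2,
                       seed = 1L) {
  if (!is.null(class_weights) && any(class_weights <= 0)) {
    stop("class weights must be strictly positive", call. = FALSE)
  }
  structure(list(batch_train = as.integer(batch_train),
                 batch_val = as.integer(batch_val),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 class_weights = class_weights, hidden = as.integer(hidden),
                 dropout = dropout, seed = as.integer(seed)),
            class = "clf_config")
}

# The head consumes the latent vector plus one auxiliary input: the
# standardized log reconstruction error of the *pretrained* autoencoder.
# The encoder compresses anomalous inputs onto the normal manifold, so
# the latent alone under-detects subtle deletions; the unsupervised
# anomaly score carries exactly that residual signal, and feeding it to
# the supervised head is what makes the model a hybrid.
build_head_layers <- function(latent_dim, cfg) {
  list(
    nn_dense("head_dense1", latent_dim + 1L, cfg$hidden, "lrelu"),
    nn_dropout("head_dropout", cfg$dropout),
    nn_dense("head_logits", cfg$hidden, 2L, "linear")
  )
}

# Standardized log reconstruction error under the frozen stage-1 AE.
aux_score <- function(pretrained_ae, X, norm) {
  e <- log(pmax(reconstruction_errors(pretrained_ae, X), 1e-12))
  (e - norm[1]) / norm[2]
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# Weighted cross-entropy over a batch: sum_i w[y_i] * nll_i / sum_i w[y_i]
# (the convention of mainstream deep-learning frameworks, which reduces
# to plain mean cross-entropy when all weights are equal). y is 0/1
# (normal/abnormal); returns loss and the gradient w.r.t. the logits.
weighted_ce <- function(logits, y, weights = c(1, 1)) {
  P <- softmax_cols(logits)
  n <- length(y)
  wi <- weights[y + 1L]
  picked <- P[cbind(y + 1L, seq_len(n))]
  loss <- sum(wi * -log(pmax(picked, 1e-12))) / sum(wi)
  G <- P
  G[cbind(y + 1L, seq_len(n))] <- G[cbind(y + 1L, seq_len(n))] - 1
  dLogits <- sweep(G, 2, wi, "*") / sum(wi)
  list(loss = loss, dLogits = dLogits, probs = P)
}

#' Extract latent features with a trained encoder
#'
#' Runs the encoder in evaluation mode (dropout off); deterministic
#' given the weights.
#'
#' @param model A `karyo_autoencoder` or `karyo_hybrid` model.
#' @param images List of standardized images or a 1024 x N matrix.
#' @return N x latent_dim feature matrix (one row per image).
#' @export
extract_features <- function(model, images) {
  enc <- if (inherits(model, "karyo_hybrid")) model$encoder
         else if (inherits(model, "karyo_autoencoder")) model$encoder
         else stop("model must be a karyo_autoencoder or karyo_hybrid", call. = FALSE)
  X <- images_to_matrix(images)
  t(net_fwd(enc, X, train = FALSE)$out)
}

default_class_weights <- function(y) {
  # inverse class frequency, normalized to mean 1
  f <- c(mean(y == 0), mean(y == 1))
  w <- 1 / f
  w / mean(w)
}

train_supervised <- function(encoder, head, X, y, cfg, train_encoder_layers,
                             weights, aux = NULL) {
  n_enc <- length(encoder)
  enc_names <- vapply(encoder, `[[`, "", "name")
  enc_trainable <- enc_names %in% train_encoder_layers
  head_trainable <- rep(TRUE, length(head))
  enc_state <- adam_init(encoder)
  head_state <- adam_init(head)
  n <- ncol(X)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0))
  step <- 0L
  # encoder dropout stays off unless encoder layers are being trained
  enc_train_mode <- any(enc_trainable)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = cfg$batch_train)) {
        idx <- ord[start:min(start + cfg$batch_train - 1L, n)]
        Xb <- X[, idx, drop = FALSE]
        yb <- y[idx]
        fe <- net_fwd(encoder, Xb, train = enc_train_mode)
        hin <- if (is.null(aux)) fe$out else rbind(fe$out, aux[idx])
        fh <- net_fwd(head, hin, train = TRUE)
        ce <- weighted_ce(fh$out, yb, weights)
        tot <- tot + ce$loss * length(idx)
        bh <- net_bwd(head, fh$caches, ce$dLogits)
        step <- step + 1L
        upd <- adam_step(head, bh$grads, head_state, cfg$learning_rate, step,
                         head_trainable)
        head <- upd$layers
        head_state <- upd$state
        if (enc_train_mode) {
          dLat <- bh$dX
          if (!is.null(aux)) dLat <- dLat[-nrow(dLat), , drop = FALSE]
          be <- net_bwd(encoder, fe$caches, dLat)
          updE <- adam_step(encoder, be$grads, enc_state, cfg$learning_rate,
                            step, enc_trainable)
          encoder <- updE$layers
          enc_state <- updE$state
        }
      }
      history <- rbind(history, data.frame(epoch = epoch, train_loss = tot / n))
    }
  })
  list(encoder = encoder, head = head, history = history)
}

#' Train the classifier head on a frozen encoder (stage 3)
#'
#' The pretrained encoder extracts latent features; a small dense head
#' is trained on labeled normal/abnormal images with unweighted
#' cross-entropy while every encoder parameter stays bit-identical.
#'
#' @param ae A trained `karyo_autoencoder` (or a `karyo_hybrid` whose
#'   encoder to reuse).
#' @param labeled_set List of labeled standardized `chromo_image`s (must
#'   contain both classes), or a list `list(x = matrix, y = 0/1 vector)`.
#' @param cfg A [clf_config()].
#' @return Object of class `karyo_hybrid` with `stage = "frozen"`.
#' @export
train_frozen <- function(ae, labeled_set, cfg = clf_config()) {
  if (!inherits(ae, "karyo_autoencoder")) {
    stop("train_frozen() requires a karyo_autoencoder", call. = FALSE)
  }
  xy <- as_labeled_xy(labeled_set)
  if (length(unique(xy$y)) < 2) {
    stop("labeled training set must contain both classes", call. = FALSE)
  }
  encoder <- ae$encoder
  pretrained <- structure(list(encoder = ae$encoder, decoder = ae$decoder),
                          class = "karyo_autoencoder")
  raw <- log(pmax(reconstruction_errors(pretrained, xy$x), 1e-12))
  aux_norm <- c(mean(raw), max(sd(raw), 1e-8))
  aux <- (raw - aux_norm[1]) / aux_norm[2]
  head <- with_seed(cfg$seed,
                    nn_init(build_head_layers(head_latent_dim(encoder), cfg)))
  w <- cfg$class_weights %||% c(1, 1)
  fit <- train_supervised(encoder, head, xy$x, xy$y, cfg,
                          train_encoder_layers = character(0), weights = w,
                          aux = aux)
  threshold <- if (!is.null(ae$report)) ae$report$threshold else NA_real_
  structure(list(encoder = fit$encoder, head = fit$head, stage = "frozen",
                 frozen_layers = encoder_layer_names(),
                 history = list(frozen = fit$history),
                 pretrained_ae = pretrained, aux_norm = aux_norm,
                 anomaly_threshold = threshold,
                 decision_threshold = 0.5, cfg = cfg),
            class = "karyo_hybrid")
}

#' Jointly fine-tune the last two encoder layers with the head (stage 4)
#'
#' Unfreezes the final convolutional layer and the dense latent
#' projection — the layers closest to the compressed representation —
#' and trains them together with the head under class-weighted
#' cross-entropy (inverse class frequency by default). All earlier
#' encoder layers stay bit-identical.
#'
#' @param model A `karyo_hybrid` from [train_frozen()].
#' @param labeled_set As in [train_frozen()].
#' @param cfg A [clf_config()].
#' @return The model with `stage = "fine_tuned"`.
#' @export
fine_tune <- function(model, labeled_set, cfg = clf_config()) {
  if (!inherits(model, "karyo_hybrid") || !identical(model$stage, "frozen")) {
    stop("fine_tune() requires a model produced by train_frozen()", call. = FALSE)
  }
  xy <- as_labeled_xy(labeled_set)
  w <- cfg$class_weights %||% default_class_weights(xy$y)
  aux <- aux_score(model$pretrained_ae, xy$x, model$aux_norm)
  fit <- train_supervised(model$encoder, model$head, xy$x, xy$y, cfg,
                          train_encoder_layers = encoder_last_two(), weights = w,
                          aux = aux)
  model$encoder <- fit$encoder
  model$head <- fit$head
  model$stage <- "fine_tuned"
  model$frozen_layers <- setdiff(encoder_layer_names(), encoder_last_two())
  model$history$fine_tune <- fit$history
  model$class_weights <- w
  model
}

head_latent_dim <- function(encoder) {
  encoder[[length(encoder)]]$n_out
}

as_labeled_xy <- function(labeled_set) {
  if (is.list(labeled_set) && !is.null(labeled_set$x)) {
    list(x = labeled_set$x, y = as.integer(labeled_set$y))
  } else {
    list(x = images_to_matrix(labeled_set),
         y = as.integer(image_labels(labeled_set)))
  }
}

#' Predict abnormality for chromosome images
#'
#' @param object A `karyo_hybrid` model.
#' @param images List of standardized images or a 1024 x N matrix.
#' @param type `"label"` (default; logical abnormal flags plus scores) or
#'   `"score"` (numeric abnormality probabilities only).
#' @param threshold Decision threshold on the abnormality score.
#' @param ... Unused.
#' @return For `type = "label"`, a data frame with `score` in `[0, 1]`
#'   and logical `abnormal` (`score > threshold`); for `type = "score"`,
#'   the score vector.
#' @export
predict.karyo_hybrid <- function(object, images, type = c("label", "score"),
                                 threshold = object$decision_threshold, ...) {
  type <- match.arg(type)
  X <- images_to_matrix(images)
  lat <- net_fwd(object$encoder, X, train = FALSE)$out
  aux <- aux_score(object$pretrained_ae, X, object$aux_norm)
  logits <- net_fwd(object$head, rbind(lat, aux), train = FALSE)$out
  score <- softmax_cols(logits)[2L, ]
  if (type == "score") return(score)
  data.frame(score = score, abnormal = score > threshold)
}

#' @export
print.karyo_hybrid <- function(x, ...) {
  cat("<karyo_hybrid> stage:", x$stage, "\n")
  cat("  frozen encoder layers:", paste(x$frozen_layers, collapse = ", "), "\n")
  if (!is.null(x$history$frozen)) {
    cat("  stage-3 final loss:",
        signif(tail(x$history$frozen$train_loss, 1), 4), "\n")
  }
  if (!is.null(x$history$fine_tune)) {
    cat("  stage-4 final loss:",
        signif(tail(x$history$fine_tune$train_loss, 1), 4),
        "| class weights:", paste(signif(x$class_weights, 3), collapse = "/"), "\n")
  }
  invisible(x)
}

#' @export
summary.karyo_hybrid <- function(object, ...) {
  print(object)
  n_par <- sum(vapply(c(object$encoder, object$head), function(l) {
    if (is.null(l$W)) 0L else length(l$W) + length(l$b)
  }, integer(1)))
  cat("  parameters (encoder + head):", n_par, "\n")
  invisible(object)
}

#' @importFrom utils tail
NULL
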