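test_that("autoencoder architecture honors its contracts", {
  ae1 <- build_autoencoder(seed = 42)
  ae2 <- build_autoencoder(seed = 42)
  ae3 <- build_autoencoder(seed = 43)
  p1 <- karyodetect:::layer_params(c(ae1$encoder, ae1$decoder))
  p2 <- karyodetect:::layer_params(c(ae2$encoder, ae2$decoder))
  expect_identical(p1, p2)
  expect_false(identical(p1, karyodetect:::layer_params(c(ae3$encoder, ae3$decoder))))

  # decode(encode(x)) has the shape of x
  X <- matrix(runif(1024 * 4), 1024, 4)
  out <- karyodetect:::ae_forward(ae1, X)$recon
  expect_equal(dim(out), dim(X))
  lat <- extract_features(ae1, X)
  expect_equal(dim(lat), c(4, 64))

  # closed-form parameter count from the layer scheme:
  # conv 3x3 stride 2 (1->16->32->64), dense 1024->64;
  # decoder dense 64->1024, tconv 64->64->32->16 (3x3), 1x1 conv 16->1
  n_expected <- (16 * 9 * 1 + 16) + (32 * 9 * 16 + 32) + (64 * 9 * 32 + 64) +
    (64 * 1024 + 64) +
    (1024 * 64 + 1024) + (64 * 9 * 64 + 64) + (64 * 9 * 32 + 32) +
    (32 * 9 * 16 + 16) + (1 * 16 + 1)
  n_actual <- sum(vapply(c(ae1$encoder, ae1$decoder), function(l) {
    if (is.null(l$W)) 0L else length(l$W) + length(l$b)
  }, integer(1)))
  expect_equal(n_actual, n_expected)

  expect_error(encoder_config(conv_filters = c(8, 16, 32)), "16, 32, 64")
  expect_error(decoder_config(deconv_filters = c(16, 32, 64)), "64, 32, 16")
})

test_that("mse obeys its identities", {
  x <- matrix(runif(16), 4, 4)
  expect_equal(mse(x, x), 0)
  expect_equal(mse(matrix(0, 32, 32), matrix(1, 32, 32)), 1.0)
  expect_equal(mse(c(0, 0.5), c(0.5, 1.0)), 0.25)
  y <- matrix(runif(16), 4, 4)
  expect_equal(mse(x, y), mse(y, x))
  expect_gte(mse(x, y), 0)
  expect_error(mse(x, y[1:3, ]), "shape")
})

test_that("training memorizes a single repeated image and behaves sanely", {
  img <- reference_image(7)
  X <- images_to_matrix(rep(list(img), 100))
  ae <- build_autoencoder(seed = 2)
  fit <- train_autoencoder(ae, X, X[, 1:5],
                           ae_config(epochs = 50, patience = 50, seed = 2))
  expect_lt(min(fit$history$val_mse), 1e-3)
  expect_true(all(is.finite(fit$history$train_mse)))
  expect_true(all(is.finite(fit$history$val_mse)))
  expect_lte(fit$history$train_mse[nrow(fit$history)], fit$history$train_mse[1])
  # learning rate 0 leaves parameters untouched
  ae0 <- build_autoencoder(seed = 3)
  fit0 <- train_autoencoder(ae0, X[, 1:10], X[, 1:5],
                            ae_config(epochs = 1, learning_rate = 0, seed = 1))
  expect_identical(karyodetect:::layer_params(fit0$encoder),
                   karyodetect:::layer_params(ae0$encoder))
  expect_identical(karyodetect:::layer_params(fit0$decoder),
                   karyodetect:::layer_params(ae0$decoder))
  expect_error(train_autoencoder(ae, matrix(0, 1024, 0), NULL, ae_config()),
               "empty")
})

test_that("anomaly threshold is mean + k*sd and flags exactly the exceedances", {
  expect_equal(anomaly_threshold(rep(0.3, 5), k = 7), 0.3)
  expect_equal(anomaly_threshold(c(1, 2, 3), k = 2), 4.0)
  expect_error(anomaly_threshold(numeric(0)), "no validation errors")
  expect_error(anomaly_threshold(c(1, 2), k = -1), "k must be")
  set.seed(5)
  errs <- rexp(50)
  thr <- anomaly_threshold(errs, k = 1.5)
  flagged <- errs > thr
  expect_identical(flagged, vapply(errs, function(e) e > thr, logical(1)))
})

test_that("encoder features are deterministic and anomaly-sensitive", {
  ae <- build_autoencoder(seed = 6)
  img <- reference_image(11)
  F1 <- extract_features(ae, list(img, img))
  expect_identical(F1[1, ], F1[2, ])
  del <- standardize(render_chromosome(apply_deletion(canonical_pattern(11), 3, 2),
                                       noise_sd = 0))
  F2 <- extract_features(ae, list(img, del))
  expect_gt(sum(abs(F2[1, ] - F2[2, ])), 0)
})
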