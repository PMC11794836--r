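# Independent brute-force oracles: deliberately naive implementations,
# sharing no code with the package internals they cross-check.

# Windowed SSIM by explicit per-window loops with population moments.
ssim_brute <- function(x, y, window, c1, c2) {
  H <- nrow(x) - window + 1L
  W <- ncol(x) - window + 1L
  map <- matrix(NA_real_, H, W)
  n <- window * window
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      px <- x[i:(i + window - 1L), j:(j + window - 1L)]
      py <- y[i:(i + window - 1L), j:(j + window - 1L)]
      mx <- sum(px) / n
      my <- sum(py) / n
      vx <- sum((px - mx)^2) / n
      vy <- sum((py - my)^2) / n
      cxy <- sum((px - mx) * (py - my)) / n
      map[i, j] <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
        ((mx^2 + my^2 + c1) * (vx + vy + c2))
    }
  }
  map
}

# Normalized cross-correlation surface by per-placement Pearson correlation.
ncc_brute <- function(image, template) {
  th <- nrow(template); tw <- ncol(template)
  H <- nrow(image) - th + 1L
  W <- ncol(image) - tw + 1L
  surf <- matrix(0, H, W)
  tv <- as.vector(template)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      pv <- as.vector(image[i:(i + th - 1L), j:(j + tw - 1L)])
      if (stats::sd(pv) < 1e-12 || stats::sd(tv) < 1e-12) {
        surf[i, j] <- 0
      } else {
        surf[i, j] <- stats::cor(pv, tv)
      }
    }
  }
  surf
}

# Mann-Whitney pairwise AUC estimator: fraction of (positive, negative)
# pairs ranked correctly, ties counting one half.
auc_pairwise <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Zero-noise standardized render of a class's canonical chromosome.
reference_image <- function(class_id) {
  standardize(render_chromosome(canonical_pattern(class_id), noise_sd = 0))
}

# Map a 0-based native pixel-row interval through standardization of a
# chromosome of native length `len` (pad when short, area-resample when
# long) to 1-based 32-image rows.
standardized_rows <- function(rows0, len) {
  if (len <= 32L) {
    pad_top <- (32L - len) %/% 2L
    c(rows0[1] + pad_top + 1L, rows0[2] + pad_top + 1L)
  } else {
    c(floor(rows0[1] * 32 / len) + 1L, ceiling((rows0[2] + 1) * 32 / len))
  }
}

# Tiny training worlds shared by the slower tests.
smoke_split <- function(seed = 5L) {
  make_split(split_config(n_unlabeled = 60L, n_labeled = 60L,
                          n_val = 30L, n_test = 30L), seed = seed)
}
smoke_ae_cfg <- function(epochs = 2L, seed = 3L) {
  ae_config(epochs = epochs, patience = 2L, seed = seed)
}
smoke_clf_cfg <- function(epochs = 3L, seed = 4L) {
  clf_config(epochs = epochs, seed = seed)
}
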