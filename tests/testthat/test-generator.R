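test_that("canonical patterns are deterministic, distinct, and internally consistent", {
  expect_identical(canonical_pattern(1), canonical_pattern(1))
  expect_error(canonical_pattern("Z"), "unknown chromosome class")

  keys <- vapply(chromosome_classes(), function(cl) {
    sp <- canonical_pattern(cl)
    # bands contiguous and non-overlapping, heights >= 1
    expect_true(all(sp$bands$height >= 1))
    expect_identical(sp$bands$start_row,
                     cumsum(c(0L, sp$bands$height[-nrow(sp$bands)])))
    paste(c(sp$bands$height, sp$bands$intensity), collapse = ",")
  }, character(1))
  expect_equal(anyDuplicated(keys), 0)

  b1 <- canonical_pattern(1)$bands
  b22 <- canonical_pattern(22)$bands
  expect_true(nrow(b1) != nrow(b22))
})

test_that("rendering draws bands as stripes and is seed-deterministic", {
  sp <- canonical_pattern(9)
  img0 <- render_chromosome(sp, noise_sd = 0)
  body <- (sp$margin + 1):(sp$width - sp$margin)
  for (i in seq_len(nrow(sp$bands))) {
    rows <- (sp$bands$start_row[i] + 1):(sp$bands$start_row[i] + sp$bands$height[i])
    expect_equal(rowMeans(img0$pixels[rows, body, drop = FALSE]),
                 rep(sp$bands$intensity[i], length(rows)))
  }
  expect_true(all(img0$pixels >= 0 & img0$pixels <= 1))

  a <- render_chromosome(sp, noise_sd = 0.05, seed = 7)
  b <- render_chromosome(sp, noise_sd = 0.05, seed = 7)
  c <- render_chromosome(sp, noise_sd = 0.05, seed = 8)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c$pixels))
  expect_error(render_chromosome(sp, noise_sd = -1), "noise_sd")
})

test_that("deletions shorten the chromosome and preserve the flanking bands", {
  sp <- canonical_pattern(5)
  h3 <- sp$bands$height[3]
  del <- apply_deletion(sp, 3, 1)
  expect_equal(spec_len <- sum(del$bands$height), sum(sp$bands$height) - h3)
  expect_identical(del$anomaly$type, "deletion")
  # bands outside the span keep intensity and order
  expect_equal(del$bands$intensity, sp$bands$intensity[-3])
  expect_equal(del$bands$label, sp$bands$label[-3])
  # zero-band deletion only annotates
  del0 <- apply_deletion(sp, 2, 0)
  expect_equal(del0$bands, sp$bands)
  expect_identical(del0$anomaly$type, "deletion")
  expect_error(apply_deletion(sp, 9, 5), "out of range")
})

test_that("deletion difference against the canonical render starts at the deleted span", {
  sp <- canonical_pattern(9)
  del <- apply_deletion(sp, 5, 2)
  full <- render_chromosome(sp, noise_sd = 0)$pixels
  short <- render_chromosome(del, noise_sd = 0)$pixels
  at <- del$anomaly$at_row  # 0-based first deleted row
  cmp <- full[seq_len(nrow(short)), , drop = FALSE]
  differs <- rowSums(abs(cmp - short)) > 0
  expect_true(all(!differs[seq_len(at)]))
  expect_true(any(differs[(at + 1):length(differs)]))
})

test_that("reciprocal translocation exchanges distal segments exactly", {
  a <- canonical_pattern(9)
  b <- canonical_pattern(22)
  ders <- apply_translocation(a, b, 5, 2)
  expect_equal(nrow(ders$der_a$bands) + nrow(ders$der_b$bands),
               nrow(a$bands) + nrow(b$bands))
  # distal of der_b is the distal of a, band for band
  distal_a <- a$bands[6:nrow(a$bands), c("height", "intensity", "label")]
  got <- ders$der_b$bands[3:nrow(ders$der_b$bands), c("height", "intensity", "label")]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(distal_a)))
  # rendered foreign block of der_b matches the source block from a (zero noise)
  ra <- render_chromosome(a, noise_sd = 0)$pixels
  rb <- render_chromosome(ders$der_b, noise_sd = 0)$pixels
  fr <- ders$der_b$anomaly$foreign_rows
  src_start <- a$bands$start_row[6]
  n <- fr[2] - fr[1] + 1
  expect_identical(rb[(fr[1] + 1):(fr[2] + 1), ],
                   ra[(src_start + 1):(src_start + n), ])
  expect_error(apply_translocation(a, b, nrow(a$bands), 2), "breakpoints")
})

test_that("split generation matches configured counts, is seeded, and never leaks labels", {
  cfg <- split_config(n_unlabeled = 30, n_labeled = 40, n_val = 20, n_test = 20)
  sp1 <- make_split(cfg, seed = 3)
  sp2 <- make_split(cfg, seed = 3)
  expect_equal(unname(rowSums(sp1$counts)), c(30, 40, 20, 20))
  expect_equal(unname(sp1$counts["labeled_train", "abnormal"]), round(0.23 * 40))
  # unlabeled pretraining split is all normal, including by spec provenance
  expect_true(all(vapply(sp1$unlabeled_train,
                         function(im) identical(im$spec$anomaly$type, "none"),
                         logical(1))))
  # seeded determinism: identical labels and pixels
  expect_identical(lapply(sp1$labeled_train, `[[`, "is_abnormal"),
                   lapply(sp2$labeled_train, `[[`, "is_abnormal"))
  expect_identical(lapply(sp1$test, `[[`, "pixels"),
                   lapply(sp2$test, `[[`, "pixels"))
  expect_false(identical(lapply(make_split(cfg, seed = 4)$test, `[[`, "pixels"),
                         lapply(sp1$test, `[[`, "pixels")))
  # all images standardized
  expect_true(all(vapply(sp1$test, function(im) all(dim(im$pixels) == 32), logical(1))))

  cfg0 <- split_config(n_unlabeled = 10, n_labeled = 10, n_val = 10, n_test = 10,
                       frac_abnormal_labeled = 0, frac_abnormal_val = 0,
                       frac_abnormal_test = 0)
  sp0 <- make_split(cfg0, seed = 1)
  expect_equal(sum(sp0$counts[, "abnormal"]), 0)
  expect_error(split_config(frac_abnormal_labeled = 1.2), "fractions")
})

test_that("same-class renders are closer than cross-class renders", {
  classes <- chromosome_classes()
  refs <- lapply(classes, function(cl) {
    standardize(render_chromosome(canonical_pattern(cl), noise_sd = 0.03,
                                  seed = 1000 + match(cl, classes)))$pixels
  })
  alts <- lapply(classes, function(cl) {
    standardize(render_chromosome(canonical_pattern(cl), noise_sd = 0.03,
                                  seed = 2000 + match(cl, classes)))$pixels
  })
  for (i in seq_along(classes)) {
    same <- mean(abs(refs[[i]] - alts[[i]]))
    for (j in seq_along(classes)) {
      if (i == j) next
      expect_lt(same, mean(abs(refs[[i]] - alts[[j]])))
    }
  }
})

test_that("splits round-trip through PGM, CSV, and JSON sidecars", {
  dir <- withr::local_tempdir()
  sp <- make_split(split_config(n_unlabeled = 3, n_labeled = 4, n_val = 2,
                                n_test = 2), seed = 9)
  write_split(sp, dir)
  lab <- read.csv(file.path(dir, "labeled_train", "labels.csv"))
  expect_equal(nrow(lab), 4)
  expect_setequal(names(lab), c("filename", "class_id", "is_abnormal",
                                "anomaly_type", "anomaly_coords"))
  px <- read_pgm(file.path(dir, "labeled_train", lab$filename[1]))
  expect_equal(dim(px), c(32, 32))
  # 8-bit quantization error only
  expect_lt(max(abs(px - sp$labeled_train[[1]]$pixels)), 1 / 255)
  specs <- jsonlite::read_json(file.path(dir, "test", "specs.json"))
  expect_length(specs, 2)
  expect_identical(specs[[1]]$filename, "img00001.pgm")
})
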