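test_that("SSIM identity, symmetry, bound, and the constant-image closed form", {
  set.seed(2)
  x <- matrix(runif(100), 10, 10)
  p <- ssim_params(window = 5)
  same <- kd_ssim(x, x, p)
  expect_equal(same$global_score, 1.0)
  expect_true(all(same$score_map == 1))

  y <- matrix(runif(100), 10, 10)
  expect_equal(kd_ssim(x, y, p)$global_score, kd_ssim(y, x, p)$global_score)
  expect_true(all(kd_ssim(x, y, p)$score_map <= 1 + 1e-12))

  a <- 0.3; b <- 0.8
  const <- kd_ssim(matrix(a, 8, 8), matrix(b, 8, 8), p)
  expect_equal(unique(as.vector(const$score_map)),
               (2 * a * b + p$c1) / (a^2 + b^2 + p$c1))

  expect_error(kd_ssim(x, y[1:9, 1:9]), "same shape")
  expect_error(ssim_params(window = 4), "odd")
})

test_that("SSIM maps match the brute-force oracle on random small images", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(6:12, 1)
    m <- sample(6:12, 1)
    w <- sample(c(3, 5), 1)
    if (w > min(n, m)) w <- 3
    x <- matrix(runif(n * m), n, m)
    y <- matrix(runif(n * m), n, m)
    p <- ssim_params(window = w)
    expect_equal(kd_ssim(x, y, p)$score_map, ssim_brute(x, y, w, p$c1, p$c2),
                 tolerance = 1e-12)
  }
})

test_that("difference regions recover deletion ground truth and order by area", {
  # identical inputs: nothing to report
  x <- reference_image(9)$pixels
  expect_equal(nrow(difference_regions(kd_ssim(x, x))), 0)

  # zero-noise deletion: the single region spans the deletion and below
  sp <- canonical_pattern(9)
  del <- apply_deletion(sp, 5, 2)
  img <- standardize(render_chromosome(del, noise_sd = 0))
  regs <- difference_regions(kd_ssim(img$pixels, x))
  expect_gte(nrow(regs), 1)
  top <- regs[1, ]
  gt <- standardized_rows(c(del$anomaly$at_row,
                            sum(sp$bands$height) - 1),
                          sum(del$bands$height))
  expect_lte(top$row_min, gt[1] + 6)  # within one SSIM window of the start
  expect_gte(top$row_max, 26)         # extends to the bottom (shift effect)

  # two disjoint altered blocks give two regions sorted by area
  base <- matrix(0.5, 32, 32)
  mod <- base
  mod[2:5, 2:13] <- 1     # larger block
  mod[24:27, 24:29] <- 0  # smaller block
  regs2 <- difference_regions(kd_ssim(base, mod), score_threshold = 0.7,
                              min_area = 2)
  expect_equal(nrow(regs2), 2)
  expect_true(all(diff(regs2$area) <= 0))
  # one region per altered block, each box covering its block
  covers <- function(r, rows, cols) {
    r$row_min <= rows[1] && r$row_max >= rows[2] &&
      r$col_min <= cols[1] && r$col_max >= cols[2]
  }
  expect_true(xor(covers(regs2[1, ], c(2, 5), c(2, 13)),
                  covers(regs2[2, ], c(2, 5), c(2, 13))))
  expect_true(xor(covers(regs2[1, ], c(24, 27), c(24, 29)),
                  covers(regs2[2, ], c(24, 27), c(24, 29))))
})

test_that("template matching matches the brute-force NCC oracle and conventions", {
  set.seed(13)
  # verbatim crop peaks at its origin with score 1
  img <- matrix(runif(32 * 32), 32, 32)
  tpl <- img[10:17, 5:12]
  m <- template_match(img, tpl)
  expect_equal(m$peak_location, c(10L, 5L))
  expect_equal(m$peak_score, 1.0, tolerance = 1e-6)

  # full-surface brute-force equivalence on random small instances
  for (i in 1:60) {
    H <- sample(5:12, 1); W <- sample(5:12, 1)
    th <- sample(2:(H - 1), 1); tw <- sample(2:(W - 1), 1)
    image <- matrix(runif(H * W), H, W)
    template <- matrix(runif(th * tw), th, tw)
    got <- template_match(image, template)
    expect_equal(got$score_surface, ncc_brute(image, template), tolerance = 1e-9)
    expect_equal(got$peak_score, max(got$score_surface))
  }

  # degenerate variance scores 0 everywhere
  flat <- template_match(matrix(runif(64), 8, 8), matrix(0.5, 3, 3))
  expect_true(all(flat$score_surface == 0))
  expect_error(template_match(matrix(1, 4, 4), matrix(1, 4, 4)), "smaller")
})

test_that("NCC peaks are shift-equivariant", {
  tpl <- matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  for (shift in list(c(0, 0), c(2, 3), c(5, 1))) {
    img <- matrix(0.5, 12, 12)
    img[shift[1] + 2:4, shift[2] + 3:5] <- tpl
    m <- template_match(img, tpl)
    expect_equal(m$peak_location, c(2L + shift[1], 3L + shift[2]))
  }
})

test_that("translocation localization recovers the donor segment; deletions and normals do not", {
  ref9 <- reference_image(9)
  ref22 <- reference_image(22)
  ders <- apply_translocation(canonical_pattern(9), canonical_pattern(22), 5, 3)
  der9 <- standardize(render_chromosome(ders$der_a, noise_sd = 0))
  loc <- localize_translocation(der9, ref9, ref22)
  expect_identical(loc$status, "translocated")
  expect_identical(loc$donor_class, "22")
  gt <- standardized_rows(ders$der_a$anomaly$foreign_rows,
                          sum(ders$der_a$bands$height))
  expect_lte(loc$region$row_min, gt[2])
  expect_gte(loc$region$row_max, gt[1])

  del <- apply_deletion(canonical_pattern(9), 2, 2)
  delimg <- standardize(render_chromosome(del, noise_sd = 0))
  locd <- localize_translocation(delimg, ref9, ref22)
  expect_identical(locd$status, "deletion-like")
  expect_true(is.na(locd$donor_class))

  locn <- localize_translocation(ref9, ref9, ref22)
  expect_identical(locn$status, "no localizable anomaly")
})

test_that("localization reports serialize to JSON", {
  dir <- withr::local_tempdir()
  ref9 <- reference_image(9)
  ref22 <- reference_image(22)
  ders <- apply_translocation(canonical_pattern(9), canonical_pattern(22), 5, 3)
  der9 <- standardize(render_chromosome(ders$der_a, noise_sd = 0))
  loc <- localize_translocation(der9, ref9, ref22)
  path <- file.path(dir, "loc.json")
  write_localization(loc, path, input = "der9")
  j <- jsonlite::read_json(path)
  expect_identical(j$prediction, "translocated")
  expect_identical(j$donor_class, "22")
  expect_true(j$match$score >= 0.8)
})
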