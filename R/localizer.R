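#' SSIM parameters
#'
#' @param window Odd side length of the sliding window (default 7; the
#'   common 11x11 leaves too few windows on 32x32 chromosome images).
#' @param c1,c2 Positive stabilizers; defaults `(0.01 L)^2` and
#'   `(0.03 L)^2` with dynamic range `L = 1`.
#' @return List of class `ssim_params`.
#' @export
ssim_params <- function(window = 7L, c1 = 0.01^2, c2 = 0.03^2) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("SSIM window must be odd", call. = FALSE)
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive", call. = FALSE)
  structure(list(window = window, c1 = c1, c2 = c2), class = "ssim_params")
}

# Sliding-window local sums via shifted submatrix accumulation.
window_sums <- function(x, w) {
  H <- nrow(x) - w + 1L
  W <- ncol(x) - w + 1L
  out <- matrix(0, H, W)
  for (dr in 0:(w - 1L)) {
    for (dc in 0:(w - 1L)) {
      out <- out + x[dr + seq_len(H), dc + seq_len(W), drop = FALSE]
    }
  }
  out
}

#' Structural similarity between two images
#'
#' Computes, over every `window x window` sliding position, the
#' stabilized similarity
#' `(2 mu_x mu_y + c1)(2 cov_xy + c2) / ((mu_x^2 + mu_y^2 + c1)(var_x + var_y + c2))`
#' with population (divide-by-n) local moments, and the global score as
#' the mean of the local map. Identical images score exactly 1.
#'
#' @param x,y Numeric matrices of the same shape, values in `[0, 1]`.
#' @param params An [ssim_params()]; the window must fit inside the image.
#' @return Object of class `ssim_result`: `global_score`, `score_map`
#'   (one entry per valid window position), `window`.
#' @export
kd_ssim <- function(x, y, params = ssim_params()) {
  x <- if (inherits(x, "chromo_image")) x$pixels else x
  y <- if (inherits(y, "chromo_image")) y$pixels else y
  if (!identical(dim(x), dim(y))) stop("images must have the same shape", call. = FALSE)
  w <- params$window
  if (w > min(dim(x))) stop("SSIM window larger than image", call. = FALSE)
  n <- w * w
  sx <- window_sums(x, w) / n
  sy <- window_sums(y, w) / n
  sxx <- window_sums(x * x, w) / n - sx^2
  syy <- window_sums(y * y, w) / n - sy^2
  sxy <- window_sums(x * y, w) / n - sx * sy
  map <- ((2 * sx * sy + params$c1) * (2 * sxy + params$c2)) /
    ((sx^2 + sy^2 + params$c1) * (sxx + syy + params$c2))
  structure(list(global_score = mean(map), score_map = map, window = w,
                 params = params, dim = dim(x)),
            class = "ssim_result")
}

#' @export
print.ssim_result <- function(x, ...) {
  cat("<ssim_result> global score", signif(x$global_score, 4),
      "| map", nrow(x$score_map), "x", ncol(x$score_map),
      "(window", x$window, ")\n")
  invisible(x)
}

# 4-connected component labeling by flood fill (images are tiny).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
              mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

#' Extract low-similarity difference regions from an SSIM map
#'
#' Window positions whose local score falls below `score_threshold` are
#' grouped into 4-connected components; each component of at least
#' `min_area` windows is reported as an axis-aligned bounding box in
#' image coordinates (the union of its windows), sorted by area
#' (component size in windows) descending.
#'
#' @param ssim_result An `ssim_result` from [kd_ssim()].
#' @param score_threshold Local-score threshold in `(0, 1]` (default 0.7).
#' @param min_area Minimum component size in windows (default 4).
#' @return Data frame with 1-based inclusive image-coordinate boxes
#'   (`row_min`, `row_max`, `col_min`, `col_max`), `area`, `mean_score`;
#'   zero rows when nothing differs.
#' @export
difference_regions <- function(ssim_result, score_threshold = 0.7, min_area = 4L) {
  stopifnot(inherits(ssim_result, "ssim_result"))
  if (score_threshold <= 0 || score_threshold > 1) {
    stop("score_threshold must lie in (0, 1]", call. = FALSE)
  }
  mask <- ssim_result$score_map < score_threshold
  empty <- data.frame(row_min = integer(0), row_max = integer(0),
                      col_min = integer(0), col_max = integer(0),
                      area = integer(0), mean_score = numeric(0))
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  w <- ssim_result$window
  out <- lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) return(NULL)
    data.frame(row_min = min(idx[, 1]), row_max = max(idx[, 1]) + w - 1L,
               col_min = min(idx[, 2]), col_max = max(idx[, 2]) + w - 1L,
               area = nrow(idx),
               mean_score = mean(ssim_result$score_map[idx]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out[order(-out$area), , drop = FALSE]
}

#' Normalized cross-correlation template matching
#'
#' Slides `template` over every valid placement in `image` and scores
#' each by the Pearson correlation between the template and the covered
#' patch. Placements where either the patch or the template has zero
#' variance score 0 (degenerate-variance convention). The peak is the
#' maximum score; ties break to the smallest `(row, col)` in row-major
#' order.
#'
#' @param image Numeric matrix (or `chromo_image`).
#' @param template Numeric matrix strictly smaller than `image` in both
#'   dimensions.
#' @return Object of class `match_result`: `peak_location` (1-based
#'   `(row, col)` of the template's top-left), `peak_score` in `[-1, 1]`,
#'   and the full `score_surface`.
#' @export
template_match <- function(image, template) {
  image <- if (inherits(image, "chromo_image")) image$pixels else image
  template <- if (inherits(template, "chromo_image")) template$pixels else template
  if (!all(dim(template) < dim(image))) {
    stop("template must be strictly smaller than the image", call. = FALSE)
  }
  th <- nrow(template); tw <- ncol(template)
  n <- th * tw
  tm <- template - mean(template)
  tnorm <- sqrt(sum(tm^2))
  H <- nrow(image) - th + 1L
  W <- ncol(image) - tw + 1L
  surf <- matrix(0, H, W)
  if (tnorm > 1e-12) {
    # local sums of the image under the template footprint
    s1 <- matrix(0, H, W); s2 <- matrix(0, H, W); xc <- matrix(0, H, W)
    for (dr in 0:(th - 1L)) for (dc in 0:(tw - 1L)) {
      sub <- image[dr + seq_len(H), dc + seq_len(W), drop = FALSE]
      s1 <- s1 + sub
      s2 <- s2 + sub^2
      xc <- xc + sub * tm[dr + 1L, dc + 1L]
    }
    denom2 <- s2 - s1^2 / n
    ok <- denom2 > 1e-12
    surf[ok] <- xc[ok] / (sqrt(denom2[ok]) * tnorm)
  }
  peak <- max(surf)
  cand <- which(surf >= peak - 1e-12, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  structure(list(peak_location = as.integer(cand[1, ]),
                 peak_score = surf[cand[1, 1], cand[1, 2]],
                 score_surface = surf,
                 template_dim = dim(template)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> peak", signif(x$peak_score, 4), "at row",
      x$peak_location[1], "col", x$peak_location[2], "\n")
  invisible(x)
}

#' Localizer configuration
#'
#' @param ssim An [ssim_params()].
#' @param score_threshold,min_area Passed to [difference_regions()].
#' @param accept_ncc Peak normalized cross-correlation at or above which
#'   the differing region is declared translocated from the partner
#'   class (default 0.8; below it a deletion-like change is reported).
#' @return List of class `localizer_config`.
#' @export
localizer_config <- function(ssim = ssim_params(), score_threshold = 0.7,
                             min_area = 4L, accept_ncc = 0.8) {
  structure(list(ssim = ssim, score_threshold = score_threshold,
                 min_area = as.integer(min_area), accept_ncc = accept_ncc),
            class = "localizer_config")
}

# First image row containing chromosome content (bands are <= 0.7 on a
# 0.95/1.0 background); Inf when the image is background only.
content_top <- function(px, cutoff = 0.85) {
  hit <- which(apply(px < cutoff, 1, any))
  if (length(hit)) hit[1] else Inf
}

# Vertical shift with background fill: registers a reference to the
# abnormal chromosome's p-arm terminus before SSIM comparison.
shift_rows <- function(px, delta, fill = 1) {
  if (delta == 0) return(px)
  out <- matrix(fill, nrow(px), ncol(px))
  if (delta > 0) {
    keep <- seq_len(nrow(px) - delta)
    out[keep + delta, ] <- px[keep, ]
  } else {
    keep <- (1 - delta):nrow(px)
    out[keep + delta, ] <- px[keep, ]
  }
  out
}

#' Localize the anomalous region of a flagged chromosome
#'
#' Pipeline: register the class-matched normal reference to the abnormal
#' chromosome's p-arm terminus (top content row), compare with SSIM,
#' take the largest low-similarity region, crop that region from the
#' abnormal image, and template-match the crop against the candidate
#' donor (partner-class) reference. A peak correlation at or above
#' `accept_ncc` labels the region as translocated material from the
#' partner; below it, the change is reported as deletion-like. With no
#' sub-threshold region the report is "no localizable anomaly".
#'
#' Both images must share the pixel scale of the reference (the
#' standardizer preserves scale for chromosomes that fit the 32-pixel
#' canvas; derivatives longer than the canvas are resampled and fall
#' outside this routine's alignment guarantee).
#'
#' @param abnormal_img Standardized image flagged abnormal upstream.
#' @param reference_same_class Standardized normal reference of the same
#'   chromosome class.
#' @param reference_partner_class Standardized normal reference of the
#'   candidate donor class.
#' @param config A [localizer_config()].
#' @return Object of class `localization_report`: `status` (one of
#'   `"translocated"`, `"deletion-like"`, `"no localizable anomaly"`),
#'   `region` (one-row data frame or `NULL`), `donor_class`, `match`
#'   (`row`, `col`, `score`), and `ssim_global`.
#' @export
localize_translocation <- function(abnormal_img, reference_same_class,
                                   reference_partner_class,
                                   config = localizer_config()) {
  ab <- if (inherits(abnormal_img, "chromo_image")) abnormal_img$pixels else abnormal_img
  ref <- if (inherits(reference_same_class, "chromo_image")) {
    reference_same_class$pixels
  } else reference_same_class
  partner <- if (inherits(reference_partner_class, "chromo_image")) {
    reference_partner_class$pixels
  } else reference_partner_class
  donor_id <- if (inherits(reference_partner_class, "chromo_image")) {
    reference_partner_class$class_id
  } else NA_character_
  delta <- content_top(ab) - content_top(ref)
  if (is.finite(delta) && delta != 0) ref <- shift_rows(ref, delta)
  ss <- kd_ssim(ab, ref, config$ssim)
  regs <- difference_regions(ss, config$score_threshold, config$min_area)
  if (nrow(regs) == 0) {
    return(structure(list(status = "no localizable anomaly", region = NULL,
                          donor_class = NA_character_, match = NULL,
                          ssim_global = ss$global_score),
                     class = "localization_report"))
  }
  r <- regs[1, ]
  crop <- ab[r$row_min:r$row_max, r$col_min:r$col_max, drop = FALSE]
  # shave pad/background margins off the crop: only chromosome material
  # carries banding signal, and trailing white rows can push the correct
  # placement outside the partner reference
  content_r <- which(apply(crop < 0.9, 1, any))
  content_c <- which(apply(crop < 0.9, 2, any))
  if (length(content_r) >= 2 && length(content_c) >= 2) {
    crop <- crop[min(content_r):max(content_r),
                 min(content_c):max(content_c), drop = FALSE]
  }
  # shave the crop if it does not fit strictly inside the partner reference
  if (nrow(crop) >= nrow(partner)) crop <- crop[seq_len(nrow(partner) - 1L), , drop = FALSE]
  if (ncol(crop) >= ncol(partner)) crop <- crop[, seq_len(ncol(partner) - 1L), drop = FALSE]
  m <- template_match(partner, crop)
  status <- if (m$peak_score >= config$accept_ncc) "translocated" else "deletion-like"
  structure(list(status = status, region = r,
                 donor_class = if (status == "translocated") donor_id else NA_character_,
                 match = list(row = m$peak_location[1], col = m$peak_location[2],
                              score = m$peak_score),
                 ssim_global = ss$global_score),
            class = "localization_report")
}

#' @export
print.localization_report <- function(x, ...) {
  cat("<localization_report>", x$status, "\n")
  if (!is.null(x$region)) {
    cat("  region rows", x$region$row_min, "-", x$region$row_max,
        "cols", x$region$col_min, "-", x$region$col_max,
        "(area", x$region$area, "windows)\n")
    cat("  partner match: score", signif(x$match$score, 4), "at row",
        x$match$row, "col", x$match$col)
    if (!is.na(x$donor_class)) cat(" | donor class", x$donor_class)
    cat("\n")
  }
  invisible(x)
}

#' Write a localization report as JSON
#'
#' @param report A `localization_report`.
#' @param path Output file.
#' @param input Optional input identifier recorded in the JSON.
#' @return Invisibly, `path`.
#' @export
write_localization <- function(report, path, input = NULL) {
  stopifnot(inherits(report, "localization_report"))
  obj <- list(input = input, prediction = report$status,
              regions = report$region, donor_class = report$donor_class,
              match = report$match, ssim_global = report$ssim_global)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
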