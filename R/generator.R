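#' Chromosome classes known to the synthetic generator
#'
#' @return Character vector `"1"`..`"22"`, `"X"`, `"Y"`.
#' @export
chromosome_classes <- function() names(.kd_catalog)

#' Canonical band layout for a chromosome class
#'
#' Returns the frozen, hand-authored band pattern for one of the 24
#' chromosome classes. Patterns are deterministic: the same class always
#' yields an identical spec, and distinct classes have distinct band
#' sequences. Bands are ordered top (p-arm end) to bottom (q-arm end),
#' are contiguous and non-overlapping, and their heights sum to the
#' chromosome length.
#'
#' @param class_id Chromosome class: one of `"1"`..`"22"`, `"X"`, `"Y"`
#'   (integers 1..22 are accepted and converted).
#' @param width Canvas width in pixels (chromosome body plus background
#'   margin on each side).
#' @return An object of class `chromo_spec`: a list with `class_id`,
#'   `bands` (data frame of `start_row` (0-based), `height`, `intensity`,
#'   `label`), `width`, `margin`, and `anomaly` (type `"none"`).
#' @examples
#' sp <- canonical_pattern(9)
#' sum(sp$bands$height)  # chromosome length in pixels
#' @export
canonical_pattern <- function(class_id, width = .kd_default_width) {
  class_id <- as.character(class_id)
  if (!class_id %in% names(.kd_catalog)) {
    stop("unknown chromosome class: ", class_id, call. = FALSE)
  }
  entry <- .kd_catalog[[class_id]]
  h <- as.integer(entry$heights)
  bands <- data.frame(
    start_row = cumsum(c(0L, h[-length(h)])),
    height = h,
    intensity = entry$intensities,
    label = paste0(class_id, "b", seq_along(h)),
    stringsAsFactors = FALSE
  )
  structure(
    list(class_id = class_id, bands = bands, width = as.integer(width),
         margin = .kd_default_margin, anomaly = list(type = "none")),
    class = "chromo_spec"
  )
}

spec_length <- function(spec) sum(spec$bands$height)

#' @export
print.chromo_spec <- function(x, ...) {
  cat("<chromo_spec> class", x$class_id,
      "|", nrow(x$bands), "bands,", spec_length(x), "x", x$width, "px",
      "| anomaly:", x$anomaly$type, "\n")
  invisible(x)
}

#' Rasterize a chromosome spec to a grayscale image
#'
#' Draws each band as a horizontal intensity stripe across the chromosome
#' body (canvas width minus a background margin on each side) on a bright
#' 0.95 background, optionally adds clamped additive Gaussian pixel noise,
#' and clamps all values to `[0, 1]`. Identical `(spec, noise_sd, seed)`
#' give bit-identical pixels.
#'
#' @param spec A `chromo_spec`.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (default 0.03; 0 disables noise).
#' @param seed Integer seed for the noise; required for reproducibility
#'   when `noise_sd > 0`.
#' @return A `chromo_image`: list with `pixels` (length x width matrix in
#'   `[0, 1]`, origin top-left, p-arm at top), `class_id`, `is_abnormal`,
#'   and the originating `spec`.
#' @export
render_chromosome <- function(spec, noise_sd = 0.03, seed = NULL) {
  stopifnot(inherits(spec, "chromo_spec"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  len <- spec_length(spec)
  if (len < 1L || spec$width <= 2L * spec$margin) {
    stop("spec geometry does not fit the canvas", call. = FALSE)
  }
  px <- matrix(.kd_background, nrow = len, ncol = spec$width)
  body <- (spec$margin + 1L):(spec$width - spec$margin)
  for (i in seq_len(nrow(spec$bands))) {
    rows <- (spec$bands$start_row[i] + 1L):(spec$bands$start_row[i] + spec$bands$height[i])
    px[rows, body] <- spec$bands$intensity[i]
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(length(px), 0, noise_sd), nrow = len))
    px <- px + noise
  }
  structure(
    list(pixels = clamp01(px), class_id = spec$class_id,
         is_abnormal = !identical(spec$anomaly$type, "none"), spec = spec),
    class = "chromo_image"
  )
}

#' @export
print.chromo_image <- function(x, ...) {
  cat("<chromo_image>", nrow(x$pixels), "x", ncol(x$pixels),
      "| class", x$class_id %||% "?",
      "|", if (isTRUE(x$is_abnormal)) "abnormal" else "normal", "\n")
  invisible(x)
}

#' Introduce a deletion into a chromosome spec
#'
#' Removes a contiguous span of bands and repacks the remaining bands so
#' they stay contiguous; the chromosome shortens by the deleted height.
#' The anomaly annotation records the deleted band labels and the pixel
#' rows (in the derivative) where material was removed.
#'
#' @param spec A `chromo_spec` with no prior anomaly.
#' @param band_start 1-based index of the first deleted band.
#' @param band_count Number of consecutive bands to delete (0 is a no-op
#'   that only annotates).
#' @return A new `chromo_spec` with `anomaly$type == "deletion"`.
#' @export
apply_deletion <- function(spec, band_start, band_count) {
  stopifnot(inherits(spec, "chromo_spec"))
  nb <- nrow(spec$bands)
  if (band_count < 0 || band_start < 1 || band_start + band_count - 1 > nb) {
    stop("deletion span out of range", call. = FALSE)
  }
  out <- spec
  if (band_count == 0) {
    out$anomaly <- list(type = "deletion", deleted_labels = character(0),
                        deleted_height = 0L, at_row = NA_integer_)
    return(out)
  }
  del <- band_start:(band_start + band_count - 1)
  deleted <- spec$bands[del, , drop = FALSE]
  keep <- spec$bands[-del, , drop = FALSE]
  keep$start_row <- cumsum(c(0L, keep$height[-nrow(keep)]))
  rownames(keep) <- NULL
  out$bands <- keep
  out$anomaly <- list(
    type = "deletion",
    deleted_labels = deleted$label,
    deleted_height = sum(deleted$height),
    at_row = spec$bands$start_row[band_start]  # 0-based row where span began
  )
  out
}

#' Exchange distal segments between two chromosome specs
#'
#' Models a reciprocal translocation: bands `1..break_a` of `spec_a` are
#' joined to the distal bands `(break_b+1)..` of `spec_b`, and vice versa.
#' Each derivative's annotation records the donor class, the foreign band
#' labels, and the 0-based pixel row range occupied by the foreign
#' segment in the derivative.
#'
#' @param spec_a,spec_b `chromo_spec` objects of different classes.
#' @param break_a,break_b Number of proximal (top) bands each chromosome
#'   retains; must be in `1..(n_bands - 1)` so both segments are nonempty.
#' @return List with derivatives `der_a` and `der_b`.
#' @export
apply_translocation <- function(spec_a, spec_b, break_a, break_b) {
  stopifnot(inherits(spec_a, "chromo_spec"), inherits(spec_b, "chromo_spec"))
  na <- nrow(spec_a$bands); nb <- nrow(spec_b$bands)
  if (break_a < 1 || break_a >= na || break_b < 1 || break_b >= nb) {
    stop("invalid translocation breakpoints", call. = FALSE)
  }
  derivative <- function(host, donor, brk_host, brk_donor) {
    prox <- host$bands[seq_len(brk_host), , drop = FALSE]
    dist <- donor$bands[(brk_donor + 1L):nrow(donor$bands), , drop = FALSE]
    bands <- rbind(prox, dist)
    bands$start_row <- cumsum(c(0L, bands$height[-nrow(bands)]))
    rownames(bands) <- NULL
    out <- host
    out$bands <- bands
    foreign_start <- sum(prox$height)
    out$anomaly <- list(
      type = "translocation",
      partner_class = donor$class_id,
      breakpoint_band = brk_host,
      foreign_labels = dist$label,
      foreign_rows = c(foreign_start, foreign_start + sum(dist$height) - 1L)
    )
    out
  }
  list(der_a = derivative(spec_a, spec_b, break_a, break_b),
       der_b = derivative(spec_b, spec_a, break_b, break_a))
}

#' Configuration for the synthetic dataset split generator
#'
#' Defaults mirror the proportions of the clinical corpus the generator
#' stands in for, at desk scale: the encoder pretraining split is all
#' normal; the labeled training split is 23\% abnormal; validation is
#' 10\% abnormal; the test split is 8.5\% abnormal. Deletions outnumber
#' translocations roughly 10.4:7.4, and translocations exchange distal
#' segments between classes 9 and 22.
#'
#' @param n_unlabeled,n_labeled,n_val,n_test Split sizes.
#' @param frac_abnormal_labeled,frac_abnormal_val,frac_abnormal_test
#'   Abnormal fraction per labeled split, each in `[0, 1]`.
#' @param frac_deletion Probability an abnormal image carries a deletion
#'   (otherwise a translocation).
#' @param deletion_bands Integer range of deleted band counts.
#' @param translocation_partners Two classes whose distal segments are
#'   exchanged.
#' @param distal_fraction Target range for the exchanged distal segment,
#'   as a fraction of chromosome length.
#' @param noise_sd Pixel noise standard deviation passed to the renderer.
#' @param standardize If `TRUE` images are standardized to 32x32.
#' @param classes Chromosome classes to sample from.
#' @return A list of class `split_config`.
#' @export
split_config <- function(n_unlabeled = 2000L, n_labeled = 600L,
                         n_val = 200L, n_test = 200L,
                         frac_abnormal_labeled = 0.23,
                         frac_abnormal_val = 0.10,
                         frac_abnormal_test = 0.085,
                         frac_deletion = 10416 / 17828,
                         deletion_bands = 1:3,
                         translocation_partners = c("9", "22"),
                         distal_fraction = c(0.25, 0.40),
                         noise_sd = 0.03,
                         standardize = TRUE,
                         classes = chromosome_classes()) {
  fr <- c(frac_abnormal_labeled, frac_abnormal_val, frac_abnormal_test)
  if (any(fr < 0 | fr > 1)) stop("abnormal fractions must lie in [0, 1]", call. = FALSE)
  if (frac_deletion < 0 || frac_deletion > 1) stop("frac_deletion must lie in [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "split_config")
}

# Draw one random anomalous spec (under the caller's RNG state).
random_abnormal_spec <- function(cfg, class_id) {
  if (stats::runif(1) < cfg$frac_deletion) {
    spec <- canonical_pattern(class_id)
    nb <- nrow(spec$bands)
    count <- sample(cfg$deletion_bands, 1)
    count <- min(count, nb - 2L)  # keep at least two bands
    start <- sample.int(nb - count + 1L, 1)
    apply_deletion(spec, start, count)
  } else {
    a <- canonical_pattern(cfg$translocation_partners[1])
    b <- canonical_pattern(cfg$translocation_partners[2])
    pick_break <- function(spec) {
      len <- spec_length(spec)
      distal <- rev(cumsum(rev(spec$bands$height)))[-1]  # height below each boundary
      frac <- distal / len
      ok <- which(frac >= cfg$distal_fraction[1] & frac <= cfg$distal_fraction[2])
      if (length(ok) == 0) ok <- which.min(abs(frac - mean(cfg$distal_fraction)))
      ok[sample.int(length(ok), 1)]
    }
    ders <- apply_translocation(a, b, pick_break(a), pick_break(b))
    if (stats::runif(1) < 0.5) ders$der_a else ders$der_b
  }
}

generate_one <- function(cfg, abnormal, seed) {
  with_seed(seed, {
    class_id <- sample(cfg$classes, 1)
    spec <- if (abnormal) random_abnormal_spec(cfg, class_id)
            else canonical_pattern(class_id)
    noise_seed <- sample.int(.Machine$integer.max - 1L, 1)
    img <- render_chromosome(spec, noise_sd = cfg$noise_sd, seed = noise_seed)
    if (cfg$standardize) img <- standardize(img)
    img
  })
}

#' Generate a seeded synthetic dataset split
#'
#' Produces four disjoint image sets — unlabeled encoder-pretraining
#' images (all normal), labeled training, validation, and test — with
#' per-split abnormal counts fixed by the configuration. Every image is
#' generated from a child seed derived from `(seed, global index)`, so
#' splits are disjoint by seed lineage and the whole split is a pure
#' function of `(config, seed)`.
#'
#' @param config A [split_config()].
#' @param seed Integer base seed.
#' @return A `karyo_split`: list with `unlabeled_train`, `labeled_train`,
#'   `validation`, `test` (lists of `chromo_image`), plus `counts`,
#'   `config`, `seed`.
#' @export
make_split <- function(config = split_config(), seed = 1L) {
  stopifnot(inherits(config, "split_config"))
  sizes <- c(unlabeled_train = config$n_unlabeled, labeled_train = config$n_labeled,
             validation = config$n_val, test = config$n_test)
  abn_frac <- c(unlabeled_train = 0, labeled_train = config$frac_abnormal_labeled,
                validation = config$frac_abnormal_val, test = config$frac_abnormal_test)
  splits <- list()
  offset <- 0L
  for (nm in names(sizes)) {
    n <- sizes[[nm]]
    n_abn <- round(abn_frac[[nm]] * n)
    flags <- c(rep(TRUE, n_abn), rep(FALSE, n - n_abn))
    flags <- with_seed(derive_seed(seed, offset), sample(flags))
    imgs <- vector("list", n)
    for (i in seq_len(n)) {
      imgs[[i]] <- generate_one(config, flags[i], derive_seed(seed, offset + i))
    }
    splits[[nm]] <- imgs
    offset <- offset + n + 1L
  }
  counts <- t(vapply(splits, function(s) {
    abn <- vapply(s, function(im) isTRUE(im$is_abnormal), logical(1))
    c(normal = sum(!abn), abnormal = sum(abn))
  }, numeric(2)))
  structure(c(splits, list(counts = counts, config = config, seed = seed)),
            class = "karyo_split")
}

#' @export
print.karyo_split <- function(x, ...) {
  cat("<karyo_split> seed", x$seed, "\n")
  print(x$counts)
  invisible(x)
}

#' Write a dataset split to disk
#'
#' Writes each image as a plain-text 8-bit PGM (portable graymap), one
#' `labels.csv` per split (filename, class_id, is_abnormal, anomaly_type,
#' anomaly_coords), and a JSON sidecar with the full ground-truth specs.
#'
#' @param split A `karyo_split`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "karyo_split"))
  written <- character(0)
  for (nm in c("unlabeled_train", "labeled_train", "validation", "test")) {
    sub <- file.path(dir, nm)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    imgs <- split[[nm]]
    rows <- vector("list", length(imgs))
    specs <- vector("list", length(imgs))
    for (i in seq_along(imgs)) {
      fn <- sprintf("img%05d.pgm", i)
      write_pgm(imgs[[i]]$pixels, file.path(sub, fn))
      an <- imgs[[i]]$spec$anomaly
      coords <- if (identical(an$type, "deletion")) {
        paste0("row=", an$at_row, ";h=", an$deleted_height)
      } else if (identical(an$type, "translocation")) {
        paste0("rows=", an$foreign_rows[1], "-", an$foreign_rows[2],
               ";donor=", an$partner_class)
      } else ""
      rows[[i]] <- data.frame(filename = fn, class_id = imgs[[i]]$class_id,
                              is_abnormal = imgs[[i]]$is_abnormal,
                              anomaly_type = an$type, anomaly_coords = coords,
                              stringsAsFactors = FALSE)
      specs[[i]] <- c(list(filename = fn), unclass(imgs[[i]]$spec))
    }
    labf <- file.path(sub, "labels.csv")
    write.csv(do.call(rbind, rows), labf, row.names = FALSE)
    specf <- file.path(sub, "specs.json")
    jsonlite::write_json(specs, specf, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    written <- c(written, labf, specf)
  }
  invisible(written)
}

# Plain-text (P2) 8-bit PGM writer/reader: a text format every image tool
# reads, avoiding a binary PNG dependency.
write_pgm <- function(pixels, path) {
  vals <- round(clamp01(pixels) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(pixels), nrow(pixels)), "255"), con)
  writeLines(apply(vals, 1, paste, collapse = " "), con)
}

#' Read a plain-text PGM image
#'
#' @param path Path to a P2 (ASCII) PGM file.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only ASCII (P2) PGM is supported", call. = FALSE)
  w <- as.integer(toks[2]); h <- as.integer(toks[3]); mx <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: wrong pixel count", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / mx
}
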