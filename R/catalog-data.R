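.kd_catalog <- list(
  `1` = list(heights = c(3L, 5L, 5L, 2L, 2L, 3L, 2L, 2L, 4L, 3L, 7L, 2), intensities = c(0.1, 0.4, 0.2, 0.7, 0.5, 0.3, 0.5, 0.7, 0.4, 0.7, 0.5, 0.1)),
  `2` = list(heights = c(3L, 3L, 3L, 5L, 2L, 2L, 4L, 3L, 5L, 2L, 4L, 3), intensities = c(0.7, 0.2, 0.7, 0.1, 0.5, 0.7, 0.5, 0.1, 0.3, 0.7, 0.2, 0.4)),
  `3` = list(heights = c(3L, 2L, 2L, 3L, 3L, 2L, 5L, 4L, 4L, 6L, 4), intensities = c(0.5, 0.1, 0.7, 0.3, 0.6, 0.1, 0.3, 0.1, 0.5, 0.3, 0.5)),
  `4` = list(heights = c(4L, 2L, 2L, 7L, 4L, 6L, 3L, 2L, 4L, 2), intensities = c(0.5, 0.2, 0.4, 0.7, 0.4, 0.2, 0.5, 0.1, 0.4, 0.7)),
  `5` = list(heights = c(6L, 2L, 3L, 5L, 3L, 3L, 2L, 6L, 3L, 2), intensities = c(0.3, 0.6, 0.4, 0.2, 0.4, 0.1, 0.5, 0.3, 0.6, 0.1)),
  `6` = list(heights = c(5L, 4L, 3L, 6L, 3L, 4L, 2L, 3L, 3), intensities = c(0.1, 0.6, 0.3, 0.5, 0.2, 0.6, 0.1, 0.7, 0.2)),
  `7` = list(heights = c(2L, 7L, 7L, 2L, 3L, 2L, 4L, 4), intensities = c(0.7, 0.2, 0.4, 0.2, 0.5, 0.7, 0.4, 0.7)),
  `8` = list(heights = c(6L, 3L, 4L, 3L, 2L, 6L, 3L, 3), intensities = c(0.6, 0.2, 0.7, 0.2, 0.6, 0.4, 0.7, 0.1)),
  `9` = list(heights = c(2L, 4L, 3L, 3L, 8L, 3L, 5L, 2), intensities = c(0.6, 0.1, 0.6, 0.2, 0.7, 0.5, 0.3, 0.1)),
  `10` = list(heights = c(4L, 5L, 5L, 2L, 5L, 2L, 3L, 3), intensities = c(0.6, 0.2, 0.7, 0.3, 0.1, 0.5, 0.7, 0.5)),
  `11` = list(heights = c(2L, 2L, 3L, 6L, 6L, 3L, 4L, 3), intensities = c(0.3, 0.6, 0.4, 0.7, 0.5, 0.2, 0.7, 0.2)),
  `12` = list(heights = c(3L, 3L, 3L, 5L, 7L, 3L, 4), intensities = c(0.4, 0.1, 0.3, 0.1, 0.6, 0.2, 0.6)),
  `13` = list(heights = c(2L, 4L, 2L, 5L, 6L, 4L, 4), intensities = c(0.1, 0.7, 0.5, 0.1, 0.4, 0.1, 0.7)),
  `14` = list(heights = c(2L, 4L, 2L, 6L, 4L, 2L, 7), intensities = c(0.7, 0.4, 0.2, 0.4, 0.6, 0.2, 0.6)),
  `15` = list(heights = c(2L, 7L, 3L, 7L, 4L, 3), intensities = c(0.2, 0.6, 0.3, 0.5, 0.1, 0.3)),
  `16` = list(heights = c(6L, 6L, 2L, 2L, 3L, 6), intensities = c(0.6, 0.2, 0.6, 0.3, 0.6, 0.3)),
  `17` = list(heights = c(4L, 2L, 6L, 6L, 5L, 2), intensities = c(0.2, 0.6, 0.4, 0.1, 0.7, 0.1)),
  `18` = list(heights = c(7L, 8L, 2L, 2L, 3L, 2), intensities = c(0.1, 0.7, 0.4, 0.2, 0.6, 0.3)),
  `19` = list(heights = c(3L, 5L, 4L, 6L, 5), intensities = c(0.7, 0.1, 0.7, 0.4, 0.6)),
  `20` = list(heights = c(2L, 5L, 6L, 6L, 4), intensities = c(0.2, 0.6, 0.4, 0.2, 0.5)),
  `21` = list(heights = c(2L, 6L, 3L, 8L, 3), intensities = c(0.6, 0.1, 0.7, 0.3, 0.5)),
  `22` = list(heights = c(3L, 5L, 6L, 7), intensities = c(0.7, 0.2, 0.5, 0.2)),
  `X` = list(heights = c(2L, 5L, 3L, 3L, 3L, 4L, 4L, 6), intensities = c(0.7, 0.1, 0.4, 0.7, 0.1, 0.7, 0.1, 0.7)),
  `Y` = list(heights = c(5L, 5L, 2L, 8), intensities = c(0.2, 0.7, 0.5, 0.3))
)

# Frozen hand-authored band catalog: one entry per chromosome class.
# Longer chromosomes (low class numbers) carry more bands, mimicking real
# ideogram ordering; intensities use the 7-level Giemsa-like palette
# {0.1, ..., 0.7} (dark bands low) on a 0.95 bright background. Authored
# once and frozen so tests and downstream models see a fixed world.
.kd_background <- 0.95
.kd_default_width <- 26L
.kd_default_margin <- 3L
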