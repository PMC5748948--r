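# Independent brute-force oracles and shared phantom families.

# Literal per-threshold recount: walks every pixel for every threshold.
oracle_sweep <- function(pixels, t_max) {
  area <- integer(t_max + 1L)
  for (t in 0:t_max) {
    n <- 0L
    for (v in as.vector(pixels)) if (v > t) n <- n + 1L
    area[t + 1L] <- n
  }
  area
}

# Inclusive (spreadsheet-style) quartile from first principles:
# linear interpolation at position h = (n - 1) p + 1 of the sorted values.
oracle_quartile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_iqr_split <- function(x, k = 1.5) {
  q1 <- oracle_quartile(x, 0.25); q3 <- oracle_quartile(x, 0.75)
  lo <- q1 - k * (q3 - q1); hi <- q3 + k * (q3 - q1)
  list(kept = x[x >= lo & x <= hi], outliers = x[x < lo | x > hi])
}

# Phantom family for PI-recovery tests: a small, dim autofluorescent yolk
# (plateau 4 on the 0-255 scale) next to a large bright mass, in a frame
# just big enough for the largest 72 hpi mass. In this regime the automatic
# threshold clears both the noise shoulder and the autofluorescence, and
# residual contamination energy is negligible relative to the mass term.
pi_phantom_spec <- function(seed, noise_sigma = 0) {
  embryo_phantom_spec(
    image_size = c(160L, 160L),
    yolk = list(center = c(60, 55), semi_axes = c(14, 18),
                plateau = 4, plateau_frac = 0.6),
    masses = list(list(center = c(80, 80), radius = 26, intensity = 190)),
    noise_sigma = noise_sigma, seed = seed)
}

# Deterministic grid of 50 area/intensity ratio pairs whose products span
# [0.25, 4] geometrically; intensity ratios stay within the 255 ceiling.
pi_ratio_grid <- function(n = 50L) {
  product <- exp(seq(log(0.25), log(4), length.out = n))
  intensity_ratio <- seq(0.8, 1.25, length.out = n)
  data.frame(area_ratio = product / intensity_ratio,
             intensity_ratio = intensity_ratio,
             product = product)
}

measure_pair_pi <- function(pair) {
  proliferation_index(
    embryo_record("phantom", "0hpi", pair$image_0),
    embryo_record("phantom", "72hpi", pair$image_72))$pi
}

# Write a phantom pair cohort to disk and return a manifest data frame.
write_phantom_cohort <- function(dir, ids, area_ratios, intensity_ratios,
                                 group = NULL, seed0 = 100L,
                                 noise_sigma = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); true_pi <- numeric(length(ids))
  for (i in seq_along(ids)) {
    pair <- render_pair(pi_phantom_spec(seed0 + 7L * i, noise_sigma),
                        area_ratios[i], intensity_ratios[i])
    f0 <- file.path(dir, paste0(ids[i], "_0hpi.png"))
    f72 <- file.path(dir, paste0(ids[i], "_72hpi.png"))
    write_image(pair$image_0, f0)
    write_image(pair$image_72, f72)
    df <- data.frame(embryo_id = ids[i], timepoint = c("0hpi", "72hpi"),
                     image = c(f0, f72), stringsAsFactors = FALSE)
    if (!is.null(group)) df$group <- group[i]
    rows[[i]] <- df
    true_pi[i] <- pair$true_pi
  }
  list(manifest = do.call(rbind, rows), true_pi = true_pi)
}
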