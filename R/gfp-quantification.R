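#' Threshold sweep: GFP pixel area at every integer threshold
#'
#' Counts, for every integer threshold `t` in `0..t_max`, the number of
#' pixels whose intensity is **strictly greater** than `t` (so `t = 0`, "no
#' threshold", counts every positive pixel while excluding true-black
#' background). The decay of this curve with increasing `t` is what the
#' automatic threshold selection reads: embryo autofluorescence occupies the
#' dim end of the scale, so the curve falls steeply while autofluorescent
#' pixels are being shed and flattens once only the bright tumor-cell mass
#' remains.
#'
#' @param image an [intensity_image()].
#' @param t_max largest threshold swept (default 50; autofluorescence in the
#'   yolk lives well below this on the 0--255 scale).
#' @return A `threshold_sweep`: list with `t` (0..t_max), `area` (pixel
#'   counts, non-increasing), `t_max`, `n_pixels`.
#' @seealso [select_threshold()], [measure_gfp()]
#' @export
compute_sweep <- function(image, t_max = 50L) {
  assert_image(image)
  if (length(t_max) != 1L || is.na(t_max) || t_max < 1L)
    stop("`t_max` must be a single integer >= 1", call. = FALSE)
  t_max <- as.integer(t_max)
  px <- as.vector(as_pixel_matrix(image))
  ts <- 0:t_max
  area <- vapply(ts, function(t) sum(px > t), integer(1L))
  structure(list(t = ts, area = area, t_max = t_max,
                 n_pixels = length(px)),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> t in [0, %d]; area(0) = %d of %d px; area(%d) = %d\n",
              x$t_max, x$area[1L], x$n_pixels, x$t_max, x$area[length(x$area)]))
  invisible(x)
}

#' Sweep as a data frame
#' @param x a `threshold_sweep`.
#' @param ... unused.
#' @return data frame with columns `t`, `area` (for export / audit plots).
#' @export
as.data.frame.threshold_sweep <- function(x, ...) {
  data.frame(t = x$t, area = x$area)
}

#' Automatic threshold selection from a sweep
#'
#' Picks the lowest threshold at which the GFP area curve has become stable,
#' i.e. the point beyond which no further step sheds a meaningful fraction
#' of the no-threshold area. Formally, with step decay
#' `d(t) = (area(t-1) - area(t)) / area(0)`, the selected threshold is the
#' smallest `t >= 1` such that `d(t') < tolerance` for **all** `t'` from `t`
#' to `t_max`. Requiring stability from `t` onward (rather than stopping at
#' the first quiet step) is robust to autofluorescence whose intensity
#' distribution has a shoulder: a plateau of dim yolk pixels at some
#' intensity `a` produces a large decay step at `t = a`, pushing the
#' selected threshold just past it.
#'
#' Two edge cases are flagged rather than silently absorbed:
#'
#' * `flat_curve` -- no step ever exceeded the tolerance, so the curve is
#'   flat from the start (an embryo with no detectable autofluorescence).
#'   The threshold is fixed at 1, which removes zero-valued background while
#'   keeping all signal.
#' * `saturated` -- the final step still exceeded the tolerance, so the
#'   curve never stabilized within the sweep. The threshold is pinned at
#'   `t_max` and a warning is raised: the measurement is unstable and a
#'   longer sweep (or a look at the image) is warranted.
#'
#' @param sweep a [compute_sweep()] result with `area(0) > 0`.
#' @param tolerance decay fraction below which a step counts as stable
#'   (default 0.10, i.e. ten percent of the no-threshold area).
#' @return A `threshold_selection`: list with `threshold`, `tolerance`,
#'   `flat_curve`, `saturated`, `decay` (the vector `d(1..t_max)`), `t_max`.
#' @export
select_threshold <- function(sweep, tolerance = 0.10) {
  if (!inherits(sweep, "threshold_sweep"))
    stop("`sweep` must be a threshold_sweep (see compute_sweep())",
         call. = FALSE)
  if (length(tolerance) != 1L || is.na(tolerance) ||
      tolerance <= 0 || tolerance >= 1)
    stop("`tolerance` must be a fraction in (0, 1)", call. = FALSE)
  a <- sweep$area
  if (a[1L] == 0L)
    stop("empty signal: area at threshold 0 is zero (nothing fluorescent to threshold)",
         call. = FALSE)
  d <- (a[-length(a)] - a[-1L]) / a[1L]   # d[t], t = 1..t_max
  unstable <- which(d >= tolerance)
  if (length(unstable) == 0L) {
    threshold <- 1L; flat <- TRUE; sat <- FALSE
  } else if (max(unstable) == sweep$t_max) {
    threshold <- sweep$t_max; flat <- FALSE; sat <- TRUE
    warning("sweep never stabilized within t_max = ", sweep$t_max,
            "; threshold pinned at t_max (measurement may include autofluorescence)",
            call. = FALSE)
  } else {
    threshold <- max(unstable) + 1L; flat <- FALSE; sat <- FALSE
  }
  structure(list(threshold = as.integer(threshold), tolerance = tolerance,
                 flat_curve = flat, saturated = sat,
                 decay = d, t_max = sweep$t_max),
            class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  flags <- c(if (x$flat_curve) "flat curve (no autofluorescence shoulder)",
             if (x$saturated) "SATURATED (never stabilized)")
  cat(sprintf("<threshold_selection> threshold = %d (tolerance %.2f)%s\n",
              x$threshold, x$tolerance,
              if (length(flags)) paste0(" [", paste(flags, collapse = "; "), "]")
              else ""))
  invisible(x)
}

#' Measure GFP area and mean intensity at a threshold
#'
#' `nGFP` is the number of pixels strictly brighter than the threshold -- a
#' proxy for tumor-cell area; `GMV` (GFP mean value) is the arithmetic mean
#' intensity of those pixels -- a proxy for signal density. Their product is
#' the per-image quantity whose 72 hpi / 0 hpi ratio defines the
#' proliferation index.
#'
#' @param image an [intensity_image()].
#' @param threshold integer threshold in \[0, 255\].
#' @return A `gfp_measurement`: list with `threshold`, `ngfp`, `gmv`
#'   (`gmv = 0` when `ngfp = 0`).
#' @export
measure_gfp <- function(image, threshold) {
  assert_image(image)
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 255)
    stop("`threshold` must be a single value in [0, 255]", call. = FALSE)
  px <- as.vector(as_pixel_matrix(image))
  sel <- px > threshold
  ngfp <- sum(sel)
  gmv <- if (ngfp > 0L) mean(px[sel]) else 0
  structure(list(threshold = threshold, ngfp = as.integer(ngfp), gmv = gmv),
            class = "gfp_measurement")
}

#' @export
print.gfp_measurement <- function(x, ...) {
  cat(sprintf("<gfp_measurement> threshold %s: nGFP = %d px, GMV = %.4f\n",
              format(x$threshold), x$ngfp, x$gmv))
  invisible(x)
}

#' Construct a per-embryo image record
#'
#' Binds an image to its embryo identity, experimental group and timepoint.
#' Each embryo is photographed twice -- immediately after injection (0 hpi)
#' and 72 hours later (72 hpi) -- and the pair feeds
#' [proliferation_index()].
#'
#' @param embryo_id character scalar identifying the embryo.
#' @param timepoint `"0hpi"` or `"72hpi"`.
#' @param image an [intensity_image()].
#' @param group named list of group labels (e.g. temperature, treatment,
#'   replicate id); free-form.
#' @return An `embryo_record`.
#' @export
embryo_record <- function(embryo_id, timepoint, image, group = list()) {
  if (!is.character(embryo_id) || length(embryo_id) != 1L || is.na(embryo_id))
    stop("`embryo_id` must be a single string", call. = FALSE)
  timepoint <- as.character(timepoint)
  if (length(timepoint) != 1L || !timepoint %in% c("0hpi", "72hpi"))
    stop("`timepoint` must be \"0hpi\" or \"72hpi\"", call. = FALSE)
  assert_image(image)
  structure(list(embryo_id = embryo_id, timepoint = timepoint,
                 image = image, group = group),
            class = "embryo_record")
}

#' Proliferation index for a 0 hpi / 72 hpi image pair
#'
#' The headline statistic of the pipeline:
#' \deqn{PI = \frac{nGFP_{72} \cdot GMV_{72}}{nGFP_{0} \cdot GMV_{0}}}
#' PI > 1 indicates tumor-cell proliferation, PI = 1 stable cells, PI < 1
#' cell death.
#'
#' A threshold is selected independently for each timepoint via
#' [select_threshold()] and the **higher of the two** is applied to both
#' images: comparability of the GFP area over time requires a single shared
#' threshold. A 72 hpi image with no fluorescent signal at all is legal
#' (total cell death: PI = 0); a 0 hpi image without measurable signal makes
#' the PI denominator zero, so an undefined-baseline error is raised -- such
#' an embryo would have been discarded as incorrectly injected.
#'
#' @param rec0,rec72 [embryo_record()]s sharing `embryo_id`, at timepoints
#'   `"0hpi"` and `"72hpi"` respectively.
#' @param tolerance decay tolerance passed to [select_threshold()].
#' @param t_max sweep extent passed to [compute_sweep()].
#' @param epsilon half-width of the "stable" band around PI = 1 (default
#'   1e-9: the trichotomy at 1 is effectively strict).
#' @return A `proliferation_result`: list with `embryo_id`, `group`,
#'   `shared_threshold`, the per-timepoint `selection_0` / `selection_72`,
#'   measurements `m0` / `m72`, `pi` and `classification`
#'   (`"death"`, `"stable"` or `"proliferation"`).
#' @export
proliferation_index <- function(rec0, rec72, tolerance = 0.10, t_max = 50L,
                                epsilon = 1e-9) {
  if (!inherits(rec0, "embryo_record") || !inherits(rec72, "embryo_record"))
    stop("`rec0` and `rec72` must be embryo_record objects", call. = FALSE)
  if (rec0$embryo_id != rec72$embryo_id)
    stop("pairing error: embryo_id mismatch (\"", rec0$embryo_id,
         "\" vs \"", rec72$embryo_id, "\")", call. = FALSE)
  if (rec0$timepoint != "0hpi" || rec72$timepoint != "72hpi")
    stop("`rec0` must be the 0hpi record and `rec72` the 72hpi record",
         call. = FALSE)

  sweep0 <- compute_sweep(rec0$image, t_max)
  if (sweep0$area[1L] == 0L)
    stop("undefined baseline: 0 hpi image of embryo \"", rec0$embryo_id,
         "\" has no fluorescent signal (PI denominator would be zero)",
         call. = FALSE)
  sel0 <- select_threshold(sweep0, tolerance)

  sweep72 <- compute_sweep(rec72$image, t_max)
  sel72 <- if (sweep72$area[1L] > 0L) select_threshold(sweep72, tolerance)
           else NULL  # blank 72 hpi image: total death, nothing to threshold

  shared <- max(sel0$threshold,
                if (is.null(sel72)) 1L else sel72$threshold)
  m0 <- measure_gfp(rec0$image, shared)
  m72 <- measure_gfp(rec72$image, shared)
  if (m0$ngfp == 0L || m0$gmv == 0)
    stop("undefined baseline: 0 hpi measurement of embryo \"",
         rec0$embryo_id, "\" is zero at the shared threshold ", shared,
         call. = FALSE)

  pi_val <- (m72$ngfp * m72$gmv) / (m0$ngfp * m0$gmv)
  classification <-
    if (pi_val < 1 - epsilon) "death"
    else if (pi_val > 1 + epsilon) "proliferation"
    else "stable"
  structure(list(embryo_id = rec0$embryo_id, group = rec0$group,
                 shared_threshold = as.integer(shared),
                 selection_0 = sel0, selection_72 = sel72,
                 m0 = m0, m72 = m72,
                 pi = pi_val, classification = classification,
                 epsilon = epsilon),
            class = "proliferation_result")
}

#' @export
print.proliferation_result <- function(x, ...) {
  cat(sprintf("<proliferation_result> embryo %s: PI = %.4f (%s)\n",
              x$embryo_id, x$pi, x$classification))
  cat(sprintf("  shared threshold %d; 0 hpi: nGFP %d, GMV %.3f; 72 hpi: nGFP %d, GMV %.3f\n",
              x$shared_threshold, x$m0$ngfp, x$m0$gmv, x$m72$ngfp, x$m72$gmv))
  invisible(x)
}
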