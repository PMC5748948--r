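#' Phantom micrographs with ground truth
#'
#' The synthetic test bed standing in for real embryo and cell-drop
#' micrographs (no public image set exists for this assay). An embryo
#' phantom is a dim, spatially broad autofluorescent yolk -- an ellipse with
#' a constant plateau intensity `a` in its core and a smooth linear falloff
#' to 0 at the ellipse edge -- plus one or more bright compact GFP cell
#' masses (disks), with optional additive Gaussian noise clipped to
#' \[0, 255\]. The plateau/falloff shape reproduces the steep-then-flat
#' decay a real sweep curve shows: the falloff sheds small pixel rings at
#' every threshold step, and the plateau sheds one large step at `t = a`.
#'
#' Ground truth (mass area, mass mean intensity, autofluorescence area) is
#' computed from the noise-free geometry before noise is added, and
#' rendering is bit-reproducible given `seed`.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param yolk list with `center` `c(row, col)`, `semi_axes`
#'   `c(row_semi, col_semi)`, `plateau` (autofluorescence plateau intensity
#'   `a`, in \[0, 60\] on the 0--255 scale) and `plateau_frac` (fraction of
#'   the elliptical radius occupied by the plateau, in \[0, 1)).
#' @param masses list of disks, each `list(center = c(row, col), radius,
#'   intensity)` with intensity in `(a, 255]`; every mass must exceed the
#'   autofluorescence plateau and lie inside the image.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise
#'   (>= 0; default 0).
#' @param seed integer RNG seed for the noise.
#' @return For `embryo_phantom_spec`, a validated `embryo_phantom_spec`
#'   object.
#' @name phantoms
NULL

#' @rdname phantoms
#' @export
embryo_phantom_spec <- function(image_size = c(200L, 200L),
                                yolk = list(center = c(100, 90),
                                            semi_axes = c(45, 60),
                                            plateau = 15,
                                            plateau_frac = 0.6),
                                masses = list(list(center = c(105, 100),
                                                   radius = 16,
                                                   intensity = 200)),
                                noise_sigma = 0,
                                seed = 1L) {
  if (length(image_size) != 2L || any(image_size < 1))
    stop("`image_size` must be c(height, width), both >= 1", call. = FALSE)
  yolk <- utils::modifyList(
    list(center = c(100, 90), semi_axes = c(45, 60),
         plateau = 15, plateau_frac = 0.6), yolk)
  if (yolk$plateau < 0 || yolk$plateau > 60)
    stop("yolk plateau intensity must be in [0, 60] (autofluorescence is dim)",
         call. = FALSE)
  if (yolk$plateau_frac < 0 || yolk$plateau_frac >= 1)
    stop("yolk plateau_frac must be in [0, 1)", call. = FALSE)
  if (any(yolk$semi_axes <= 0))
    stop("yolk semi-axes must be positive", call. = FALSE)
  for (m in masses) {
    if (is.null(m$center) || is.null(m$radius) || is.null(m$intensity))
      stop("each mass needs center, radius and intensity", call. = FALSE)
    if (m$intensity <= yolk$plateau || m$intensity > 255)
      stop("mass intensity (", m$intensity,
           ") must strictly exceed the autofluorescence plateau (",
           yolk$plateau, ") and be <= 255", call. = FALSE)
    if (m$radius <= 0) stop("mass radius must be positive", call. = FALSE)
    if (m$center[1L] - m$radius < 1 || m$center[1L] + m$radius > image_size[1L] ||
        m$center[2L] - m$radius < 1 || m$center[2L] + m$radius > image_size[2L])
      stop("mass at (", m$center[1L], ", ", m$center[2L], ") with radius ",
           m$radius, " does not lie inside the ", image_size[1L], " x ",
           image_size[2L], " image", call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  structure(list(image_size = as.integer(image_size), yolk = yolk,
                 masses = masses, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "embryo_phantom_spec")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

disk_mask <- function(h, w, center, radius) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - center[1L])^2 + (cols - center[2L])^2 <= radius^2
}

#' Render an embryo phantom
#'
#' @param spec an [embryo_phantom_spec()].
#' @return A list with `image` (an [intensity_image()]) and `truth`, a
#'   `phantom_ground_truth` carrying `mass_area` (pixel count of the union
#'   of mass disks), `mass_mean_intensity`, `autofluor_area` (pixels with
#'   noise-free rendered intensity in `(0, a]`) and the noise-free geometry.
#' @export
render_embryo <- function(spec) {
  if (!inherits(spec, "embryo_phantom_spec"))
    stop("`spec` must come from embryo_phantom_spec()", call. = FALSE)
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  yk <- spec$yolk
  rho <- sqrt(((rows - yk$center[1L]) / yk$semi_axes[1L])^2 +
              ((cols - yk$center[2L]) / yk$semi_axes[2L])^2)
  base <- matrix(0, h, w)
  a <- yk$plateau; pf <- yk$plateau_frac
  if (a > 0) {
    base[rho <= pf] <- a
    ring <- rho > pf & rho < 1
    base[ring] <- a * (1 - rho[ring]) / (1 - pf)
  }
  mass_mask <- matrix(FALSE, h, w)
  for (m in spec$masses) {
    dm <- (rows - m$center[1L])^2 + (cols - m$center[2L])^2 <= m$radius^2
    base[dm] <- pmax(base[dm], m$intensity)
    mass_mask <- mass_mask | dm
  }
  truth <- structure(list(
    mass_area = sum(mass_mask),
    mass_mean_intensity = if (any(mass_mask)) mean(base[mass_mask]) else 0,
    autofluor_area = sum(base > 0 & base <= a & !mass_mask),
    plateau = a,
    cell_centers = NULL
  ), class = "phantom_ground_truth")
  img <- if (spec$noise_sigma > 0) {
    noisy <- with_seed(spec$seed,
                       base + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w))
    pmin(pmax(noisy, 0), 255)
  } else base
  list(image = intensity_image(img), truth = truth)
}

#' Render a 0 hpi / 72 hpi phantom pair with known true PI
#'
#' The 72 hpi image is the 0 hpi spec with every mass disk's area scaled by
#' `area_ratio` (radius by its square root) and intensity by
#' `intensity_ratio`. The returned `true_pi` is computed from the rasterized
#' ground truth,
#' `(area72 * intensity72) / (area0 * intensity0)`, which equals
#' `area_ratio * intensity_ratio` up to disk rasterization error.
#' Noise (if any) is drawn independently per timepoint (`seed` and
#' `seed + 1`).
#'
#' @param spec0 the 0 hpi [embryo_phantom_spec()].
#' @param area_ratio,intensity_ratio positive scale factors for the 72 hpi
#'   masses; the scaled masses must still fit in frame, stay `<= 255` and
#'   stay above the autofluorescence plateau.
#' @return list with `image_0`, `image_72`, `truth_0`, `truth_72`,
#'   `true_pi`.
#' @export
render_pair <- function(spec0, area_ratio, intensity_ratio) {
  if (!inherits(spec0, "embryo_phantom_spec"))
    stop("`spec0` must come from embryo_phantom_spec()", call. = FALSE)
  if (area_ratio <= 0 || intensity_ratio <= 0)
    stop("`area_ratio` and `intensity_ratio` must be positive", call. = FALSE)
  masses72 <- lapply(spec0$masses, function(m) {
    m$radius <- m$radius * sqrt(area_ratio)
    m$intensity <- m$intensity * intensity_ratio
    m
  })
  spec72 <- embryo_phantom_spec(spec0$image_size, spec0$yolk, masses72,
                                spec0$noise_sigma, spec0$seed + 1L)
  r0 <- render_embryo(spec0)
  r72 <- render_embryo(spec72)
  true_pi <- (r72$truth$mass_area * r72$truth$mass_mean_intensity) /
             (r0$truth$mass_area * r0$truth$mass_mean_intensity)
  list(image_0 = r0$image, image_72 = r72$image,
       truth_0 = r0$truth, truth_72 = r72$truth, true_pi = true_pi)
}

#' Render a cell-drop phantom for counting
#'
#' Emulates a droplet of GFP-labeled cells photographed on a slide before
#' injection: `n_cells` bright disks with radii drawn uniformly from
#' `radius_range`, placed by rejection sampling so that pairwise center
#' separations are at least `min_separation` (set it below twice the radius
#' to create the crowded, partially overlapping regime of high injection
#' loads). Placement is abandoned with an error after `200 * n_cells`
#' attempts.
#'
#' @param n_cells number of cells to place (>= 0).
#' @param radius_range `c(r_min, r_max)` disk radii in pixels.
#' @param min_separation minimum pairwise center distance in pixels.
#' @param intensity disk intensity on the 0--255 scale.
#' @param noise_sigma additive Gaussian noise SD (>= 0).
#' @param seed integer RNG seed (placement and noise).
#' @param image_size `c(height, width)` in pixels.
#' @return list with `image` and `truth`; `truth$cell_centers` is an
#'   `n_cells x 2` matrix of (row, col) centers and `truth$cell_radii` the
#'   matching radii.
#' @export
render_cell_drop <- function(n_cells, radius_range = c(5, 8),
                             min_separation = 2 * radius_range[2L],
                             intensity = 200, noise_sigma = 0,
                             seed = 1L, image_size = c(256L, 256L)) {
  if (n_cells < 0) stop("`n_cells` must be >= 0", call. = FALSE)
  if (length(radius_range) != 2L || radius_range[1L] > radius_range[2L] ||
      radius_range[1L] <= 0)
    stop("`radius_range` must be c(r_min, r_max) with 0 < r_min <= r_max",
         call. = FALSE)
  h <- image_size[1L]; w <- image_size[2L]
  r_max <- radius_range[2L]
  budget <- 200L * max(n_cells, 1L)
  placed <- with_seed(seed, {
    centers <- matrix(numeric(0), 0L, 2L)
    radii <- numeric(0)
    attempts <- 0L
    while (nrow(centers) < n_cells) {
      attempts <- attempts + 1L
      if (attempts > budget)
        stop("could not place ", n_cells, " cells with min_separation ",
             min_separation, " in a ", h, " x ", w, " frame within ",
             budget, " attempts", call. = FALSE)
      cand <- c(stats::runif(1L, r_max + 1, h - r_max),
                stats::runif(1L, r_max + 1, w - r_max))
      if (nrow(centers) == 0L ||
          min(sqrt((centers[, 1L] - cand[1L])^2 +
                   (centers[, 2L] - cand[2L])^2)) >= min_separation) {
        centers <- rbind(centers, cand)
        radii <- c(radii, stats::runif(1L, radius_range[1L], radius_range[2L]))
      }
    }
    noise <- if (noise_sigma > 0)
      matrix(stats::rnorm(h * w, 0, noise_sigma), h, w) else NULL
    list(centers = centers, radii = radii, noise = noise)
  })
  base <- matrix(0, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  if (n_cells > 0) {
    for (i in seq_len(n_cells)) {
      dm <- (rows - placed$centers[i, 1L])^2 +
            (cols - placed$centers[i, 2L])^2 <= placed$radii[i]^2
      base[dm] <- pmax(base[dm], intensity)
    }
  }
  truth <- structure(list(
    mass_area = sum(base > 0),
    mass_mean_intensity = if (any(base > 0)) mean(base[base > 0]) else 0,
    autofluor_area = 0L,
    plateau = 0,
    cell_centers = unname(placed$centers),
    cell_radii = placed$radii
  ), class = "phantom_ground_truth")
  img <- if (!is.null(placed$noise)) pmin(pmax(base + placed$noise, 0), 255)
         else base
  list(image = intensity_image(img), truth = truth)
}

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat(sprintf("<phantom_ground_truth> mass area %d px (mean intensity %.2f), autofluorescence area %d px",
              x$mass_area, x$mass_mean_intensity, x$autofluor_area))
  if (!is.null(x$cell_centers))
    cat(sprintf("; %d cell centers", nrow(x$cell_centers)))
  cat("\n")
  invisible(x)
}
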