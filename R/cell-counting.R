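#' Count cells in a droplet micrograph by circular Hough transform
#'
#' Estimates the number of cells in a pre-injection cell-drop image by
#' detecting bright circular objects of approximately known radius. The
#' pipeline is the classic gradient-vote circular Hough transform:
#'
#' 1. **Edges**: Sobel gradients; a pixel is an edge when its gradient
#'    magnitude is at least `edge_strength` times the image's maximum
#'    gradient magnitude. The cutoff is relative, so the count is invariant
#'    to uniform intensity scaling of the image.
#' 2. **Voting**: each edge pixel casts one vote per candidate radius `r`
#'    (integer steps in `[r_min, r_max]`) at the point `r` pixels along its
#'    gradient direction -- for a bright disk on a dark background the
#'    gradient at the rim points at the center.
#' 3. **Peaks**: each radius accumulator is 3x3 box-summed (to absorb
#'    rasterization spread), the per-pixel best radius is kept, and peaks
#'    must collect at least `accum_threshold * 2 * pi * r` votes -- the
#'    fraction of a full rim that must be present. Surviving local maxima
#'    are thinned by greedy non-maximum suppression at `min_separation`.
#'
#' Touching cells closer than `min_separation` may merge into a single
#' detection; this is accepted -- at high injection loads only an estimate
#' of the count is needed, and a clump delimited by one contour legitimately
#' counts as one object.
#'
#' @param image an [intensity_image()].
#' @param r_min,r_max radius bounds in pixels, `1 <= r_min <= r_max`.
#' @param edge_strength relative gradient-magnitude cutoff in (0, 1]
#'   (default 0.5).
#' @param min_separation minimum distance between detected centers
#'   (default `r_min`).
#' @param accum_threshold minimum fraction of a full circle rim that must
#'   vote for a peak (default 0.3).
#' @return A `cell_count_result`: list with `count`, `detections` (data
#'   frame of `center_row`, `center_col`, `radius`, `score`) and `params`.
#' @examples
#' drop <- render_cell_drop(5, radius_range = c(6, 6), min_separation = 30,
#'                          seed = 7, image_size = c(128, 128))
#' count_cells(drop$image, r_min = 4, r_max = 8)$count
#' @export
count_cells <- function(image, r_min, r_max,
                        edge_strength = 0.5,
                        min_separation = r_min,
                        accum_threshold = 0.3) {
  assert_image(image)
  if (r_min < 1 || r_min > r_max)
    stop("need 1 <= r_min <= r_max (got r_min = ", r_min,
         ", r_max = ", r_max, ")", call. = FALSE)
  if (edge_strength <= 0 || edge_strength > 1)
    stop("`edge_strength` must be in (0, 1]", call. = FALSE)
  params <- list(r_min = r_min, r_max = r_max, edge_strength = edge_strength,
                 min_separation = min_separation,
                 accum_threshold = accum_threshold)
  empty <- function() structure(
    list(count = 0L,
         detections = data.frame(center_row = numeric(0),
                                 center_col = numeric(0),
                                 radius = numeric(0), score = numeric(0)),
         params = params),
    class = "cell_count_result")

  m <- as_pixel_matrix(image)
  h <- nrow(m); w <- ncol(m)
  if (h < 3L || w < 3L) return(empty())
  g <- sobel_gradients(m)
  gmax <- max(g$mag)
  if (gmax == 0) return(empty())          # constant image: no edges
  edge <- which(g$mag >= edge_strength * gmax)
  er <- (edge - 1L) %% h + 1L
  ec <- (edge - 1L) %/% h + 1L
  ur <- g$gr[edge] / g$mag[edge]
  uc <- g$gc[edge] / g$mag[edge]

  radii <- seq(floor(r_min), ceiling(r_max))
  radii <- radii[radii >= 1]
  score <- matrix(0, h, w)
  best_r <- matrix(radii[1L], h, w)
  acc_by_r <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    vr <- as.integer(round(er + r * ur))
    vc <- as.integer(round(ec + r * uc))
    ok <- vr >= 1L & vr <= h & vc >= 1L & vc <= w
    acc <- matrix(tabulate((vc[ok] - 1L) * h + vr[ok], nbins = h * w), h, w)
    acc <- box_sum3(acc)
    acc_by_r[[k]] <- acc
    better <- acc > score
    score[better] <- acc[better]
    best_r[better] <- r
  }

  gate <- accum_threshold * 2 * pi * best_r
  cand <- which(score >= gate & score > 0 & is_local_max(score))
  if (length(cand) == 0L) return(empty())
  ord <- cand[order(score[cand], decreasing = TRUE)]
  cr <- (ord - 1L) %% h + 1L
  cc <- (ord - 1L) %/% h + 1L
  # sub-pixel candidate centers: vote-weighted 3x3 centroid of the winning
  # radius accumulator, computed before suppression so the min_separation
  # guarantee holds for the returned coordinates
  n_cand <- length(ord)
  frow <- numeric(n_cand); fcol <- numeric(n_cand); frad <- numeric(n_cand)
  for (i in seq_len(n_cand)) {
    r_idx <- match(best_r[cr[i], cc[i]], radii)
    acc <- acc_by_r[[r_idx]]
    rr <- max(1L, cr[i] - 1L):min(h, cr[i] + 1L)
    cc2 <- max(1L, cc[i] - 1L):min(w, cc[i] + 1L)
    wts <- acc[rr, cc2, drop = FALSE]
    tot <- sum(wts)
    frow[i] <- if (tot > 0) sum(outer(rr, rep(1, length(cc2))) * wts) / tot else cr[i]
    fcol[i] <- if (tot > 0) sum(outer(rep(1, length(rr)), cc2) * wts) / tot else cc[i]
    frad[i] <- radii[r_idx]
  }
  # greedy non-maximum suppression on the refined centers
  kr <- numeric(0L); kc <- numeric(0L); sel <- integer(0L)
  for (i in seq_len(n_cand)) {
    if (length(kr) == 0L ||
        min((kr - frow[i])^2 + (kc - fcol[i])^2) >= min_separation^2) {
      kr <- c(kr, frow[i]); kc <- c(kc, fcol[i]); sel <- c(sel, i)
    }
  }
  det <- data.frame(center_row = frow[sel], center_col = fcol[sel],
                    radius = frad[sel],
                    score = score[cbind(cr[sel], cc[sel])])
  structure(list(count = nrow(det), detections = det, params = params),
            class = "cell_count_result")
}

#' @export
print.cell_count_result <- function(x, ...) {
  cat(sprintf("<cell_count_result> %d cells detected (radii %g-%g px, edge strength %.2f)\n",
              x$count, x$params$r_min, x$params$r_max, x$params$edge_strength))
  invisible(x)
}

sobel_gradients <- function(m) {
  h <- nrow(m); w <- ncol(m)
  z <- matrix(0, h, w)
  sh <- function(dr, dc) {
    out <- z
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  # d/dcol and d/drow Sobel responses; sh(dr, dc)(r, c) == m(r - dr, c - dc),
  # so sh(0, -1) reads the right-hand neighbor
  gc <- (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L)) -
        (sh(-1L,  1L) + 2 * sh(0L,  1L) + sh(1L,  1L))
  gr <- (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L)) -
        (sh( 1L, -1L) + 2 * sh( 1L, 0L) + sh( 1L, 1L))
  # the zero-padded border produces spurious gradients; blank it
  gr[c(1L, h), ] <- 0; gr[, c(1L, w)] <- 0
  gc[c(1L, h), ] <- 0; gc[, c(1L, w)] <- 0
  list(gr = gr, gc = gc, mag = sqrt(gr^2 + gc^2))
}

box_sum3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  sh <- function(dr, dc) {
    out <- matrix(0, h, w)
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  sh(-1,-1) + sh(-1,0) + sh(-1,1) + sh(0,-1) + m + sh(0,1) +
    sh(1,-1) + sh(1,0) + sh(1,1)
}

is_local_max <- function(m) {
  h <- nrow(m); w <- ncol(m)
  sh <- function(dr, dc) {
    out <- matrix(-Inf, h, w)
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  m >= sh(-1,-1) & m >= sh(-1,0) & m >= sh(-1,1) & m >= sh(0,-1) &
    m >= sh(0,1) & m >= sh(1,-1) & m >= sh(1,0) & m >= sh(1,1)
}

#' Draw detected circles on an image
#'
#' Writes an RGB PNG of the input image with detection contours drawn in
#' red, mirroring the audit overlay a counting run produces.
#'
#' @param image the counted [intensity_image()].
#' @param result a `cell_count_result` from [count_cells()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
overlay_detections <- function(image, result, path) {
  assert_image(image)
  m <- as_pixel_matrix(image) / 255
  h <- nrow(m); w <- ncol(m)
  rgb <- array(0, c(h, w, 3L))
  rgb[, , 1L] <- m; rgb[, , 2L] <- m; rgb[, , 3L] <- m
  th <- seq(0, 2 * pi, length.out = 180L)
  for (i in seq_len(result$count)) {
    d <- result$detections[i, ]
    rr <- round(d$center_row + d$radius * cos(th))
    cc <- round(d$center_col + d$radius * sin(th))
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    idx <- cbind(rr[ok], cc[ok])
    rgb[cbind(idx, 1L)] <- 1; rgb[cbind(idx, 2L)] <- 0; rgb[cbind(idx, 3L)] <- 0
  }
  png::writePNG(rgb, target = path)
  invisible(path)
}
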