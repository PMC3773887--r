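# Brightfield IHC slide phantoms with known vessel ground truth.
#
# The phantom is composed in optical-density space: per pixel
# OD(x) = aH(x) * s_hema + aD(x) * s_dab, then transmitted intensity
# I_c = background_c * 10^(-OD_c). Vessels are elliptical annuli whose
# wall carries the DAB amplitude; the counterstain is a field of nuclear
# blobs. A multiplicative radial vignette (per camera field), additive
# intensity noise and integer quantization emulate acquisition; the slide
# is cut into overlapping tiles with small integer stage errors.

# canonical Hematoxylin / DAB OD directions (unit-normalized on use)
.default_s_hema <- c(0.65, 0.70, 0.29)
.default_s_dab <- c(0.27, 0.57, 0.78)

#' Parameters of a synthetic slide phantom
#'
#' Defaults emulate the study's acquisition conventions: background 235 on
#' all channels, 15\% tile overlap, integer stage errors up to 3 px.
#'
#' @param width_px,height_px canvas dimensions in pixels.
#' @param pixel_size_um physical pixel size (default 0.65 um/px, a 10x
#'   objective with a 3 MP colour sensor).
#' @param vessel_area_fraction target fraction of canvas covered by
#'   vessel wall, in [0, 0.15].
#' @param vessel_radius_range_um (min, max) outer semi-major radii, um.
#' @param wall_thickness_um annulus wall thickness, um.
#' @param nuclei_density_per_mm2 counterstain blob density.
#' @param dab_od_peak,hema_od_peak per-stain OD amplitudes.
#' @param background_rgb background intensity triple (default 235).
#' @param noise_sd additive Gaussian intensity noise (camera counts).
#' @param shading_amplitude peak relative attenuation of the vignette at
#'   the tile corner, in [0, 0.5].
#' @param tile_size_px,overlap_fraction tiling scheme (default 15\%
#'   overlap); overlap_fraction in [0, 0.5).
#' @param seed integer seed driving all randomness.
#' @return object of class \code{slide_phantom_params}.
#' @export
slide_phantom_params <- function(width_px = 1200L, height_px = 1200L,
                                 pixel_size_um = 0.65,
                                 vessel_area_fraction = 0.02,
                                 vessel_radius_range_um = c(8, 30),
                                 wall_thickness_um = 4,
                                 nuclei_density_per_mm2 = 1500,
                                 dab_od_peak = 0.8, hema_od_peak = 0.5,
                                 background_rgb = c(235, 235, 235),
                                 noise_sd = 3, shading_amplitude = 0.15,
                                 tile_size_px = 512L, overlap_fraction = 0.15,
                                 seed = 1L) {
  if (width_px <= 0 || height_px <= 0 || tile_size_px <= 0)
    stop("dimensions must be positive")
  if (vessel_area_fraction < 0 || vessel_area_fraction > 0.15)
    stop("vessel_area_fraction must be in [0, 0.15]")
  if (overlap_fraction < 0 || overlap_fraction >= 0.5)
    stop("overlap_fraction must be in [0, 0.5)")
  if (any(background_rgb <= 0) || any(background_rgb > 255))
    stop("background channels must be in (0, 255]")
  if (shading_amplitude < 0 || shading_amplitude > 0.5)
    stop("shading_amplitude must be in [0, 0.5]")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  structure(as.list(environment()), class = "slide_phantom_params")
}

# radial cosine vignette over one camera field, 1 at centre,
# (1 - amplitude) at the corner
.shading_field <- function(h, w, amplitude) {
  if (amplitude == 0) return(matrix(1, h, w))
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  d <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`))
  dmax <- sqrt((h - cy)^2 + (w - cx)^2)
  1 - amplitude * sin(pi * d / (2 * dmax))^2
}

# pixels of an elliptical annulus; returns linear indices into H x W
.ring_pixels <- function(cx, cy, a, b, theta, wall, H, W) {
  half <- ceiling(a) + 1L
  rows <- max(1L, floor(cy - half)):min(H, ceiling(cy + half))
  cols <- max(1L, floor(cx - half)):min(W, ceiling(cx + half))
  dy <- rep(rows - cy, times = length(cols))
  dx <- rep(cols - cx, each = length(rows))
  ct <- cos(theta); st <- sin(theta)
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  outer_in <- (u / a)^2 + (v / b)^2 <= 1
  a_in <- a - wall; b_in <- b - wall
  inner_in <- if (a_in > 0 && b_in > 0)
    (u / a_in)^2 + (v / b_in)^2 <= 1 else rep(FALSE, length(u))
  sel <- outer_in & !inner_in
  rr <- rep(rows, times = length(cols))[sel]
  cc <- rep(cols, each = length(rows))[sel]
  (cc - 1L) * H + rr
}

#' Generate a synthetic slide phantom
#'
#' Places non-overlapping elliptical vessel rings by rejection sampling
#' until the target wall-area fraction is reached (within 15\% relative),
#' adds nuclear counterstain blobs, composes intensities by Beer-Lambert,
#' then cuts overlapping tiles with integer stage jitter, applies the
#' per-field vignette and noise, and quantizes.
#'
#' @param params \code{\link{slide_phantom_params}}.
#' @param rois optional \code{roi_set}; when given, per-ROI ground-truth
#'   endothelial areas are included.
#' @return object of class \code{slide_phantom}: \code{tiles} (list of
#'   tile objects), \code{white} (tile-sized white reference),
#'   \code{ground_truth} (vessel mask, true tile offsets, achieved
#'   fraction, quantized clean canvas, per-ROI true EA), and the true
#'   \code{stain_model}.
#' @export
generate_slide_phantom <- function(params, rois = NULL) {
  stopifnot(inherits(params, "slide_phantom_params"))
  set.seed(params$seed)
  H <- as.integer(params$height_px); W <- as.integer(params$width_px)
  p_um <- params$pixel_size_um
  if (params$tile_size_px > min(H, W))
    stop("tile_size_px exceeds canvas dimensions")

  r_px <- params$vessel_radius_range_um / p_um
  wall_px <- params$wall_thickness_um / p_um
  if (params$vessel_area_fraction > 0 && 2 * r_px[1] + 2 > min(H, W))
    stop("vessel radii too large for the canvas")

  a_dab <- matrix(0, H, W)
  vessel_mask <- matrix(FALSE, H, W)
  n_target <- round(params$vessel_area_fraction * H * W)
  achieved <- 0L
  if (n_target > 0) {
    # conservative mean ring area (px) for the attempt budget
    r_mid <- mean(r_px)
    ring_px_est <- max(pi * (r_mid^2 - max(r_mid - wall_px, 0)^2), 1)
    max_attempts <- 10L * max(1L, ceiling(n_target / ring_px_est))
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    attempts <- 0L
    while (achieved < n_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      a <- stats::runif(1, r_px[1], r_px[2])
      ecc <- stats::runif(1, 0, 0.8)
      b <- a * sqrt(1 - ecc^2)
      theta <- stats::runif(1, 0, pi)
      if (2 * a + 2 > min(H, W)) next
      cx <- stats::runif(1, a + 1, W - a)
      cy <- stats::runif(1, a + 1, H - a)
      if (nrow(centers) > 0 &&
          any(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) <
              radii + a + 1)) next
      idx <- .ring_pixels(cx, cy, a, b, theta, wall_px, H, W)
      if (achieved + length(idx) > 1.15 * n_target) next
      a_dab[idx] <- params$dab_od_peak
      vessel_mask[idx] <- TRUE
      achieved <- achieved + length(idx)
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, a)
    }
    if (achieved < 0.85 * n_target)
      stop(sprintf(paste0("vessel_area_fraction %.4f unreachable for the given ",
                          "radius range; achieved at most %.4f"),
                   params$vessel_area_fraction, achieved / (H * W)))
  }

  # nuclear counterstain blobs (round discs, amplitude combined by max)
  a_hema <- matrix(0, H, W)
  area_mm2 <- H * W * p_um^2 / 1e6
  n_nuc <- stats::rpois(1, params$nuclei_density_per_mm2 * area_mm2)
  if (n_nuc > 0) {
    nx <- stats::runif(n_nuc, 1, W)
    ny <- stats::runif(n_nuc, 1, H)
    nr <- stats::runif(n_nuc, 2.5, 4.5) / p_um
    for (i in seq_len(n_nuc)) {
      idx <- .ring_pixels(nx[i], ny[i], nr[i], nr[i], 0, 2 * nr[i], H, W)
      a_hema[idx] <- pmax(a_hema[idx], params$hema_od_peak)
    }
  }

  s_h <- .default_s_hema / sqrt(sum(.default_s_hema^2))
  s_d <- .default_s_dab / sqrt(sum(.default_s_dab^2))
  bg <- rep(params$background_rgb, length.out = 3L)
  clean <- array(0, dim = c(H, W, 3))
  for (c in 1:3)
    clean[, , c] <- bg[c] * 10^(-(a_hema * s_h[c] + a_dab * s_d[c]))

  # tiling grid with integer stage jitter (first tile anchors the frame)
  Tpx <- as.integer(params$tile_size_px)
  stride <- max(1L, as.integer(round(Tpx * (1 - params$overlap_fraction))))
  starts <- function(total) {
    if (total <= Tpx) return(0L)
    s <- seq(0L, total - Tpx, by = stride)
    if (s[length(s)] < total - Tpx) s <- c(s, total - Tpx)
    as.integer(s)
  }
  xs <- starts(W); ys <- starts(H)
  shading <- .shading_field(Tpx, Tpx, params$shading_amplitude)
  white <- array(0, dim = c(Tpx, Tpx, 3))
  for (c in 1:3) white[, , c] <- round(bg[c] * shading)

  tiles <- list()
  offsets <- data.frame(id = character(0), x = integer(0), y = integer(0),
                        stringsAsFactors = FALSE)
  k <- 0L
  for (ri in seq_along(ys)) for (ci in seq_along(xs)) {
    k <- k + 1L
    jit <- if (ri == 1L && ci == 1L) c(0L, 0L) else
      sample(-3:3, 2L, replace = TRUE)
    x0 <- min(max(xs[ci] + jit[1], 0L), W - Tpx)
    y0 <- min(max(ys[ri] + jit[2], 0L), H - Tpx)
    block <- clean[y0 + seq_len(Tpx), x0 + seq_len(Tpx), , drop = FALSE]
    for (c in 1:3) {
      v <- block[, , c] * shading
      if (params$noise_sd > 0)
        v <- v + stats::rnorm(length(v), 0, params$noise_sd)
      block[, , c] <- round(pmin(pmax(v, 0), 255))
    }
    id <- sprintf("r%02dc%02d", ri, ci)
    tiles[[k]] <- list(pixels = block, grid_pos = c(ri, ci),
                       nominal_offset_px = c(xs[ci], ys[ri]), id = id)
    offsets <- rbind(offsets, data.frame(id = id, x = x0, y = y0,
                                         stringsAsFactors = FALSE))
  }

  true_ea <- NULL
  if (!is.null(rois)) {
    stopifnot(inherits(rois, "roi_set"))
    true_ea <- vapply(rois$rois, function(r) {
      m <- roi_mask(r, c(H, W), p_um)
      sum(vessel_mask & m) * p_um^2 / 1e6
    }, numeric(1))
    names(true_ea) <- vapply(rois$rois, `[[`, character(1), "id")
  }

  structure(list(
    tiles = tiles, white = white,
    ground_truth = list(vessel_mask = vessel_mask, tile_offsets = offsets,
                        achieved_fraction = achieved / (H * W),
                        canvas = round(clean),
                        true_ea_mm2_per_roi = true_ea),
    stain_model = stain_model(s_h, s_d, bg),
    pixel_size_um = p_um, params = params), class = "slide_phantom")
}

#' @export
print.slide_phantom <- function(x, ...) {
  cat(sprintf("Slide phantom: %d x %d px at %.2f um/px, %d tiles\n",
              x$params$height_px, x$params$width_px, x$pixel_size_um,
              length(x$tiles)))
  cat(sprintf("  vessel wall fraction: target %.4f, achieved %.4f\n",
              x$params$vessel_area_fraction, x$ground_truth$achieved_fraction))
  invisible(x)
}
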