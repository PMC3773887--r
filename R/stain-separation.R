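# Reference-shade (stain-vector) optical-density model for two-stain
# brightfield IHC: Hematoxylin counterstain + CD34-DAB chromogen.

#' Convert RGB intensities to optical density
#'
#' Applies the Beer-Lambert transform per channel,
#' \eqn{OD_c = -\log_{10}(I_c / I_{0,c})}, against the acquisition
#' background intensity. Intensities are floored at 1 so OD stays finite,
#' OD is clipped below at 0 (intensities above background carry no stain)
#' and capped at 3 (camera dynamic-range limit).
#'
#' @param image numeric array (H x W x 3) or matrix (n x 3) of intensities
#'   in [0, 255].
#' @param background_i0 per-channel background intensity, default
#'   \code{c(235, 235, 235)} (the standardized acquisition background).
#' @return array/matrix of the same shape with per-channel OD values.
#' @export
rgb_to_od <- function(image, background_i0 = c(235, 235, 235)) {
  if (any(background_i0 <= 0)) stop("background_i0 channels must be > 0")
  i0 <- rep(background_i0, length.out = 3L)
  od <- .per_channel(image, function(x, c) {
    v <- -log10(pmax(x, 1) / i0[c])
    pmin(pmax(v, 0), 3)
  })
  od
}

#' Convert optical density back to RGB intensities
#'
#' Exact inverse of \code{\link{rgb_to_od}} before quantization:
#' \eqn{I_c = I_{0,c} \cdot 10^{-OD_c}}.
#'
#' @inheritParams rgb_to_od
#' @param od numeric array (H x W x 3) or matrix (n x 3) of OD values.
#' @return intensities on the same shape (float; quantize at write time).
#' @export
od_to_rgb <- function(od, background_i0 = c(235, 235, 235)) {
  if (any(od < 0)) stop("negative OD input")
  i0 <- rep(background_i0, length.out = 3L)
  .per_channel(od, function(x, c) i0[c] * 10^(-x))
}

# apply f(values, channel) channelwise to HxWx3 arrays or nx3 matrices
.per_channel <- function(x, f) {
  if (is.matrix(x) && ncol(x) == 3L) {
    for (c in 1:3) x[, c] <- f(x[, c], c)
    return(x)
  }
  d <- dim(x)
  if (length(d) != 3L || d[3] != 3L) stop("expected H x W x 3 array or n x 3 matrix")
  for (c in 1:3) x[, , c] <- f(x[, , c], c)
  x
}

# exact non-negative least squares for the two-variable stain fit:
# unconstrained solve; if infeasible the optimum is on a boundary of the
# quadrant, so the two single-stain candidates are compared
.clamped_ls <- function(P, sh, sd_) {
  g <- sum(sh * sd_)            # unit vectors: Gram matrix [[1, g], [g, 1]]
  th <- as.numeric(P %*% sh)
  td <- as.numeric(P %*% sd_)
  det_g <- 1 - g^2
  ah <- (th - g * td) / det_g
  ad <- (td - g * th) / det_g
  neg <- ah < 0 | ad < 0
  if (any(neg)) {
    ah1 <- pmax(th[neg], 0)                     # ad = 0 candidate
    ad2 <- pmax(td[neg], 0)                     # ah = 0 candidate
    # residual^2 = |od|^2 + q with q = a'Ga - 2 a.t; compare candidates
    q1 <- ah1^2 - 2 * ah1 * th[neg]
    q2 <- ad2^2 - 2 * ad2 * td[neg]
    use1 <- q1 <= q2
    ah[neg] <- ifelse(use1, ah1, 0)
    ad[neg] <- ifelse(use1, 0, ad2)
  }
  r2 <- rowSums(P^2) - 2 * (ah * th + ad * td) + ah^2 + ad^2 + 2 * g * ah * ad
  list(ah = ah, ad = ad, residual = sqrt(pmax(r2, 0)))
}

.as_pixel_matrix <- function(x) {
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  d <- dim(x)
  if (length(d) == 3L && d[3] == 3L) return(matrix(x, ncol = 3L))
  stop("expected H x W x 3 array or n x 3 matrix")
}

#' Fit a two-stain reference-shade model from training pixels
#'
#' Estimates unit-norm OD stain vectors for Hematoxylin and CD34-DAB from
#' user-indicated pixels of each stain. The base estimate is the normalized
#' mean OD vector of each training set. Because training pixels in tissue
#' are rarely pure, up to \code{max_rounds} alternating refinement rounds
#' follow: each set's OD vectors have their component along the other
#' stain's current vector removed (floored at 0 componentwise) before
#' re-averaging and re-normalizing. Iteration stops when both vectors move
#' by less than 1e-6; the clamped non-negative fit is what lets partially
#' contaminated training sets drift back to the true stain direction, and
#' that drift needs a few tens of rounds.
#'
#' @param hema_pixels,dab_pixels n x 3 matrices of RGB training pixels
#'   (at least 10 each).
#' @param background_i0 background intensity triple.
#' @param max_rounds maximum refinement rounds (default 100).
#' @return an object of class \code{stain_model}: background, unit OD
#'   vectors \code{s_hema}, \code{s_dab}, and the condition number of the
#'   3 x 2 stain matrix.
#' @export
fit_stain_model <- function(hema_pixels, dab_pixels,
                            background_i0 = c(235, 235, 235),
                            max_rounds = 100L) {
  hema_pixels <- .as_pixel_matrix(hema_pixels)
  dab_pixels <- .as_pixel_matrix(dab_pixels)
  if (nrow(hema_pixels) < 10L || nrow(dab_pixels) < 10L)
    stop("at least 10 training pixels per stain are required")
  od_h <- rgb_to_od(hema_pixels, background_i0)
  od_d <- rgb_to_od(dab_pixels, background_i0)

  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop("training set has zero mean optical density")
    v / n
  }
  s_h <- unit(colMeans(od_h))
  s_d <- unit(colMeans(od_d))

  for (round in seq_len(max_rounds)) {
    # remove the other stain's fitted contribution from each training set
    # (non-negative two-variable fit, so pure training data is untouched),
    # floor at 0 componentwise
    fit_h <- .clamped_ls(od_h, s_h, s_d)
    fit_d <- .clamped_ls(od_d, s_h, s_d)
    resid_h <- pmax(od_h - outer(fit_h$ad, s_d), 0)
    resid_d <- pmax(od_d - outer(fit_d$ah, s_h), 0)
    s_h_new <- unit(colMeans(resid_h))
    s_d_new <- unit(colMeans(resid_d))
    moved <- max(sqrt(sum((s_h_new - s_h)^2)), sqrt(sum((s_d_new - s_d)^2)))
    s_h <- s_h_new
    s_d <- s_d_new
    if (moved < 1e-6) break
  }
  stain_model(s_h, s_d, background_i0)
}

#' Construct a stain model from explicit OD vectors
#'
#' @param s_hema,s_dab non-negative OD 3-vectors (normalized internally).
#' @param background_i0 background intensity triple.
#' @return \code{stain_model} object.
#' @export
stain_model <- function(s_hema, s_dab, background_i0 = c(235, 235, 235)) {
  s_hema <- s_hema / sqrt(sum(s_hema^2))
  s_dab <- s_dab / sqrt(sum(s_dab^2))
  if (any(s_hema < 0) || any(s_dab < 0))
    stop("stain vectors must be non-negative componentwise")
  ang <- stain_angle_deg(s_hema, s_dab)
  if (ang < 5)
    stop(sprintf("ill-conditioned stain model: vectors %0.2f degrees apart (< 5)", ang))
  S <- cbind(s_hema, s_dab)
  sv <- svd(S)$d
  structure(
    list(background_i0 = rep(background_i0, length.out = 3L),
         s_hema = as.numeric(s_hema), s_dab = as.numeric(s_dab),
         angle_deg = ang, condition_number = sv[1] / sv[2]),
    class = "stain_model")
}

#' Angle between two stain vectors in degrees
#' @param a,b OD 3-vectors.
#' @return angle in degrees.
#' @export
stain_angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}

#' @export
print.stain_model <- function(x, ...) {
  cat("Two-stain reference-shade model\n")
  cat(sprintf("  background I0: (%s)\n", paste(round(x$background_i0, 1), collapse = ", ")))
  cat(sprintf("  s_hema: (%s)\n", paste(sprintf("%.4f", x$s_hema), collapse = ", ")))
  cat(sprintf("  s_dab:  (%s)\n", paste(sprintf("%.4f", x$s_dab), collapse = ", ")))
  cat(sprintf("  angle: %.1f deg, condition number %.2f\n",
              x$angle_deg, x$condition_number))
  invisible(x)
}

#' Unmix an OD image into Hematoxylin and DAB abundance maps
#'
#' Per pixel solves \eqn{\min_{a_H, a_D \ge 0} \|OD - a_H s_H - a_D s_D\|_2}.
#' The unconstrained two-variable least-squares solution is used when
#' feasible; otherwise the optimum lies on a boundary of the non-negative
#' quadrant, so the two single-stain candidates (the other abundance
#' clamped to 0 and the remaining coefficient re-solved, floored at 0)
#' are evaluated and the lower-residual one taken. Exact for this convex
#' two-variable problem.
#'
#' @param od OD array (H x W x 3) or matrix (n x 3).
#' @param model \code{stain_model}.
#' @return object of class \code{abundance_maps}: \code{a_hema},
#'   \code{a_dab} and \code{residual} (OD misfit norm), each H x W
#'   (or vectors for matrix input).
#' @export
unmix <- function(od, model) {
  stopifnot(inherits(model, "stain_model"))
  d <- dim(od)
  P <- .as_pixel_matrix(od)
  fit <- .clamped_ls(P, model$s_hema, model$s_dab)
  ah <- fit$ah; ad <- fit$ad; res <- fit$residual
  if (length(d) == 3L) {
    dim(ah) <- d[1:2]; dim(ad) <- d[1:2]; dim(res) <- d[1:2]
  }
  structure(list(a_hema = ah, a_dab = ad, residual = res), class = "abundance_maps")
}

#' Write a stain model to JSON
#' @param model \code{stain_model}.
#' @param path output file.
#' @export
write_stain_model <- function(model, path) {
  stopifnot(inherits(model, "stain_model"))
  jsonlite::write_json(
    list(background_i0 = model$background_i0,
         s_hema = model$s_hema, s_dab = model$s_dab),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a stain model from JSON
#' @param path JSON file written by \code{\link{write_stain_model}}.
#' @return \code{stain_model}.
#' @export
read_stain_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_model(x$s_hema, x$s_dab, x$background_i0)
}
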