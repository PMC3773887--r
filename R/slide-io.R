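# Virtual-slide assembly: flat-field shading compensation against a
# white reference, overlap-based integer translation refinement, and
# stitching with a single-coverage seam rule.

.tile_pixels <- function(tile) if (is.list(tile) && !is.null(tile$pixels)) tile$pixels else tile

#' Flat-field shading compensation
#'
#' Divides out the acquisition vignette using a non-saturated white
#' reference: \code{out_c(x) = round(clip(tile_c(x) * target_c / white_c(x),
#' 0, 255))}. Deterministic.
#'
#' @param tile tile object or H x W x 3 intensity array.
#' @param white white-reference array of the same dimensions, strictly
#'   positive everywhere.
#' @param target target background intensity (scalar or triple,
#'   default 235).
#' @return corrected tile (same type as the input).
#' @export
shading_correct <- function(tile, white, target = c(235, 235, 235)) {
  px <- .tile_pixels(tile)
  if (!all(dim(px) == dim(white))) stop("tile and white dimensions differ")
  bad <- which(white <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("white reference not strictly positive at pixel (%d, %d)",
                 bad[1, 1], bad[1, 2]))
  target <- rep(target, length.out = 3L)
  out <- px
  for (c in 1:3)
    out[, , c] <- round(pmin(pmax(px[, , c] * target[c] / white[, , c], 0), 255))
  if (is.list(tile) && !is.null(tile$pixels)) { tile$pixels <- out; tile } else out
}

.grayscale <- function(px) (px[, , 1] + px[, , 2] + px[, , 3]) / 3

#' Refine a tile-pair offset from the overlap content
#'
#' Searches integer shifts within \code{search_radius_px} of the nominal
#' offset for the one maximizing normalized cross-correlation of the
#' grayscale overlap regions. To bound cost on large tiles, correlation is
#' computed on a central patch of the overlap (up to
#' \code{max_patch_px} per side). If the best correlation is below 0.2
#' (featureless overlap) the nominal offset is returned with a fallback
#' flag.
#'
#' @param tile_a,tile_b tile objects or intensity arrays.
#' @param nominal_offset integer (x, y) position of \code{tile_b}
#'   relative to \code{tile_a}.
#' @param search_radius_px half-width of the search window (default 8).
#' @param max_patch_px cap on the correlation patch side (default 256).
#' @return list with \code{offset} (refined (x, y)), \code{correlation},
#'   and \code{fallback} (TRUE if the nominal offset was kept).
#' @export
register_overlap <- function(tile_a, tile_b, nominal_offset,
                             search_radius_px = 8L, max_patch_px = 256L) {
  ga <- .grayscale(.tile_pixels(tile_a))
  gb <- .grayscale(.tile_pixels(tile_b))
  Ha <- nrow(ga); Wa <- ncol(ga); Hb <- nrow(gb); Wb <- ncol(gb)
  ox <- as.integer(round(nominal_offset[1])); oy <- as.integer(round(nominal_offset[2]))
  r <- as.integer(search_radius_px)

  # overlap of a:[0,Wa)x[0,Ha) with b at (ox,oy), shrunk by the search
  # radius so every candidate shift compares the same a-region
  x0 <- max(0L, ox) ; x1 <- min(Wa, ox + Wb)
  y0 <- max(0L, oy) ; y1 <- min(Ha, oy + Hb)
  if (x1 - x0 <= 0 || y1 - y0 <= 0) stop("tiles do not overlap at the nominal offset")
  x0 <- x0 + r; x1 <- x1 - r; y0 <- y0 + r; y1 <- y1 - r
  if (x1 - x0 < 2 || y1 - y0 < 2)
    stop("overlap too small for the requested search radius")
  # central patch cap
  if (x1 - x0 > max_patch_px) {
    cx <- (x0 + x1) %/% 2L
    x0 <- cx - max_patch_px %/% 2L; x1 <- x0 + max_patch_px
  }
  if (y1 - y0 > max_patch_px) {
    cy <- (y0 + y1) %/% 2L
    y0 <- cy - max_patch_px %/% 2L; y1 <- y0 + max_patch_px
  }
  pa <- as.vector(ga[(y0 + 1):y1, (x0 + 1):x1])
  best <- -Inf; best_dx <- 0L; best_dy <- 0L
  for (dy in -r:r) for (dx in -r:r) {
    bx0 <- x0 - (ox + dx); by0 <- y0 - (oy + dy)
    pb <- as.vector(gb[(by0 + 1):(by0 + (y1 - y0)), (bx0 + 1):(bx0 + (x1 - x0))])
    if (stats::sd(pa) == 0 || stats::sd(pb) == 0) next
    cc <- stats::cor(pa, pb)
    if (!is.na(cc) && cc > best) { best <- cc; best_dx <- dx; best_dy <- dy }
  }
  if (!is.finite(best) || best < 0.2)
    return(list(offset = c(ox, oy), correlation = if (is.finite(best)) best else NA_real_,
                fallback = TRUE))
  list(offset = c(ox + best_dx, oy + best_dy), correlation = best, fallback = FALSE)
}

#' Assemble tiles into a virtual slide
#'
#' Places each tile at its refined offset on a canvas sized to the
#' bounding box of all placements. In overlap regions the pixel is taken
#' from the tile whose centre is nearest (seam at the overlap midline) —
#' a single-coverage rule, so downstream area measurements never
#' double-count; ties keep the earlier-placed tile.
#'
#' @param tiles list of tile objects.
#' @param refined_offsets data frame (id, x, y) of absolute integer
#'   offsets, or NULL to use each tile's nominal offset.
#' @param pixel_size_um physical pixel size, um.
#' @return object of class \code{virtual_slide}: \code{pixels},
#'   \code{pixel_size_um} and \code{provenance}.
#' @export
assemble_virtual_slide <- function(tiles, refined_offsets = NULL, pixel_size_um) {
  ids <- vapply(tiles, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate tile placement: ids must be unique")
  if (is.null(refined_offsets)) {
    refined_offsets <- data.frame(
      id = ids,
      x = vapply(tiles, function(t) t$nominal_offset_px[1], numeric(1)),
      y = vapply(tiles, function(t) t$nominal_offset_px[2], numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(refined_offsets$id)) stop("duplicate tile placement in offsets")
  off <- refined_offsets[match(ids, refined_offsets$id), ]
  if (anyNA(off$x)) stop("missing offsets for some tiles")
  hs <- vapply(tiles, function(t) nrow(.tile_pixels(t)), integer(1))
  ws <- vapply(tiles, function(t) ncol(.tile_pixels(t)), integer(1))
  x_min <- min(off$x); y_min <- min(off$y)
  W <- as.integer(max(off$x + ws) - x_min)
  H <- as.integer(max(off$y + hs) - y_min)
  canvas <- array(0, dim = c(H, W, 3))
  dist2 <- matrix(Inf, H, W)
  for (i in seq_along(tiles)) {
    px <- .tile_pixels(tiles[[i]])
    h <- hs[i]; w <- ws[i]
    rows <- (off$y[i] - y_min) + seq_len(h)
    cols <- (off$x[i] - x_min) + seq_len(w)
    d2 <- outer((seq_len(h) - (h + 1) / 2)^2, (seq_len(w) - (w + 1) / 2)^2, `+`)
    better <- d2 < dist2[rows, cols]
    if (any(better)) {
      dist2[rows, cols][better] <- d2[better]
      for (c in 1:3) {
        sub <- canvas[rows, cols, c]
        sub[better] <- px[, , c][better]
        canvas[rows, cols, c] <- sub
      }
    }
  }
  structure(list(pixels = canvas, pixel_size_um = pixel_size_um,
                 provenance = list(tile_ids = ids,
                                   offsets = off,
                                   origin = c(x = x_min, y = y_min))),
            class = "virtual_slide")
}

#' @export
print.virtual_slide <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Virtual slide: %d x %d px at %g um/px (%d tiles)\n",
              d[1], d[2], x$pixel_size_um, length(x$provenance$tile_ids)))
  invisible(x)
}

#' Shading-correct, register and stitch a tile set
#'
#' The full assembly path: every tile is flat-field corrected against the
#' white reference, then offsets are refined by chaining pairwise overlap
#' registration along the grid (each tile against its left neighbour, or
#' the tile above for the first column; the first tile anchors the frame
#' at its nominal offset), and the set is stitched.
#'
#' @param tiles list of tile objects (with grid_pos and
#'   nominal_offset_px).
#' @param white white-reference array, or NULL to skip shading
#'   correction.
#' @param pixel_size_um physical pixel size, um.
#' @param target background target intensity (default 235).
#' @param register refine offsets from overlap content (default TRUE).
#' @param search_radius_px registration search radius.
#' @return \code{virtual_slide}.
#' @export
stitch_tiles <- function(tiles, white = NULL, pixel_size_um,
                         target = c(235, 235, 235), register = TRUE,
                         search_radius_px = 8L) {
  if (!is.null(white))
    tiles <- lapply(tiles, shading_correct, white = white, target = target)
  grid <- t(vapply(tiles, `[[`, numeric(2), "grid_pos"))
  ids <- vapply(tiles, `[[`, character(1), "id")
  nom <- t(vapply(tiles, `[[`, numeric(2), "nominal_offset_px"))
  refined <- nom
  n_fallback <- 0L
  if (register && length(tiles) > 1) {
    ord <- order(grid[, 1], grid[, 2])
    for (i in ord) {
      r <- grid[i, 1]; c <- grid[i, 2]
      if (r == min(grid[, 1]) && c == min(grid[, 2])) next
      j <- if (c > min(grid[, 2]))
        which(grid[, 1] == r & grid[, 2] == c - 1) else
        which(grid[, 1] == r - 1 & grid[, 2] == c)
      if (length(j) != 1) next
      rel_nom <- nom[i, ] - nom[j, ]
      reg <- register_overlap(tiles[[j]], tiles[[i]], rel_nom,
                              search_radius_px = search_radius_px)
      if (reg$fallback) n_fallback <- n_fallback + 1L
      refined[i, ] <- refined[j, ] + reg$offset
    }
  }
  off <- data.frame(id = ids, x = as.integer(round(refined[, 1])),
                    y = as.integer(round(refined[, 2])),
                    stringsAsFactors = FALSE)
  slide <- assemble_virtual_slide(tiles, off, pixel_size_um)
  slide$provenance$shading_corrected <- !is.null(white)
  slide$provenance$registered <- isTRUE(register)
  slide$provenance$registration_fallbacks <- n_fallback
  slide
}

#' Read an image file as a 0-255 intensity array
#' @param path PNG or TIFF file.
#' @return H x W x 3 numeric array in [0, 255].
#' @export
read_image <- function(path) {
  x <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::readTIFF(path)
  else stop("unsupported image format: ", path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' Write a 0-255 intensity array to PNG or TIFF
#' @param pixels H x W x 3 array in [0, 255] (or H x W matrix).
#' @param path output file (.png or .tif/.tiff).
#' @export
write_image <- function(pixels, path) {
  x <- pmin(pmax(pixels / 255, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(x, path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::writeTIFF(x, path)
  else stop("unsupported image format: ", path)
  invisible(path)
}

#' Write a tile set with manifest and white reference
#'
#' Tiles are written as PNG with a JSON manifest (ids, grid positions,
#' nominal offsets, pixel size) and the white reference alongside.
#'
#' @param tiles list of tile objects.
#' @param white white-reference array (or NULL).
#' @param dir output directory (created if needed).
#' @param pixel_size_um physical pixel size, um.
#' @export
write_tileset <- function(tiles, white, dir, pixel_size_um) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(pixel_size_um = jsonlite::unbox(pixel_size_um),
                   tiles = lapply(tiles, function(t)
                     list(id = jsonlite::unbox(t$id),
                          file = jsonlite::unbox(paste0(t$id, ".png")),
                          grid_pos = as.integer(t$grid_pos),
                          nominal_offset_px = as.integer(t$nominal_offset_px))))
  for (t in tiles) write_image(t$pixels, file.path(dir, paste0(t$id, ".png")))
  if (!is.null(white)) {
    write_image(white, file.path(dir, "white.png"))
    manifest$white <- jsonlite::unbox("white.png")
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), digits = NA)
  invisible(dir)
}

#' Read a tile set written by \code{\link{write_tileset}}
#' @param dir tile-set directory containing manifest.json.
#' @return list with \code{tiles}, \code{white} (or NULL) and
#'   \code{pixel_size_um}.
#' @export
read_tileset <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = FALSE)
  tiles <- lapply(m$tiles, function(t)
    list(pixels = read_image(file.path(dir, t$file)),
         grid_pos = unlist(t$grid_pos),
         nominal_offset_px = unlist(t$nominal_offset_px),
         id = t$id))
  white <- if (!is.null(m$white)) read_image(file.path(dir, m$white)) else NULL
  list(tiles = tiles, white = white, pixel_size_um = m$pixel_size_um)
}
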