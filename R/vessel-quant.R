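# Endothelial-area extraction from the CD34-DAB abundance map: global
# manual OD threshold, connected-component object model, morphological
# flags, manual correction ledger, and area measurement.

#' Detection parameters for endothelial-area extraction
#'
#' The DAB OD threshold is global and manual: in the study design one
#' threshold is chosen by iterative visual review and applied to every
#' sample. Objects more eccentric than \code{max_eccentricity_flag} are
#' flagged as fibroblast-like but never auto-removed; removal is a manual
#' ledger decision.
#'
#' @param dab_od_threshold DAB abundance (OD amount) threshold, > 0.
#' @param min_object_area_um2 smallest kept component, um^2 (default 20,
#'   suppresses single-pixel noise).
#' @param connectivity 4 or 8 (default 8).
#' @param fill_holes fill object holes before component definition
#'   (vessel lumens are unstained); lumen pixels still never count
#'   towards endothelial area.
#' @param max_eccentricity_flag eccentricity above which an object is
#'   flagged fibroblast-like (default 0.95).
#' @return object of class \code{detection_params}.
#' @export
detection_params <- function(dab_od_threshold, min_object_area_um2 = 20,
                             connectivity = 8L, fill_holes = TRUE,
                             max_eccentricity_flag = 0.95) {
  if (!is.numeric(dab_od_threshold) || dab_od_threshold <= 0)
    stop("dab_od_threshold must be > 0")
  if (min_object_area_um2 < 0) stop("min_object_area_um2 must be >= 0")
  stopifnot(connectivity %in% c(4L, 8L))
  structure(list(dab_od_threshold = dab_od_threshold,
                 min_object_area_um2 = min_object_area_um2,
                 connectivity = as.integer(connectivity),
                 fill_holes = isTRUE(fill_holes),
                 max_eccentricity_flag = max_eccentricity_flag),
            class = "detection_params")
}

#' Threshold the DAB abundance map
#'
#' @param a_dab numeric matrix of DAB abundances (from \code{\link{unmix}}).
#' @param params \code{detection_params}.
#' @return logical mask; pixel positive iff abundance >= threshold
#'   (inclusive comparison).
#' @export
threshold_dab <- function(a_dab, params) {
  stopifnot(inherits(params, "detection_params"))
  if (inherits(a_dab, "abundance_maps")) a_dab <- a_dab$a_dab
  a_dab >= params$dab_od_threshold
}

# second-moment eccentricity of a pixel set (rows, cols)
.pixel_eccentricity <- function(rows, cols) {
  n <- length(rows)
  if (n < 2) return(0)
  mu20 <- stats::var(cols) * (n - 1) / n
  mu02 <- stats::var(rows) * (n - 1) / n
  mu11 <- stats::cov(cols, rows) * (n - 1) / n
  tr <- mu20 + mu02
  det_ <- mu20 * mu02 - mu11^2
  disc <- sqrt(pmax(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(pmax(1 - l2 / l1, 0))
}

#' Extract vessel objects from a binary DAB mask
#'
#' Connected components at the chosen connectivity define candidate
#' objects (on the hole-filled mask when \code{fill_holes}). The object
#' area is the endothelial (mask) area only: lumen pixels gained by hole
#' filling shape the object but are excluded from area. Components below
#' the minimum area are dropped; overly eccentric objects are flagged as
#' fibroblast-like and retained pending ledger review.
#'
#' @param mask logical matrix from \code{\link{threshold_dab}}.
#' @param params \code{detection_params}.
#' @param pixel_size_um physical pixel size, um.
#' @return object of class \code{vessel_objects}: a data frame
#'   \code{$objects} (label, area_um2, centroid, eccentricity, source,
#'   flags), per-object mask-pixel indices \code{$pixels}, the mask
#'   dimensions and pixel size.
#' @export
extract_objects <- function(mask, params, pixel_size_um) {
  stopifnot(inherits(params, "detection_params"), pixel_size_um > 0)
  mode(mask) <- "logical"
  shape <- mask
  if (params$fill_holes && any(mask))
    shape <- EBImage::fillHull(mask * 1L) > 0
  lab <- label_components(shape, params$connectivity)
  n <- max(lab)
  px_area <- pixel_size_um^2
  objects <- list(); pixels <- list()
  keep <- 0L
  if (n > 0) {
    idx_by_lab <- split(which(lab > 0), lab[lab > 0])
    H <- nrow(mask)
    for (k in seq_len(n)) {
      comp <- idx_by_lab[[k]]
      wall <- comp[mask[comp]]         # endothelium only, lumen excluded
      area <- length(wall) * px_area
      if (area < params$min_object_area_um2 || area <= 0) next
      rows <- ((comp - 1L) %% H) + 1L
      cols <- ((comp - 1L) %/% H) + 1L
      ecc <- .pixel_eccentricity(rows, cols)
      keep <- keep + 1L
      objects[[keep]] <- data.frame(
        label = keep,
        area_um2 = area,
        centroid_x_um = (mean(cols) - 0.5) * pixel_size_um,
        centroid_y_um = (mean(rows) - 0.5) * pixel_size_um,
        eccentricity = ecc,
        source = "auto",
        flags = if (ecc > params$max_eccentricity_flag) "fibroblast-like" else "",
        stringsAsFactors = FALSE)
      pixels[[keep]] <- wall
    }
  }
  objects <- if (keep > 0) do.call(rbind, objects) else
    data.frame(label = integer(0), area_um2 = numeric(0),
               centroid_x_um = numeric(0), centroid_y_um = numeric(0),
               eccentricity = numeric(0), source = character(0),
               flags = character(0), stringsAsFactors = FALSE)
  structure(list(objects = objects, pixels = pixels,
                 dim = dim(mask), pixel_size_um = pixel_size_um,
                 counts = c(auto = keep, manual = 0L, deleted = 0L)),
            class = "vessel_objects")
}

#' @export
print.vessel_objects <- function(x, ...) {
  cat(sprintf("Vessel objects: %d auto, %d manual, %d deleted\n",
              x$counts["auto"], x$counts["manual"], x$counts["deleted"]))
  cat(sprintf("  total endothelial area: %.1f um^2\n", sum(x$objects$area_um2)))
  invisible(x)
}

#' Create a manual-correction ledger
#'
#' Ordered add/delete events mirroring interactive validation: vessels the
#' automatic threshold missed are added as polygons; detected objects that
#' are not vessels (fibroblasts, artefacts, background) are deleted by
#' label.
#'
#' @param events list of events, each a list with \code{type} ("add" or
#'   "delete"), \code{target} (an n x 2 polygon matrix in um for adds, an
#'   object label for deletes), optional \code{note} and \code{timestamp}.
#' @return object of class \code{correction_ledger}.
#' @export
correction_ledger <- function(events = list()) {
  for (e in events) {
    if (!e$type %in% c("add", "delete")) stop("event type must be add or delete")
  }
  structure(list(events = events), class = "correction_ledger")
}

# shoelace polygon area (um^2); vertices n x 2, open (not repeated)
.polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) && ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  seg <- function(i) list(p[i, ], p[if (i == n) 1L else i + 1L, ])
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(i - j) <= 1L || (i == 1L && j == n)) next   # adjacent share a vertex
    a <- seg(i); b <- seg(j)
    if (.segments_cross(a[[1]], a[[2]], b[[1]], b[[2]])) return(TRUE)
  }
  FALSE
}

# even-odd point-in-polygon for pixel centres inside the bounding box;
# returns linear indices into an H x W matrix
.rasterize_polygon <- function(poly_um, dims, pixel_size_um) {
  H <- dims[1]; W <- dims[2]
  r_rng <- range(poly_um[, 2]) / pixel_size_um + 0.5
  c_rng <- range(poly_um[, 1]) / pixel_size_um + 0.5
  rows <- max(1L, floor(r_rng[1])):min(H, ceiling(r_rng[2]))
  cols <- max(1L, floor(c_rng[1])):min(W, ceiling(c_rng[2]))
  if (!length(rows) || !length(cols)) return(integer(0))
  cx <- (cols - 0.5) * pixel_size_um
  cy <- (rows - 0.5) * pixel_size_um
  px <- rep(cx, each = length(cy))
  py <- rep(cy, times = length(cx))
  inside <- rep(FALSE, length(px))
  n <- nrow(poly_um)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_um[i, 1]; yi <- poly_um[i, 2]
    xj <- poly_um[j, 1]; yj <- poly_um[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  (cc[inside] - 1L) * H + rr[inside]
}

#' Apply a manual-correction ledger to detected objects
#'
#' Events are applied in order: deletes remove the referenced object,
#' adds rasterize their polygon and append a manual-source object whose
#' area is the polygon (shoelace) area.
#'
#' @param objects \code{vessel_objects} from \code{\link{extract_objects}}.
#' @param ledger \code{correction_ledger}.
#' @param pixel_size_um physical pixel size, um.
#' @return corrected \code{vessel_objects}; \code{$counts} reports auto,
#'   manual and deleted totals.
#' @export
apply_corrections <- function(objects, ledger, pixel_size_um = objects$pixel_size_um) {
  stopifnot(inherits(objects, "vessel_objects"), inherits(ledger, "correction_ledger"))
  obj <- objects$objects
  px <- objects$pixels
  deleted <- 0L; added <- 0L
  for (e in ledger$events) {
    if (e$type == "delete") {
      i <- match(e$target, obj$label)
      if (is.na(i)) stop(sprintf("delete of unknown object label %s", e$target))
      obj <- obj[-i, , drop = FALSE]
      px <- px[-i]
      deleted <- deleted + 1L
    } else {
      poly <- e$target
      if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L)
        stop("add event target must be an n x 2 polygon matrix (n >= 3)")
      if (.polygon_self_intersects(poly)) stop("add polygon is self-intersecting")
      new_label <- if (nrow(obj)) max(obj$label) + 1L else 1L
      idx <- .rasterize_polygon(poly, objects$dim, pixel_size_um)
      obj <- rbind(obj, data.frame(
        label = new_label, area_um2 = .polygon_area(poly),
        centroid_x_um = mean(poly[, 1]), centroid_y_um = mean(poly[, 2]),
        eccentricity = NA_real_, source = "manual", flags = "",
        stringsAsFactors = FALSE))
      px <- c(px, list(idx))
      added <- added + 1L
    }
  }
  structure(list(objects = obj, pixels = px, dim = objects$dim,
                 pixel_size_um = pixel_size_um,
                 counts = c(auto = unname(objects$counts["auto"]),
                            manual = added, deleted = deleted)),
            class = "vessel_objects")
}

#' Measure endothelial area inside an ROI
#'
#' EA is the physical area of the union of validated object pixels that
#' fall inside the ROI mask. Using the pixel union (single coverage)
#' guarantees EA never exceeds the analyzed area.
#'
#' @param objects \code{vessel_objects}.
#' @param roi_mask logical mask in slide coordinates (same dimensions as
#'   the object map).
#' @param pixel_size_um physical pixel size, um.
#' @return endothelial area in mm^2.
#' @export
measure_endothelial_area <- function(objects, roi_mask,
                                     pixel_size_um = objects$pixel_size_um) {
  stopifnot(inherits(objects, "vessel_objects"))
  if (!all(dim(roi_mask) == objects$dim))
    stop("roi_mask dimensions do not match the object map")
  if (!length(objects$pixels)) return(0)
  idx <- unique(unlist(objects$pixels, use.names = FALSE))
  sum(roi_mask[idx]) * pixel_size_um^2 / 1e6
}

#' Write a correction ledger to JSON
#' @param ledger \code{correction_ledger}.
#' @param path output file.
#' @export
write_ledger <- function(ledger, path) {
  ev <- lapply(ledger$events, function(e) {
    out <- list(type = jsonlite::unbox(e$type))
    out$target <- if (e$type == "delete") jsonlite::unbox(e$target) else e$target
    if (!is.null(e$note)) out$note <- jsonlite::unbox(e$note)
    if (!is.null(e$timestamp)) out$timestamp <- jsonlite::unbox(e$timestamp)
    out
  })
  jsonlite::write_json(list(events = ev), path, digits = NA)
  invisible(path)
}

#' Read a correction ledger from JSON
#' @param path JSON file.
#' @return \code{correction_ledger}.
#' @export
read_ledger <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  events <- lapply(x$events, function(e) {
    target <- if (e$type == "add")
      matrix(unlist(e$target), ncol = 2L, byrow = TRUE) else e$target
    list(type = e$type, target = target, note = e$note, timestamp = e$timestamp)
  })
  correction_ledger(events)
}

#' Export the object table as CSV
#' @param objects \code{vessel_objects}.
#' @param path output CSV.
#' @export
write_object_table <- function(objects, path) {
  utils::write.csv(objects$objects, path, row.names = FALSE)
  invisible(path)
}
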