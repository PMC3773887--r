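# Compartment-labelled circular regions of interest: tumour-associated
# stroma (TAS, green), tumour parenchyma (T, blue), invasive front
# (IF, red). Slide physical coordinates are in micrometres, origin at the
# canvas top-left corner, x rightward, y downward.

#' Compartment labels and their display colours
#' @return named character vector mapping compartment to display colour.
#' @export
compartments <- function() c(TAS = "green", T = "blue", IF = "red")

#' Define a circular region of interest
#'
#' @param id unique ROI identifier.
#' @param center_um numeric (x, y) centre in slide coordinates, um.
#' @param compartment one of \code{"TAS"}, \code{"T"}, \code{"IF"}.
#' @param diameter_um disc diameter in um (default 1000, i.e. 1 mm).
#' @return object of class \code{roi_def}.
#' @export
roi_def <- function(id, center_um, compartment, diameter_um = 1000) {
  stopifnot(length(center_um) == 2L, is.numeric(center_um))
  if (!is.numeric(diameter_um) || diameter_um <= 0) stop("diameter_um must be > 0")
  compartment <- match.arg(compartment, names(compartments()))
  structure(list(id = as.character(id), center_um = as.numeric(center_um),
                 diameter_um = diameter_um, compartment = compartment),
            class = "roi_def")
}

#' Group ROIs of one patient into a set
#' @param patient_id patient identifier.
#' @param rois list of \code{roi_def}.
#' @return object of class \code{roi_set}.
#' @export
roi_set <- function(patient_id, rois) {
  stopifnot(all(vapply(rois, inherits, logical(1), "roi_def")))
  ids <- vapply(rois, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("ROI ids must be unique")
  structure(list(patient_id = as.character(patient_id), rois = rois),
            class = "roi_set")
}

#' Rasterize a circular ROI to a binary mask
#'
#' A pixel belongs to the disc iff its centre lies strictly within the
#' radius of the ROI centre (half-open rule). Pixel (r, c) has its centre
#' at ((c - 0.5) p, (r - 0.5) p) um for pixel size p.
#'
#' @param roi \code{roi_def}.
#' @param slide_dims_px integer (rows, cols) of the slide canvas.
#' @param pixel_size_um physical pixel size, um.
#' @return logical matrix of dimension \code{slide_dims_px}.
#' @export
roi_mask <- function(roi, slide_dims_px, pixel_size_um) {
  stopifnot(inherits(roi, "roi_def"), pixel_size_um > 0)
  h <- slide_dims_px[1]; w <- slide_dims_px[2]
  r_um <- roi$diameter_um / 2
  cx <- roi$center_um[1]; cy <- roi$center_um[2]
  if (cx - r_um < 0 || cy - r_um < 0 ||
      cx + r_um > w * pixel_size_um || cy + r_um > h * pixel_size_um)
    stop(sprintf("ROI '%s' disc exits slide bounds", roi$id))
  x <- (seq_len(w) - 0.5) * pixel_size_um
  y <- (seq_len(h) - 0.5) * pixel_size_um
  dx2 <- (x - cx)^2
  dy2 <- (y - cy)^2
  outer(dy2, dx2, `+`) < r_um^2
}

#' Analyzed area of an ROI mask
#'
#' @param mask logical ROI mask.
#' @param pixel_size_um physical pixel size, um.
#' @return area in mm^2 (pixel count times pixel area).
#' @export
analyzed_area <- function(mask, pixel_size_um) {
  n <- sum(mask)
  if (n == 0) stop("empty ROI mask")
  n * pixel_size_um^2 / 1e6
}

#' Validate an ROI set against the study conventions
#'
#' Checks that every compartment is represented by 1-3 ROIs and that all
#' discs lie inside the slide. Overlap between ROIs of different
#' compartments is reported as a warning, not a violation: compartment
#' borders (especially T vs IF) are genuinely ambiguous.
#'
#' @param roiset \code{roi_set}.
#' @param slide_dims_px integer (rows, cols).
#' @param pixel_size_um physical pixel size, um.
#' @return list with character vectors \code{violations} and
#'   \code{warnings}; a valid set has an empty \code{violations}.
#' @export
validate_roiset <- function(roiset, slide_dims_px, pixel_size_um) {
  stopifnot(inherits(roiset, "roi_set"))
  violations <- character(0)
  warnings <- character(0)
  comp <- vapply(roiset$rois, `[[`, character(1), "compartment")
  for (k in names(compartments())) {
    n <- sum(comp == k)
    if (n == 0) violations <- c(violations, sprintf("missing compartment %s", k))
    if (n > 3) violations <- c(violations, sprintf("%d ROIs in compartment %s (max 3)", n, k))
  }
  h_um <- slide_dims_px[1] * pixel_size_um
  w_um <- slide_dims_px[2] * pixel_size_um
  for (roi in roiset$rois) {
    r <- roi$diameter_um / 2
    if (roi$center_um[1] - r < 0 || roi$center_um[2] - r < 0 ||
        roi$center_um[1] + r > w_um || roi$center_um[2] + r > h_um)
      violations <- c(violations, sprintf("ROI '%s' disc exits slide bounds", roi$id))
  }
  n <- length(roiset$rois)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- roiset$rois[[i]]; b <- roiset$rois[[j]]
      d <- sqrt(sum((a$center_um - b$center_um)^2))
      if (d < (a$diameter_um + b$diameter_um) / 2 && a$compartment != b$compartment)
        warnings <- c(warnings,
                      sprintf("ROIs '%s' (%s) and '%s' (%s) overlap",
                              a$id, a$compartment, b$id, b$compartment))
    }
  }
  list(violations = violations, warnings = warnings)
}

#' Write an ROI set to JSON
#' @param roiset \code{roi_set}.
#' @param path output file.
#' @export
write_roiset <- function(roiset, path) {
  stopifnot(inherits(roiset, "roi_set"))
  jsonlite::write_json(
    list(patient_id = jsonlite::unbox(roiset$patient_id),
         units = jsonlite::unbox("um"),
         rois = lapply(roiset$rois, function(r)
           list(id = jsonlite::unbox(r$id), center_um = r$center_um,
                diameter_um = jsonlite::unbox(r$diameter_um),
                compartment = jsonlite::unbox(r$compartment)))),
    path, digits = NA)
  invisible(path)
}

#' Read an ROI set from JSON or CSV
#'
#' JSON follows the schema written by \code{\link{write_roiset}}. The CSV
#' dialect has columns \code{patient_id, id, center_x_um, center_y_um,
#' diameter_um, compartment}.
#'
#' @param path input file (.json or .csv).
#' @return \code{roi_set}.
#' @export
read_roiset <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = FALSE)
    rois <- lapply(x$rois, function(r)
      roi_def(r$id, unlist(r$center_um), r$compartment, r$diameter_um))
    return(roi_set(x$patient_id, rois))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rois <- lapply(seq_len(nrow(df)), function(i)
    roi_def(df$id[i], c(df$center_x_um[i], df$center_y_um[i]),
            df$compartment[i], df$diameter_um[i]))
  roi_set(df$patient_id[1], rois)
}
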