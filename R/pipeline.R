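# Study-level orchestration: config handling, per-slide analysis
# (shading -> stitching -> unmixing -> threshold -> objects -> ledger ->
# per-ROI EA/AA), batch runs and table-shaped exports.

# polynomial rolling hash over the JSON form of the config; gives a
# short reproducible run id tying every output to the configuration and
# seed (kept below 2^31 so integer arithmetic stays exact)
.config_hash <- function(config) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(config, digits = NA,
                                                   auto_unbox = TRUE,
                                                   force = TRUE)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Build a study configuration
#'
#' @param pixel_size_um physical pixel size, um.
#' @param stain_model_path path to a stain-model JSON
#'   (\code{\link{write_stain_model}}).
#' @param detection list of \code{\link{detection_params}} arguments.
#' @param patients list of per-patient entries: \code{id},
#'   \code{tiles_dir}, \code{roi_file}, optional \code{ledger_file},
#'   \code{nodal_status}, \code{subtype}.
#' @param out_dir output directory.
#' @param background_target background intensity target (default 235).
#' @param register refine tile offsets from overlap content.
#' @param seed integer seed recorded with every output.
#' @return object of class \code{study_config}.
#' @export
study_config <- function(pixel_size_um, stain_model_path, detection,
                         patients, out_dir, background_target = 235,
                         register = TRUE, seed = 1L) {
  stopifnot(pixel_size_um > 0)
  det <- do.call(detection_params, detection)   # validates ranges
  cfg <- list(pixel_size_um = pixel_size_um,
              stain_model_path = stain_model_path,
              detection = detection, patients = patients,
              out_dir = out_dir, background_target = background_target,
              register = isTRUE(register), seed = as.integer(seed))
  cfg$run_id <- .config_hash(cfg)
  structure(cfg, class = "study_config")
}

#' Read a study configuration from YAML or JSON
#' @param path config file (.yaml/.yml or .json).
#' @return \code{study_config}.
#' @export
read_study_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(x$patients))
    x$patients <- lapply(seq_len(nrow(x$patients)),
                         function(i) as.list(x$patients[i, ]))
  study_config(pixel_size_um = x$pixel_size_um,
               stain_model_path = x$stain_model_path,
               detection = x$detection, patients = x$patients,
               out_dir = x$out_dir,
               background_target = x$background_target %||% 235,
               register = x$register %||% TRUE,
               seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_config_paths <- function(config, patient_id = NULL) {
  if (!file.exists(config$stain_model_path))
    stop("stain model file not found: ", config$stain_model_path)
  patients <- config$patients
  if (!is.null(patient_id))
    patients <- Filter(function(p) p$id %in% patient_id, patients)
  for (p in patients) {
    if (!dir.exists(p$tiles_dir))
      stop(sprintf("patient %s: tiles_dir not found: %s", p$id, p$tiles_dir))
    if (!file.exists(p$roi_file))
      stop(sprintf("patient %s: roi_file not found: %s", p$id, p$roi_file))
    if (!is.null(p$ledger_file) && !file.exists(p$ledger_file))
      stop(sprintf("patient %s: ledger_file not found: %s", p$id, p$ledger_file))
  }
  invisible(TRUE)
}

#' Per-ROI endothelial-area analysis of an assembled slide
#'
#' The in-memory analysis core shared by \code{\link{run_analysis}}:
#' unmixes the slide, thresholds the DAB abundance map, extracts and
#' (optionally) ledger-corrects vessel objects, then measures EA and AA
#' for every ROI.
#'
#' @param slide \code{virtual_slide}.
#' @param model \code{stain_model}.
#' @param roiset \code{roi_set}.
#' @param det_params \code{detection_params}.
#' @param ledger optional \code{correction_ledger}.
#' @return list: \code{roi_table} (roi_id, compartment, ea_mm2, aa_mm2),
#'   \code{patient} (pooled per-compartment EA/AA/REA), \code{objects}.
#' @export
analyze_virtual_slide <- function(slide, model, roiset, det_params,
                                  ledger = NULL) {
  stopifnot(inherits(slide, "virtual_slide"))
  dims <- dim(slide$pixels)[1:2]
  p_um <- slide$pixel_size_um
  rep_ <- validate_roiset(roiset, dims, p_um)
  if (length(rep_$violations))
    stop("ROI set invalid: ", paste(rep_$violations, collapse = "; "))
  od <- rgb_to_od(slide$pixels, model$background_i0)
  maps <- unmix(od, model)
  mask <- threshold_dab(maps$a_dab, det_params)
  objects <- extract_objects(mask, det_params, p_um)
  if (!is.null(ledger)) objects <- apply_corrections(objects, ledger, p_um)
  roi_table <- do.call(rbind, lapply(roiset$rois, function(r) {
    m <- roi_mask(r, dims, p_um)
    data.frame(roi_id = r$id, compartment = r$compartment,
               ea_mm2 = measure_endothelial_area(objects, m, p_um),
               aa_mm2 = analyzed_area(m, p_um), stringsAsFactors = FALSE)
  }))
  patient <- aggregate_patient(data.frame(compartment = roi_table$compartment,
                                          ea_mm2 = roi_table$ea_mm2,
                                          aa_mm2 = roi_table$aa_mm2))
  list(roi_table = roi_table, patient = patient, objects = objects)
}

#' Run the full per-slide analysis for one patient
#'
#' Executes shading correction, stitching, unmixing, thresholding,
#' object extraction, ledger corrections and per-ROI EA/AA measurement
#' as configured; writes the per-ROI table to the output directory.
#' Deterministic given the configuration.
#'
#' @param config \code{study_config}.
#' @param patient_id patient to analyze (must be in the config).
#' @param verbose emit structured progress lines (default TRUE).
#' @return list: roi_table, patient record fields, objects, log.
#' @export
run_analysis <- function(config, patient_id, verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  .validate_config_paths(config, patient_id)
  entry <- Filter(function(p) p$id == patient_id, config$patients)
  if (length(entry) != 1) stop("unknown patient id: ", patient_id)
  entry <- entry[[1]]
  log <- list()
  say <- function(stage, ...) {
    line <- sprintf("[%s] patient=%s run=%s %s", stage, patient_id,
                    config$run_id, sprintf(...))
    if (verbose) message(line)
    log[[length(log) + 1L]] <<- line
  }
  res <- tryCatch({
    say("config", "seed=%d pixel_size_um=%g threshold=%g",
        config$seed, config$pixel_size_um,
        config$detection$dab_od_threshold)
    ts <- read_tileset(entry$tiles_dir)
    say("read", "%d tiles, white=%s", length(ts$tiles), !is.null(ts$white))
    slide <- stitch_tiles(ts$tiles, ts$white, config$pixel_size_um,
                          target = rep(config$background_target, 3),
                          register = config$register)
    say("stitch", "canvas %d x %d, fallbacks=%d", dim(slide$pixels)[1],
        dim(slide$pixels)[2], slide$provenance$registration_fallbacks)
    model <- read_stain_model(config$stain_model_path)
    roiset <- read_roiset(entry$roi_file)
    ledger <- if (!is.null(entry$ledger_file)) read_ledger(entry$ledger_file)
    det <- do.call(detection_params, config$detection)
    out <- analyze_virtual_slide(slide, model, roiset, det, ledger)
    say("measure", "%d ROIs, %d objects", nrow(out$roi_table),
        nrow(out$objects$objects))
    out
  }, error = function(e)
    stop(sprintf("patient %s: %s", patient_id, conditionMessage(e)),
         call. = FALSE))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- res$roi_table
  tab$run_id <- config$run_id
  tab$seed <- config$seed
  utils::write.csv(tab, file.path(config$out_dir,
                                  sprintf("%s_roi_areas.csv", patient_id)),
                   row.names = FALSE)
  c(res, list(log = log))
}

#' Run the whole study batch and export cohort statistics
#'
#' Analyzes every configured patient (stage outputs are independent
#' across patients, so order does not affect results); per-patient
#' failures are collected and reported while the batch continues.
#'
#' @param config \code{study_config}.
#' @param patient_ids subset of patients (default: all configured).
#' @param verbose emit structured progress lines.
#' @return list: \code{cohort} (cohort_table of analyzed patients),
#'   \code{failures} (named character vector of error messages),
#'   \code{paths} (exported CSVs).
#' @export
run_batch <- function(config, patient_ids = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(patient_ids))
    patient_ids <- vapply(config$patients, `[[`, character(1), "id")
  if (!length(patient_ids)) stop("empty patient list")
  rows <- list(); failures <- character(0)
  for (pid in patient_ids) {
    res <- tryCatch(run_analysis(config, pid, verbose = verbose),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[pid] <- conditionMessage(res)
      next
    }
    entry <- Filter(function(p) p$id == pid, config$patients)[[1]]
    rows[[pid]] <- data.frame(
      patient_id = pid,
      nodal_status = entry$nodal_status %||% "unknown",
      subtype = entry$subtype %||% "unknown",
      tas_ea_mm2 = res$patient$tas_ea_mm2, tas_aa_mm2 = res$patient$tas_aa_mm2,
      t_ea_mm2 = res$patient$t_ea_mm2, t_aa_mm2 = res$patient$t_aa_mm2,
      if_ea_mm2 = res$patient$if_ea_mm2, if_aa_mm2 = res$patient$if_aa_mm2,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("all patients failed: ",
                          paste(names(failures), collapse = ", "))
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  class(cohort) <- c("cohort_table", "data.frame")
  paths <- export_results(cohort, config$out_dir)
  if (length(failures))
    warning("failed patients: ", paste(names(failures), collapse = ", "))
  list(cohort = cohort, failures = failures, paths = paths)
}

#' Reproduce the study-shaped tables on a synthetic cohort
#'
#' Generates the default synthetic cohort (50 patients at the study's
#' compartment means, nodal split and subtype counts), computes the REA
#' statistics layer and writes the patient-, mean-, ratio- and
#' correlation-shaped CSVs.
#'
#' @param out_dir output directory.
#' @param seed integer seed for the cohort draw.
#' @param n_patients cohort size (default 50).
#' @return list: cohort, group means, correlation table, written paths.
#' @export
reproduce_tables <- function(out_dir, seed = 1L, n_patients = 50L) {
  # scale the study's nodal split and subtype counts for other cohort sizes
  sub <- round(c(LuminalA = 25, LuminalB = 9, BasalLike = 5, HER2 = 11) *
                 n_patients / 50)
  sub[1] <- sub[1] + n_patients - sum(sub)
  params <- cohort_sim_params(n_patients = n_patients,
                              n0_count = max(1L, round(13 * n_patients / 50)),
                              subtype_counts = sub, seed = seed)
  cohort <- generate_cohort(params)
  paths <- export_results(cohort, out_dir)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  list(cohort = cohort,
       group_means = rbind(group_mean_rea(cohort, "all"),
                           group_mean_rea(cohort, "nodal")),
       correlations = correlation_table(cohort, "all"),
       paths = paths)
}
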