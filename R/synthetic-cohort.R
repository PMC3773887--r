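# Synthetic patient cohorts with the statistical structure of the study
# population: three positively correlated per-compartment REA values per
# patient (correlated lognormal via a Gaussian copula), nodal-status and
# molecular-subtype labels assigned by fixed counts.

#' Parameters of a synthetic cohort
#'
#' Defaults reproduce the study population: 50 patients, compartment REA
#' means (TAS, T, IF) = (0.91, 1.95, 4.2) percent, 13 node-negative
#' patients, molecular subtypes Luminal A/Luminal B/Basal-like/HER2 =
#' 25/9/5/11, and the reported between-compartment correlation structure
#' (used here as the log-scale copula target).
#'
#' @param n_patients number of patients.
#' @param compartment_means_pct REA means (TAS, T, IF), percent.
#' @param compartment_cv coefficient of variation per compartment
#'   (recycled to length 3).
#' @param correlation_matrix 3 x 3 target Pearson matrix on the log scale
#'   (symmetric positive-definite, unit diagonal).
#' @param n0_count number of node-negative (N0) patients.
#' @param subtype_counts named counts for LuminalA, LuminalB, BasalLike,
#'   HER2 (must sum to \code{n_patients}).
#' @param roi_aa_mm2 analyzed area contributed by one ROI, mm^2 (default
#'   the 1-mm disc area pi/4).
#' @param seed integer seed.
#' @return object of class \code{cohort_sim_params}.
#' @export
cohort_sim_params <- function(n_patients = 50L,
                              compartment_means_pct = c(TAS = 0.91, T = 1.95, IF = 4.2),
                              compartment_cv = 0.5,
                              correlation_matrix = rbind(
                                c(1, 0.418, 0.432),
                                c(0.418, 1, 0.655),
                                c(0.432, 0.655, 1)),
                              n0_count = 13L,
                              subtype_counts = c(LuminalA = 25L, LuminalB = 9L,
                                                 BasalLike = 5L, HER2 = 11L),
                              roi_aa_mm2 = pi / 4,
                              seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (any(compartment_means_pct <= 0)) stop("compartment means must be positive")
  compartment_cv <- rep(compartment_cv, length.out = 3L)
  if (any(compartment_cv < 0)) stop("compartment_cv must be >= 0")
  R <- correlation_matrix
  if (!isTRUE(all.equal(R, t(R))) || !isTRUE(all.equal(diag(R), rep(1, 3))))
    stop("correlation_matrix must be symmetric with unit diagonal")
  if (inherits(try(chol(R), silent = TRUE), "try-error"))
    stop("correlation_matrix is not positive-definite")
  if (n0_count > n_patients) stop("n0_count exceeds n_patients")
  if (sum(subtype_counts) != n_patients)
    stop("subtype counts must sum to n_patients")
  structure(as.list(environment()), class = "cohort_sim_params")
}

#' Generate a synthetic patient cohort table
#'
#' Per-patient compartment REA values are drawn from a correlated
#' lognormal: a trivariate Gaussian copula with the target log-scale
#' correlation matrix, with lognormal marginals matching the requested
#' means and coefficients of variation. Each compartment gets 1-3 ROIs;
#' AA is the ROI count times the per-ROI area, and EA = REA * AA / 100,
#' so the table is self-consistent under pooled-ratio aggregation.
#'
#' @param params \code{\link{cohort_sim_params}}.
#' @return data frame (class \code{cohort_table}) with columns
#'   patient_id, nodal_status, subtype, and per-compartment
#'   \code{*_ea_mm2}, \code{*_aa_mm2}.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(params$seed)
  n <- params$n_patients
  m <- unname(params$compartment_means_pct)
  cv <- params$compartment_cv
  sigma <- sqrt(log(1 + cv^2))
  mu <- log(m) - sigma^2 / 2
  z <- if (any(sigma > 0))
    MASS::mvrnorm(n, mu = rep(0, 3), Sigma = params$correlation_matrix)
  else matrix(0, n, 3)
  if (n == 1L) z <- matrix(z, nrow = 1)
  rea <- exp(sweep(sweep(z, 2, sigma, `*`), 2, mu, `+`))

  n_roi <- matrix(sample(1:3, 3 * n, replace = TRUE), n, 3)
  aa <- n_roi * params$roi_aa_mm2
  ea <- rea * aa / 100

  nodal <- rep("N>N0", n)
  nodal[sample.int(n, params$n0_count)] <- "N0"
  subtype <- sample(rep(names(params$subtype_counts), params$subtype_counts))

  out <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    nodal_status = nodal,
    subtype = subtype,
    tas_ea_mm2 = ea[, 1], tas_aa_mm2 = aa[, 1],
    t_ea_mm2 = ea[, 2], t_aa_mm2 = aa[, 2],
    if_ea_mm2 = ea[, 3], if_aa_mm2 = aa[, 3],
    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write a cohort table to CSV
#' @param cohort \code{cohort_table} data frame.
#' @param path output CSV.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#' @param path CSV with the cohort schema.
#' @return \code{cohort_table} data frame.
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("patient_id", "nodal_status", "subtype",
            "tas_ea_mm2", "tas_aa_mm2", "t_ea_mm2", "t_aa_mm2",
            "if_ea_mm2", "if_aa_mm2")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stop("cohort CSV is missing columns: ", paste(missing, collapse = ", "))
  class(out) <- c("cohort_table", "data.frame")
  out
}
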