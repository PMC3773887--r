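# Relative endothelial area (REA) statistics: pooled per-compartment REA
# per patient, group means and compartment ratios, Pearson correlations
# with exact two-tailed significance (Student-t transform), paired
# t-tests, and CSV export.

.compartment_cols <- c(TAS = "tas", T = "t", IF = "if")

#' Relative endothelial area in percent
#'
#' REA percent = 100 * EA / AA.
#'
#' @param ea_mm2 endothelial area, mm^2.
#' @param aa_mm2 analyzed area, mm^2 (> 0).
#' @return REA in percent.
#' @export
compute_rea <- function(ea_mm2, aa_mm2) {
  if (any(aa_mm2 <= 0)) stop("analyzed area must be > 0")
  if (any(ea_mm2 < 0) || any(ea_mm2 > aa_mm2))
    stop("endothelial area must satisfy 0 <= EA <= AA")
  100 * ea_mm2 / aa_mm2
}

#' Aggregate per-ROI areas into one patient record
#'
#' Areas are pooled per compartment — EA and AA are summed over the
#' compartment's ROIs and one REA is computed from the totals (pooled
#' ratio, not the mean of per-ROI ratios).
#'
#' @param roi_areas data frame with columns \code{compartment} (TAS, T,
#'   IF), \code{ea_mm2}, \code{aa_mm2}, one row per ROI.
#' @return named list with \code{<comp>_ea_mm2}, \code{<comp>_aa_mm2} and
#'   \code{<comp>_rea_pct} for each compartment.
#' @export
aggregate_patient <- function(roi_areas) {
  missing <- setdiff(names(.compartment_cols), roi_areas$compartment)
  if (length(missing))
    stop("missing compartment(s): ", paste(missing, collapse = ", "))
  out <- list()
  for (k in names(.compartment_cols)) {
    rows <- roi_areas$compartment == k
    ea <- sum(roi_areas$ea_mm2[rows])
    aa <- sum(roi_areas$aa_mm2[rows])
    p <- .compartment_cols[[k]]
    out[[paste0(p, "_ea_mm2")]] <- ea
    out[[paste0(p, "_aa_mm2")]] <- aa
    out[[paste0(p, "_rea_pct")]] <- compute_rea(ea, aa)
  }
  out
}

#' Per-patient REA columns of a cohort table
#'
#' @param cohort \code{cohort_table} data frame (EA/AA schema).
#' @return data frame with patient_id, nodal_status, subtype and
#'   tas/t/if \code{_rea_pct} columns.
#' @export
cohort_rea <- function(cohort) {
  out <- cohort[, c("patient_id", "nodal_status", "subtype")]
  for (p in unname(.compartment_cols))
    out[[paste0(p, "_rea_pct")]] <-
      compute_rea(cohort[[paste0(p, "_ea_mm2")]], cohort[[paste0(p, "_aa_mm2")]])
  out
}

.group_indices <- function(rea, grouping) {
  if (grouping == "all") return(list(all = seq_len(nrow(rea))))
  key <- if (grouping == "nodal") rea$nodal_status else rea$subtype
  idx <- seq_len(nrow(rea))
  if (grouping == "subtype") {
    known <- key != "unknown"
    n_unknown <- sum(!known)
    if (n_unknown > 0)
      message(sprintf("excluding %d patient(s) with unknown subtype", n_unknown))
    idx <- idx[known]; key <- key[known]
  }
  split(idx, key)
}

#' Per-compartment mean REA by group
#'
#' Unweighted arithmetic means of per-patient REA, per compartment, for
#' the whole cohort or stratified by nodal status or molecular subtype.
#' Patients with unknown subtype are excluded from subtype tables with a
#' logged count; empty groups are omitted with a warning.
#'
#' @param cohort \code{cohort_table} data frame.
#' @param grouping one of \code{"all"}, \code{"nodal"},
#'   \code{"subtype"}.
#' @return data frame: group, n, tas_rea_pct, t_rea_pct, if_rea_pct.
#' @export
group_mean_rea <- function(cohort, grouping = c("all", "nodal", "subtype")) {
  grouping <- match.arg(grouping)
  rea <- cohort_rea(cohort)
  groups <- .group_indices(rea, grouping)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  if (!length(groups)) {
    warning("no non-empty groups")
    return(data.frame(group = character(0), n = integer(0)))
  }
  do.call(rbind, lapply(names(groups), function(g) {
    i <- groups[[g]]
    data.frame(group = g, n = length(i),
               tas_rea_pct = mean(rea$tas_rea_pct[i]),
               t_rea_pct = mean(rea$t_rea_pct[i]),
               if_rea_pct = mean(rea$if_rea_pct[i]),
               stringsAsFactors = FALSE)
  }))
}

#' Ratio of two compartment means
#'
#' @param mean_a,mean_b group-mean REA values; \code{mean_b} must be > 0.
#' @return \code{mean_a / mean_b} at full precision (rounding is
#'   presentation only).
#' @export
compartment_ratio <- function(mean_a, mean_b) {
  if (any(mean_b <= 0)) stop("denominator mean must be > 0")
  mean_a / mean_b
}

#' Two-tailed significance of a Pearson correlation
#'
#' Standard exact transform: \eqn{t = r \sqrt{(n-2)/(1-r^2)}} referred to
#' the Student-t distribution with n - 2 degrees of freedom (evaluated by
#' R's incomplete-beta based t CDF), two-tailed.
#'
#' @param r Pearson correlation, |r| <= 1.
#' @param n sample size, >= 3.
#' @return two-tailed p-value; exactly 0 (with an exact-fit attribute)
#'   when |r| = 1.
#' @export
p_from_correlation <- function(r, n) {
  if (n < 3) stop("n must be >= 3")
  if (abs(r) > 1) stop("|r| must be <= 1")
  if (abs(r) == 1) {
    p <- 0
    attr(p, "exact_fit") <- TRUE
    return(p)
  }
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
}

#' Pearson correlation with exact two-tailed significance
#'
#' @param x,y numeric vectors of equal length n >= 3, non-constant.
#' @param pair optional character pair label, e.g. c("TAS", "T").
#' @return list of class \code{correlation_result}: pair, n, r,
#'   p_two_tailed.
#' @export
pearson_correlation <- function(x, y, pair = c("x", "y")) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("n must be >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- stats::cor(x, y)
  structure(list(pair = pair, n = n, r = r,
                 p_two_tailed = as.numeric(p_from_correlation(r, n))),
            class = "correlation_result")
}

#' Paired two-tailed t-test
#'
#' Standard paired t on the differences, df = n - 1, two-tailed p from
#' the Student-t CDF.
#'
#' @param x,y numeric vectors of equal length n >= 2.
#' @param pair optional character pair label.
#' @return list of class \code{paired_test_result}: pair, n, t_stat, df,
#'   p_two_tailed.
#' @export
paired_ttest <- function(x, y, pair = c("x", "y")) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("n must be >= 2")
  d <- y - x
  s <- stats::sd(d)
  if (all(d == 0)) {
    return(structure(list(pair = pair, n = n, t_stat = 0, df = n - 1,
                          p_two_tailed = 1), class = "paired_test_result"))
  }
  if (s == 0) stop("zero-variance non-zero differences: paired t undefined")
  t_stat <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  structure(list(pair = pair, n = n, t_stat = t_stat, df = n - 1,
                 p_two_tailed = p), class = "paired_test_result")
}

#' Pairwise compartment correlation table
#'
#' Pearson r, exact two-tailed significance and the paired-difference
#' test for each compartment pair (TAS-T, TAS-IF, T-IF), for the whole
#' cohort or per group.
#'
#' @param cohort \code{cohort_table} data frame.
#' @param grouping one of "all", "nodal", "subtype".
#' @param log_scale correlate log REA instead of raw (default FALSE,
#'   matching the study's raw-scale tables).
#' @return data frame: group, pair, n, r, p_two_tailed, t_paired,
#'   p_paired.
#' @export
correlation_table <- function(cohort, grouping = c("all", "nodal", "subtype"),
                              log_scale = FALSE) {
  grouping <- match.arg(grouping)
  rea <- cohort_rea(cohort)
  groups <- .group_indices(rea, grouping)
  pairs <- list(c("TAS", "T"), c("TAS", "IF"), c("T", "IF"))
  rows <- list()
  for (g in names(groups)) {
    i <- groups[[g]]
    if (length(i) < 3) next
    for (pr in pairs) {
      a <- rea[[paste0(.compartment_cols[[pr[1]]], "_rea_pct")]][i]
      b <- rea[[paste0(.compartment_cols[[pr[2]]], "_rea_pct")]][i]
      if (log_scale) { a <- log(a); b <- log(b) }
      cr <- pearson_correlation(a, b, pair = pr)
      tt <- paired_ttest(a, b, pair = pr)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, pair = paste(pr, collapse = "-"), n = cr$n,
        r = cr$r, p_two_tailed = cr$p_two_tailed,
        t_paired = tt$t_stat, p_paired = tt$p_two_tailed,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Export cohort results as CSV files
#'
#' Writes patients.csv (patient-level EA/AA/REA), group_means.csv (all,
#' nodal and subtype groupings stacked), ratios.csv (IF/T, IF/TAS, T/TAS
#' per group) and correlations.csv. Byte-stable for identical input.
#'
#' @param cohort \code{cohort_table} data frame.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the written paths.
#' @export
export_results <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "group_means.csv",
                            "ratios.csv", "correlations.csv"))
  patients <- if (nrow(cohort)) cbind(
    as.data.frame(cohort),
    cohort_rea(cohort)[, c("tas_rea_pct", "t_rea_pct", "if_rea_pct")])
  else cbind(as.data.frame(cohort),
             data.frame(tas_rea_pct = numeric(0), t_rea_pct = numeric(0),
                        if_rea_pct = numeric(0)))
  utils::write.csv(patients, paths[1], row.names = FALSE)

  if (nrow(cohort)) {
    gm <- do.call(rbind, lapply(c("all", "nodal", "subtype"), function(g) {
      x <- group_mean_rea(cohort, g); x$grouping <- g; x
    }))
    ratios <- data.frame(
      group = gm$group,
      if_over_t = compartment_ratio(gm$if_rea_pct, gm$t_rea_pct),
      if_over_tas = compartment_ratio(gm$if_rea_pct, gm$tas_rea_pct),
      t_over_tas = compartment_ratio(gm$t_rea_pct, gm$tas_rea_pct),
      stringsAsFactors = FALSE)
    ct <- do.call(rbind, lapply(c("all", "nodal", "subtype"),
                                function(g) correlation_table(cohort, g)))
  } else {
    gm <- data.frame(group = character(0), n = integer(0),
                     tas_rea_pct = numeric(0), t_rea_pct = numeric(0),
                     if_rea_pct = numeric(0), grouping = character(0))
    ratios <- data.frame(group = character(0), if_over_t = numeric(0),
                         if_over_tas = numeric(0), t_over_tas = numeric(0))
    ct <- data.frame(group = character(0), pair = character(0),
                     n = integer(0), r = numeric(0),
                     p_two_tailed = numeric(0), t_paired = numeric(0),
                     p_paired = numeric(0))
  }
  utils::write.csv(gm, paths[2], row.names = FALSE)
  utils::write.csv(ratios, paths[3], row.names = FALSE)
  utils::write.csv(ct, paths[4], row.names = FALSE)
  invisible(paths)
}
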