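test_that("REA formula and its guards", {
  expect_equal(compute_rea(0.021, 1.0), 2.1)
  expect_equal(compute_rea(0, 5), 0)
  expect_equal(compute_rea(0.7853975 * 0.042, 0.7853975), 4.2)
  expect_error(compute_rea(1, 0), "> 0")
  expect_error(compute_rea(2, 1), "EA <= AA")
})

test_that("patient aggregation pools sums, not per-ROI ratios", {
  one <- data.frame(compartment = c("TAS", "T", "IF"),
                    ea_mm2 = c(0.01, 0.02, 0.03), aa_mm2 = c(1, 1, 1))
  rec <- aggregate_patient(one)
  expect_equal(rec$tas_rea_pct, 1)
  expect_equal(rec$if_rea_pct, 3)

  # pooled 100*0.04/1.5 = 2.667 differs from mean-of-ratios 3.5
  two <- data.frame(compartment = c("T", "T", "TAS", "IF"),
                    ea_mm2 = c(0.01, 0.03, 0.001, 0.001),
                    aa_mm2 = c(1.0, 0.5, 1, 1))
  rec2 <- aggregate_patient(two)
  expect_equal(rec2$t_rea_pct, 100 * 0.04 / 1.5)

  # invariant to splitting one ROI into two sub-ROIs
  split_roi <- data.frame(compartment = c("T", "T", "T", "TAS", "IF"),
                          ea_mm2 = c(0.005, 0.005, 0.03, 0.001, 0.001),
                          aa_mm2 = c(0.5, 0.5, 0.5, 1, 1))
  expect_equal(aggregate_patient(split_roi)$t_rea_pct, rec2$t_rea_pct)

  expect_error(aggregate_patient(one[1:2, ]), "IF")
})

test_that("group means stratify by nodal status and subtype", {
  co <- data.frame(
    patient_id = sprintf("P%d", 1:4),
    nodal_status = c("N0", "N0", "N>N0", "N>N0"),
    subtype = c("LuminalA", "unknown", "LuminalA", "HER2"),
    tas_ea_mm2 = c(0.01, 0.03, 0.01, 0.01), tas_aa_mm2 = 1,
    t_ea_mm2 = c(0.02, 0.02, 0.04, 0.04), t_aa_mm2 = 1,
    if_ea_mm2 = c(0.05, 0.05, 0.03, 0.03), if_aa_mm2 = 1)
  all_means <- group_mean_rea(co, "all")
  expect_equal(all_means$n, 4)
  expect_equal(all_means$tas_rea_pct, mean(c(1, 3, 1, 1)))
  nodal <- group_mean_rea(co, "nodal")
  expect_equal(nodal$if_rea_pct[nodal$group == "N0"], 5)
  expect_equal(nodal$t_rea_pct[nodal$group == "N>N0"], 4)
  expect_message(sub <- group_mean_rea(co, "subtype"), "unknown subtype")
  expect_false("unknown" %in% sub$group)
  expect_equal(sum(sub$n), 3)
  # single patient: means equal that patient
  single <- group_mean_rea(co[1, ], "all")
  expect_equal(single$t_rea_pct, 2)
})

test_that("compartment ratios reproduce the printed study values", {
  expect_equal(compartment_ratio(4.2, 1.95), 2.1538, tolerance = 1e-4)
  expect_equal(compartment_ratio(3, 3), 1)
  expect_equal(compartment_ratio(4.99, 2.72), 1.8346, tolerance = 1e-4)
  expect_error(compartment_ratio(1, 0), "> 0")
})

test_that("pearson correlation matches hand computation", {
  x <- 1:5
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  # hand product-moment: sum xy dev = 8, sqrt(10*10) = 10
  expect_equal(pearson_correlation(x, c(2, 1, 4, 3, 5))$r, 0.8)
  expect_error(pearson_correlation(x, rep(2, 5)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "n must be >= 3")
})

test_that("correlation significance agrees with the df = 3 closed form", {
  # r = 0.966, n = 5 -> t with 3 degrees of freedom
  r <- 0.966; n <- 5
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p_closed <- 2 * (1 - pt3_closed_form(t_stat))
  expect_equal(as.numeric(p_from_correlation(r, n)), p_closed, tolerance = 1e-12)
  expect_equal(round(p_closed, 3), 0.007)
})

test_that("t CDF route agrees with numerical integration of the density", {
  for (n in c(5, 13, 25, 37, 50)) for (r in seq(0.1, 0.9, by = 0.2)) {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p_num <- 2 * integrate(function(u) dt(u, df = n - 2), t_stat, Inf,
                           rel.tol = 1e-12)$value
    expect_equal(as.numeric(p_from_correlation(r, n)), p_num, tolerance = 1e-6)
  }
  expect_equal(as.numeric(p_from_correlation(0, 10)), 1)
  p1 <- p_from_correlation(1, 10)
  expect_equal(as.numeric(p1), 0)
  expect_true(attr(p1, "exact_fit"))
  expect_error(p_from_correlation(0.5, 2), ">= 3")
})

test_that("paired t-test matches stats::t.test and handles degeneracy", {
  x <- c(1, 2, 3, 4); y <- c(1.1, 2.3, 2.8, 4.4)
  mine <- paired_ttest(x, y)
  ref <- t.test(y, x, paired = TRUE)
  expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_two_tailed, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$df, 3)

  same <- paired_ttest(x, x)
  expect_equal(same$p_two_tailed, 1)
  expect_equal(same$t_stat, 0)
  # constant shift: zero variance of differences is degenerate
  expect_error(paired_ttest(c(1, 2, 3), c(2, 3, 4)), "zero-variance")
})

test_that("correlation tables cover all pairs and groups", {
  co <- generate_cohort(cohort_sim_params(seed = 12))
  ct <- correlation_table(co, "all")
  expect_equal(ct$pair, c("TAS-T", "TAS-IF", "T-IF"))
  expect_equal(ct$n, rep(50, 3))
  expect_true(all(ct$r > -1 & ct$r < 1))
  expect_true(all(ct$p_two_tailed > 0 & ct$p_two_tailed <= 1))
  nodal <- correlation_table(co, "nodal")
  expect_equal(sort(unique(nodal$group)), c("N0", "N>N0"))
  # log-scale option transforms before correlating
  lt <- correlation_table(co, "all", log_scale = TRUE)
  rea <- cohort_rea(co)
  expect_equal(lt$r[lt$pair == "T-IF"],
               cor(log(rea$t_rea_pct), log(rea$if_rea_pct)))
})

test_that("export writes byte-stable CSVs with the declared shapes", {
  co <- generate_cohort(cohort_sim_params(seed = 5))
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  p1 <- export_results(co, d1)
  p2 <- export_results(co, d2)
  for (i in seq_along(p1))
    expect_identical(readBin(p1[i], "raw", file.size(p1[i])),
                     readBin(p2[i], "raw", file.size(p2[i])))
  patients <- read.csv(file.path(d1, "patients.csv"))
  expect_equal(nrow(patients), 50)
  expect_true(all(c("tas_rea_pct", "if_rea_pct") %in% names(patients)))
  ratios <- read.csv(file.path(d1, "ratios.csv"))
  expect_true(all(c("if_over_t", "if_over_tas", "t_over_tas") %in% names(ratios)))
  # empty cohort: header-only files
  d3 <- file.path(tempdir(), "exp3")
  export_results(co[0, ], d3)
  expect_equal(nrow(read.csv(file.path(d3, "patients.csv"))), 0)
  unlink(c(d1, d2, d3), recursive = TRUE)
})
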