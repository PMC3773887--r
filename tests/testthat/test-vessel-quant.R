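test_that("run-based labelling agrees with EBImage at 4-connectivity", {
  set.seed(5)
  for (i in 1:5) {
    m <- matrix(runif(2500) < 0.35, 50, 50)
    mine <- label_components(m, 4L)
    ref <- EBImage::bwlabel(m * 1L)
    expect_equal(max(mine), max(ref))
    # identical partitions: labels map one-to-one
    expect_equal(length(unique(paste(mine[m], ref[m]))), max(mine))
  }
})

test_that("connectivity rule splits or joins diagonal touches", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(label_components(m, 8L)), 1)
  expect_equal(max(label_components(m, 4L)), 2)

  par8 <- detection_params(0.1, min_object_area_um2 = 0, connectivity = 8L)
  par4 <- detection_params(0.1, min_object_area_um2 = 2, connectivity = 4L)
  expect_equal(nrow(extract_objects(m, par8, 1)$objects), 1)
  # at 4-connectivity both single-pixel objects fall below 2 um^2
  expect_equal(nrow(extract_objects(m, par4, 1)$objects), 0)
})

test_that("thresholding is inclusive and deterministic", {
  par <- detection_params(0.15)
  expect_false(any(threshold_dab(matrix(0, 5, 5), par)))
  expect_true(all(threshold_dab(matrix(0.15, 5, 5), par)))
  a <- matrix(c(0.149, 0.15, 0.151, 0), 2, 2)
  expect_identical(threshold_dab(a, par), a >= 0.15)
})

test_that("object extraction measures areas, holes and eccentricity", {
  par <- detection_params(0.5, min_object_area_um2 = 20)
  m <- matrix(FALSE, 40, 40)
  m[5:14, 5:14] <- TRUE                        # 10x10 square
  obj <- extract_objects(m, par, 1)
  expect_equal(nrow(obj$objects), 1)
  expect_equal(obj$objects$area_um2, 100)
  expect_equal(obj$objects$centroid_x_um, 9)
  expect_equal(obj$objects$eccentricity, 0, tolerance = 1e-12)

  # ring: lumen shapes the object but does not count towards area
  ring <- matrix(FALSE, 40, 40)
  ring[10:20, 10:20] <- TRUE
  ring[13:17, 13:17] <- FALSE
  obj2 <- extract_objects(ring, detection_params(0.5, fill_holes = TRUE), 1)
  expect_equal(nrow(obj2$objects), 1)
  expect_equal(obj2$objects$area_um2, 11 * 11 - 5 * 5)

  # without hole filling the lumen is background; same wall area
  obj3 <- extract_objects(ring, detection_params(0.5, fill_holes = FALSE), 1)
  expect_equal(obj3$objects$area_um2, 11 * 11 - 5 * 5)

  # elongated object flagged fibroblast-like but retained
  thin <- matrix(FALSE, 40, 40)
  thin[20, 3:38] <- TRUE
  obj4 <- extract_objects(thin, detection_params(0.5, min_object_area_um2 = 10,
                                                 max_eccentricity_flag = 0.95), 1)
  expect_equal(obj4$objects$flags, "fibroblast-like")

  expect_equal(nrow(extract_objects(matrix(FALSE, 5, 5), par, 1)$objects), 0)
})

test_that("component areas conserve mask area before filtering", {
  set.seed(9)
  m <- matrix(runif(10000) < 0.2, 100, 100)
  obj <- extract_objects(m, detection_params(0.1, min_object_area_um2 = 0,
                                             fill_holes = FALSE), 1)
  expect_equal(sum(obj$objects$area_um2), sum(m))
})

test_that("correction ledger deletes, adds and validates", {
  m <- matrix(FALSE, 60, 60)
  m[10:19, 10:19] <- TRUE
  obj <- extract_objects(m, detection_params(0.5), 1)

  expect_equal(apply_corrections(obj, correction_ledger())$objects, obj$objects)

  led <- correction_ledger(list(list(type = "delete", target = 1)))
  out <- apply_corrections(obj, led)
  expect_equal(nrow(out$objects), 0)
  expect_equal(unname(out$counts["deleted"]), 1L)

  # 1 mm x 10 um rectangle has shoelace area 1e4 um^2
  big <- cbind(c(0, 1000, 1000, 0), c(0, 0, 10, 10))
  expect_equal(vesselquant:::.polygon_area(big), 1e4)
  # a 50 x 10 um rectangle within the 60x60 map as a manual add
  rect <- cbind(c(2, 52, 52, 2), c(20, 20, 30, 30))
  led2 <- correction_ledger(list(list(type = "add", target = rect)))
  out2 <- apply_corrections(obj, led2)
  expect_equal(nrow(out2$objects), 2)
  expect_equal(out2$objects$area_um2[2], 500)   # 50 x 10 um rectangle
  expect_equal(out2$objects$source[2], "manual")

  expect_error(apply_corrections(obj, correction_ledger(
    list(list(type = "delete", target = 99)))), "99")
  bow_tie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(apply_corrections(obj, correction_ledger(
    list(list(type = "add", target = bow_tie)))), "self-intersecting")
})

test_that("ledger JSON round-trips", {
  led <- correction_ledger(list(
    list(type = "delete", target = 3, note = "fibroblast", timestamp = "t1"),
    list(type = "add", target = cbind(c(0, 5, 5, 0), c(0, 0, 5, 5)))))
  path <- tempfile(fileext = ".json")
  write_ledger(led, path)
  led2 <- read_ledger(path)
  expect_equal(led2$events[[1]]$type, "delete")
  expect_equal(led2$events[[1]]$target, 3)
  expect_equal(led2$events[[2]]$target, cbind(c(0, 5, 5, 0), c(0, 0, 5, 5)))
})

test_that("EA measurement respects ROI masks and saturates at AA", {
  m <- matrix(FALSE, 100, 100)
  m[30:69, 30:69] <- TRUE                      # 40x40 block
  obj <- extract_objects(m, detection_params(0.5), 1)
  roi <- roi_mask(roi_def("r", c(50, 50), "T", 20), c(100, 100), 1)
  aa <- analyzed_area(roi, 1)
  # object fully contains the ROI: EA == AA
  expect_equal(measure_endothelial_area(obj, roi, 1), aa)
  # empty object set
  none <- extract_objects(matrix(FALSE, 100, 100), detection_params(0.5), 1)
  expect_equal(measure_endothelial_area(none, roi, 1), 0)
})

test_that("lowering the DAB threshold never decreases EA", {
  set.seed(13)
  a_dab <- matrix(pmax(rnorm(10000, 0.1, 0.15), 0), 100, 100)
  roi <- matrix(TRUE, 100, 100)
  eas <- vapply(c(0.4, 0.3, 0.2, 0.1, 0.05), function(th) {
    par <- detection_params(th, min_object_area_um2 = 0)
    obj <- extract_objects(threshold_dab(a_dab, par), par, 1)
    measure_endothelial_area(obj, roi, 1)
  }, numeric(1))
  expect_true(all(diff(eas) >= 0))
})
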