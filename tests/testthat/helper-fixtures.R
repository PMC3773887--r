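# Shared fixtures and independent oracles.

# canonical Hematoxylin / DAB OD unit vectors used across tests
s_hema_true <- c(0.65, 0.70, 0.29) / sqrt(sum(c(0.65, 0.70, 0.29)^2))
s_dab_true <- c(0.27, 0.57, 0.78) / sqrt(sum(c(0.27, 0.57, 0.78)^2))

# independent unmixing oracle: two-stage dense grid search over the
# non-negative box (coarse pass over [0, amax], then a 1e-3-step fine
# grid around the coarse minimum; valid because the objective is convex)
oracle_unmix <- function(od, sh, sd_, amax = 5, coarse = 0.05, fine = 1e-3) {
  th <- sum(od * sh); td <- sum(od * sd_); g <- sum(sh * sd_)
  grid_min <- function(ahs, ads) {
    obj <- outer(ahs^2 - 2 * ahs * th, ads^2 - 2 * ads * td, `+`) +
      2 * g * outer(ahs, ads)
    k <- arrayInd(which.min(obj), dim(obj))
    c(ahs[k[1]], ads[k[2]])
  }
  c1 <- grid_min(seq(0, amax, by = coarse), seq(0, amax, by = coarse))
  grid_min(seq(max(0, c1[1] - coarse), c1[1] + coarse, by = fine),
           seq(max(0, c1[2] - coarse), c1[2] + coarse, by = fine))
}

# closed-form Student-t CDF for df = 3 (independent of R's pt)
pt3_closed_form <- function(x) {
  0.5 + (1 / pi) * ((x / sqrt(3)) / (1 + x^2 / 3) + atan(x / sqrt(3)))
}

# small phantom with ROIs, shared across test files (generated once)
small_phantom_fixture <- local({
  cache <- NULL
  function(noise_sd = 3, shading_amplitude = 0.15, seed = 11) {
    key <- paste(noise_sd, shading_amplitude, seed)
    if (!is.null(cache) && cache$key == key) return(cache$val)
    p <- slide_phantom_params(width_px = 700, height_px = 700,
                              pixel_size_um = 1, vessel_area_fraction = 0.02,
                              tile_size_px = 300, noise_sd = noise_sd,
                              shading_amplitude = shading_amplitude,
                              seed = seed)
    rois <- roi_set("P01", list(
      roi_def("tas1", c(180, 180), "TAS", 300),
      roi_def("t1", c(520, 180), "T", 300),
      roi_def("if1", c(350, 520), "IF", 300)))
    val <- list(phantom = generate_slide_phantom(p, rois), rois = rois)
    cache <<- list(key = key, val = val)
    val
  }
})
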