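make_tile <- function(px, row, col, x, y, id = sprintf("r%dc%d", row, col)) {
  list(pixels = px, grid_pos = c(row, col), nominal_offset_px = c(x, y), id = id)
}

flat_img <- function(h, w, value) array(value, dim = c(h, w, 3))

test_that("shading correction inverts the vignette", {
  # self-correction: white corrected by itself is uniformly the target
  set.seed(2)
  sh <- vesselquant:::.shading_field(64, 64, 0.2)
  white <- flat_img(64, 64, 0)
  for (c in 1:3) white[, , c] <- 235 * sh
  expect_true(all(shading_correct(white, white) == 235))

  # flat white: identity up to rounding
  tile <- flat_img(64, 64, 0)
  for (c in 1:3) tile[, , c] <- round(runif(64 * 64, 0, 255))
  expect_equal(shading_correct(tile, flat_img(64, 64, 235)), tile)

  # a 20% corner falloff applied to a flat 200-intensity field inverts
  # to uniform within 1 intensity
  shaded <- flat_img(64, 64, 0)
  for (c in 1:3) shaded[, , c] <- round(200 * sh)
  corrected <- shading_correct(shaded, white)
  expect_lte(max(abs(corrected - 200)), 1)

  # idempotence: correcting the corrected tile with a flat white
  again <- shading_correct(corrected, flat_img(64, 64, 235))
  expect_equal(again, corrected)
})

test_that("shading correction validates its inputs", {
  tile <- flat_img(10, 10, 100)
  bad_white <- flat_img(10, 10, 200)
  bad_white[3, 4, 2] <- 0
  expect_error(shading_correct(tile, bad_white), "\\(3, 4\\)")
  expect_error(shading_correct(tile, flat_img(12, 10, 200)), "dimensions")
})

test_that("registration recovers a known integer shift exactly", {
  ph <- small_phantom_fixture(noise_sd = 0, shading_amplitude = 0)$phantom
  canvas <- ph$ground_truth$canvas
  # two 200x200 crops: b's content is shifted (+2, -1) from its nominal
  a <- canvas[101:300, 101:300, ]
  true_shift <- c(2, -1)
  nominal <- c(150, 0)                         # b nominally right of a
  b <- canvas[(101 + nominal[2] + true_shift[2]):(300 + nominal[2] + true_shift[2]),
              (101 + nominal[1] + true_shift[1]):(300 + nominal[1] + true_shift[1]), ]
  reg <- register_overlap(a, b, nominal)
  expect_false(reg$fallback)
  expect_equal(reg$offset, nominal + true_shift)

  # identical tiles at the exact nominal offset refine to zero shift
  reg0 <- register_overlap(a, a, c(0, 0))
  expect_equal(reg0$offset, c(0, 0))

  # refined offset never leaves the declared search radius
  expect_lte(max(abs(reg$offset - nominal)), 8)
})

test_that("featureless overlaps fall back to the nominal offset", {
  set.seed(77)
  a <- array(round(runif(200 * 200 * 3, 0, 255)), dim = c(200, 200, 3))
  b <- array(round(runif(200 * 200 * 3, 0, 255)), dim = c(200, 200, 3))
  reg <- register_overlap(a, b, c(150, 0))
  expect_true(reg$fallback)
  expect_equal(reg$offset, c(150, 0))
  expect_error(register_overlap(a, b, c(500, 0)), "not overlap")
})

test_that("assembly obeys the bounding box and seam rule", {
  # single tile: canvas equals the tile
  t1 <- make_tile(flat_img(50, 50, 100), 1, 1, 0, 0)
  s1 <- assemble_virtual_slide(list(t1), pixel_size_um = 1)
  expect_equal(s1$pixels, t1$pixels)

  # 15% overlap, zero stage error: dims = tile*n - overlap*(n-1)
  tile <- 100; ov <- 15; n <- 3
  tiles <- list()
  for (r in 1:n) for (c in 1:n)
    tiles[[length(tiles) + 1]] <-
      make_tile(flat_img(tile, tile, (r * n + c) * 10), r, c,
                (c - 1) * (tile - ov), (r - 1) * (tile - ov))
  s <- assemble_virtual_slide(tiles, pixel_size_um = 1)
  expect_equal(dim(s$pixels)[1:2], rep(tile * n - ov * (n - 1), 2))

  dup <- c(tiles, list(make_tile(flat_img(tile, tile, 5), 1, 1, 0, 0)))
  expect_error(assemble_virtual_slide(dup, pixel_size_um = 1), "unique")
})

test_that("stitching a noise-free phantom reproduces the source canvas", {
  fix <- small_phantom_fixture(noise_sd = 0, shading_amplitude = 0)
  ph <- fix$phantom
  slide <- stitch_tiles(ph$tiles, ph$white, ph$pixel_size_um)
  # registration recovered every jittered offset
  off <- slide$provenance$offsets
  tru <- ph$ground_truth$tile_offsets
  m <- merge(off, tru, by = "id")
  expect_equal(m$x.x, m$x.y)
  expect_equal(m$y.x, m$y.y)
  # with exact offsets and consistent tiles the canvas matches everywhere
  # inside the jitter-wide border (stage errors can leave the outermost
  # 3 px uncovered at the slide edge)
  core <- 4:697
  expect_equal(slide$pixels[core, core, ], ph$ground_truth$canvas[core, core, ])
})

test_that("tile sets round-trip through PNG plus manifest", {
  fix <- small_phantom_fixture()
  ph <- fix$phantom
  dir <- file.path(tempdir(), "tileset-roundtrip")
  write_tileset(ph$tiles, ph$white, dir, ph$pixel_size_um)
  back <- read_tileset(dir)
  expect_equal(length(back$tiles), length(ph$tiles))
  expect_equal(back$pixel_size_um, ph$pixel_size_um)
  i <- 3
  expect_equal(back$tiles[[i]]$pixels, ph$tiles[[i]]$pixels)
  expect_equal(back$tiles[[i]]$nominal_offset_px, ph$tiles[[i]]$nominal_offset_px)
  expect_equal(back$white, ph$white)
  unlink(dir, recursive = TRUE)
})

test_that("image I/O preserves 8-bit intensities for PNG and TIFF", {
  set.seed(3)
  img <- array(round(runif(40 * 30 * 3, 0, 255)), dim = c(40, 30, 3))
  for (ext in c(".png", ".tif")) {
    path <- tempfile(fileext = ext)
    write_image(img, path)
    expect_equal(read_image(path), img, tolerance = 1e-9)
  }
})
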