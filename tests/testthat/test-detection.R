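test_that("stage-1 clipping is the closed form of the down-up shift", {
  v <- matrix(c(0L, 10L, 20L, 21L, 100L, 255L), 1, 6)
  expect_equal(as.vector(stage1_clip(v, 21L)), c(21L, 21L, 21L, 21L, 100L, 255L))
  full <- matrix(255L, 4, 4)
  expect_equal(stage1_clip(full, 21L), full)

  set.seed(21)
  for (i in 1:10) {
    img <- rand_img(10, 10, 255L)
    out <- stage1_clip(img, 21L)
    expect_equal(out, pmax(img, 21L))
    # explicit saturating down-then-up composition
    expect_equal(out, pmax(img - 21L, 0L) + 21L)
    expect_false(any(out %in% 1:20))
  }
  expect_error(stage1_clip(v, 0L), "diff")
})

test_that("the morphological pyramid halves each level after C-O filtering", {
  img <- rand_img(64, 64, 255L)
  pyr <- build_pyramid(img)
  expect_identical(pyr$l1, img)
  expect_equal(dim(pyr$l2), c(32L, 32L))
  expect_equal(dim(pyr$l3), c(16L, 16L))
  flat <- matrix(77L, 16, 16)
  expect_true(all(build_pyramid(flat)$l2 == 77L))
  expect_true(all(build_pyramid(flat)$l3 == 77L))

  # period-2 checkerboard is single-pixel structure: flat after C-O
  cb <- matrix(0L, 16, 16)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 30L
  l2 <- build_pyramid(cb)$l2
  expect_equal(length(unique(as.vector(l2[2:7, 2:7]))), 1L)
  co <- co_filter(cb)
  expect_equal(l2, co[seq(1, 16, 2), seq(1, 16, 2)])

  expect_error(build_pyramid(matrix(0L, 4, 4)), "8 x 8")
})

test_that("the per-level residue detector responds to small bright spots", {
  expect_false(any(detect_level(matrix(9L, 10, 10), 4L)))

  img <- matrix(10L, 10, 10)
  img[5, 5] <- 50L
  resid <- img - pmin(opening(closing(img)), img)
  expect_equal(resid[5, 5], 40L)
  expect_true(detect_level(img, 4L)[5, 5])

  set.seed(22)
  for (i in 1:10) {
    img <- rand_img(10, 10, 255L)
    resid <- img - pmin(opening(closing(img)), img)
    expect_true(all(resid >= 0L))
    expect_true(all(resid <= img))
  }
})

test_that("block upsampling replicates pixels and crops to the target", {
  m <- matrix(FALSE, 2, 2); m[1, 2] <- TRUE
  up <- upsample_mask(m, 2L, c(4L, 4L))
  expect_equal(sum(up), 4L)
  expect_true(all(up[1:2, 3:4]))

  expect_equal(sum(upsample_mask(matrix(FALSE, 3, 3), 4L, c(12L, 12L))), 0L)

  set.seed(23)
  m <- rand_mask(8, 8, 0.3)
  expect_equal(sum(upsample_mask(m, 2L, c(16L, 16L))), 4L * sum(m))
  # crop drops exactly the overhang
  up <- upsample_mask(m, 2L, c(15L, 15L))
  expect_equal(dim(up), c(15L, 15L))
  expect_error(upsample_mask(m, 2L, c(64L, 64L)), "too small")
})

test_that("multiscale signals are the OR of the upsampled level detections", {
  flat <- matrix(30L, 64, 64)
  s <- multiscale_signals(flat)
  expect_false(any(s$level2) || any(s$level3) || any(s$union))

  ph <- generate_phantom(phantom_preset("easy", seed = 2, width = 128, height = 128))
  img2 <- stage1_clip(ph$image, 21L)
  s <- multiscale_signals(img2)
  expect_identical(s$union, s$level2 | s$level3)
  expect_equal(dim(s$union), dim(img2))
  # signals hit every truth blob at some level
  for (i in seq_len(nrow(ph$objects))) {
    expect_gt(sum(s$union & ph$calc_labels == i), 0L)
  }
})

test_that("chord removal deletes elongated regions but keeps compact ones", {
  img <- matrix(50L, 90, 90)
  img[10:14, 6:71] <- 80L    # band with a 66-px horizontal chord
  img[40:42, 40:42] <- 80L   # compact 9-px dot
  br <- bright_regions(img, 5L, 50L)
  expect_equal(sum(br & (row(br) %in% 10:14)), 0L)
  expect_true(all(br[40:42, 40:42]))

  sq <- matrix(50L, 90, 90)
  sq[20:59, 20:59] <- 80L    # 40 x 40 square: longest chord 40 <= 50
  expect_true(all(bright_regions(sq, 5L, 50L)[20:59, 20:59]))

  expect_false(any(bright_regions(matrix(7L, 70, 70), 5L, 50L)))
})

test_that("map assembly reconstructs signalled regions and cleans the result", {
  empty <- matrix(FALSE, 64, 64)
  bright <- empty
  bright[20:24, 20:26] <- TRUE  # 35-px candidate region
  expect_false(any(build_map(bright, empty, empty)))

  sig <- empty; sig[22, 22] <- TRUE  # single signal pixel inside the blob
  map <- build_map(bright, sig, empty)
  expect_identical(map, bright)  # whole component recovered

  small <- empty; small[30:31, 40:43] <- TRUE  # 8 px < min_pxls
  sig2 <- empty; sig2[30, 40] <- TRUE
  expect_false(any(build_map(small, sig2, empty)))

  expect_error(build_map(bright, matrix(FALSE, 8, 8), empty), "dimensions")
})

test_that("the end-to-end detector finds well-separated phantom blobs", {
  flat <- matrix(100L, 64, 64)
  expect_false(any(detect_mc(flat)))

  sp <- phantom_spec(width = 256L, height = 256L, lesion_type = "malignant",
                     n_calcs = 6L, diameter_range = c(8.5, 9.3),
                     contrast_range = c(20, 25), cluster_radius = 70,
                     background = "flat", noise_sigma = 0.5,
                     n_distractors = 0L, seed = 5L)
  ph <- generate_phantom(sp)
  map <- detect_mc(ph$image)
  lab <- label_components(map)
  expect_equal(max(lab), 6L)
  for (i in 1:6) expect_gt(sum(map & ph$calc_labels == i), 0L)

  # determinism
  expect_identical(map, detect_mc(ph$image))

  # cleaning postconditions
  sizes <- tabulate(lab[lab > 0], max(lab))
  expect_true(all(sizes >= 10L & sizes <= 70L))
  expect_false(any(map[c(1, 256), ]) || any(map[, c(1, 256)]))
  expect_identical(fill_holes(map), map)
})

test_that("raising blob contrast never loses recovered blobs", {
  recovered <- function(contrast, seed) {
    sp <- phantom_spec(width = 256L, height = 256L, lesion_type = "benign",
                       n_calcs = 4L, diameter_range = c(11.5, 13),
                       contrast_range = c(contrast, contrast + 0.01),
                       background = "flat", noise_sigma = 0.5,
                       n_distractors = 0L, seed = seed)
    ph <- generate_phantom(sp)
    map <- detect_mc(ph$image)
    sum(vapply(1:4, function(i) any(map & ph$calc_labels == i), TRUE))
  }
  for (seed in 0:1) {
    counts <- vapply(c(5, 10, 15, 20, 30, 40), recovered, 0, seed = seed)
    expect_true(all(diff(counts) >= 0))
    expect_gt(counts[6], counts[1])
  }
})

test_that("detection parameters validate and load from config files", {
  p <- detection_params()
  expect_equal(unlist(p[c("diff", "th", "h", "n_pxls", "min_pxls", "max_pxls")]),
               c(diff = 21L, th = 4L, h = 5L, n_pxls = 50L,
                 min_pxls = 10L, max_pxls = 70L))
  expect_error(detection_params(min_pxls = 80L), "min_pxls")
  expect_error(detection_params(th = 0L), "positive")

  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("diff: 15", "h: 3"), cfg)
  p2 <- read_params(cfg)
  expect_equal(p2$diff, 15L)
  expect_equal(p2$h, 3L)
  expect_equal(p2$th, 4L)  # untouched default
  writeLines(c("diff: 15", "bogus: 1"), cfg)
  expect_error(read_params(cfg), "unknown config key")
})
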