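test_that("erosion and dilation match the windowed min/max semantics", {
  se <- se_square3()
  flat <- matrix(7L, 5, 5)
  expect_equal(erode(flat, se), flat)
  expect_equal(dilate(flat, se), flat)

  spike <- matrix(0L, 5, 5); spike[3, 3] <- 50L
  expect_true(all(erode(spike, se) == 0L))
  d <- dilate(spike, se)
  expect_true(all(d[2:4, 2:4] == 50L))
  expect_true(all(d[-(2:4), ] == 0L) && all(d[, -(2:4)] == 0L))

  set.seed(11)
  for (i in 1:20) {
    img <- rand_img(6, 6)
    expect_equal(erode(img, se), o_minfilt(img, se$dr, se$dc))
    expect_equal(dilate(img, se), o_maxfilt(img, se$dr, se$dc))
  }
})

test_that("line structuring elements erode along their own direction only", {
  img <- matrix(0L, 9, 9)
  img[5, 2:8] <- 10L  # horizontal bar, 7 px
  eh <- erode(img, se_line(5L, "horizontal"))
  ev <- erode(img, se_line(5L, "vertical"))
  expect_true(any(eh[5, ] == 10L))  # bar longer than the SE survives
  expect_true(all(ev == 0L))        # 1-px thickness dies vertically
  expect_error(se_line(4L, "horizontal"), "odd")
})

test_that("opening/closing bracket the identity and are idempotent", {
  set.seed(12)
  for (i in 1:10) {
    img <- rand_img(8, 8)
    op <- opening(img); cl <- closing(img)
    expect_true(all(op <= img) && all(img <= cl))
    expect_equal(opening(op), op)
    expect_equal(closing(cl), cl)
    expect_equal(op, o_opening(img))
    expect_equal(cl, o_closing(img))
  }
})

test_that("closing-opening filter removes isolated spikes and pits", {
  img <- matrix(100L, 8, 8)
  img[3, 3] <- 160L  # bright spike
  img[6, 6] <- 40L   # dark pit
  expect_true(all(co_filter(img) == 100L))
  set.seed(13)
  for (i in 1:5) {
    img <- rand_img(16, 16)
    f <- co_filter(img)
    expect_equal(co_filter(f), f)  # idempotent
  }
})

test_that("reconstruction by dilation recovers exactly the marked components", {
  mask <- matrix(0L, 8, 8)
  mask[2:3, 2:3] <- 9L   # blob A
  mask[6:7, 5:7] <- 9L   # blob B
  marker <- matrix(0L, 8, 8)
  marker[2, 2] <- 9L     # seed inside A only
  rec <- reconstruct_by_dilation(marker, mask)
  expected <- matrix(0L, 8, 8); expected[2:3, 2:3] <- 9L
  expect_equal(rec, expected)

  expect_equal(reconstruct_by_dilation(mask, mask), mask)   # fixed point
  zero <- matrix(0L, 8, 8)
  expect_equal(reconstruct_by_dilation(zero, mask), zero)

  set.seed(14)
  for (i in 1:15) {
    mk <- rand_img(7, 7); ms <- rand_img(7, 7)
    mk2 <- pmin(mk, ms)
    rec <- reconstruct_by_dilation(mk2, ms)
    expect_equal(rec, o_reconstruct(mk2, ms))
    expect_true(all(rec >= mk2) && all(rec <= ms))
  }
  expect_error(reconstruct_by_dilation(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               "dimensions")
})

test_that("reconstruction is increasing in both arguments", {
  set.seed(15)
  for (i in 1:10) {
    ms <- rand_img(7, 7)
    mk_small <- pmin(rand_img(7, 7), ms)
    mk_big <- pmin(mk_small + sample(0:2, 49, TRUE), ms)
    expect_true(all(reconstruct_by_dilation(mk_small, ms) <=
                    reconstruct_by_dilation(mk_big, ms)))
  }
})

test_that("h-convexity residue isolates domes of height above h", {
  # a constant image is one global plateau: the reconstruction of f - h
  # under f is f - h, so the residue is uniformly h (and any such
  # full-frame region is later removed by the chord rule)
  expect_true(all(h_convexity(matrix(50L, 6, 6), 5L) == 5L))

  dome <- matrix(10L, 9, 9)
  dome[4:6, 4:6] <- 25L
  dome[5, 5] <- 30L  # peak 20 above background
  hc <- h_convexity(dome, 5L)
  expect_true(all(hc >= 0L & hc <= 5L))
  expect_equal(hc[5, 5], 5L)      # cap value h at the peak
  expect_true(all(hc[dome == 10L] == 0L))  # background fully recovered
  expect_equal(hc, dome - o_reconstruct(pmax(dome - 5L, 0L), dome))

  # peak of height 3 < h on a background whose own dynamic range is below
  # h: values frozen from the brute-force reconstruction oracle
  peak3 <- matrix(10L, 7, 7); peak3[4, 4] <- 13L
  hc3 <- h_convexity(peak3, 5L)
  expect_equal(hc3, peak3 - o_reconstruct(pmax(peak3 - 5L, 0L), peak3))
  expect_equal(hc3[4, 4], 5L)
  expect_true(all(hc3[-25] == 2L))
  expect_error(h_convexity(dome, 0L), ">= 1")
})

test_that("thresholding keeps the pixel equal to the threshold", {
  img <- matrix(c(3L, 4L, 5L, 0L), 2, 2)
  m <- threshold_mask(img, 4L)
  expect_identical(as.vector(m), c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(threshold_mask(img, 0L)))
})

test_that("regional minima are plateaus with no lower neighbour", {
  expect_true(all(regional_minima(matrix(5L, 4, 4))))
  ramp <- matrix(rep(1:6, each = 4), 4, 6)
  rm <- regional_minima(ramp, 8L)
  expect_true(all(rm[, 1]) && !any(rm[, -1]))
  set.seed(16)
  for (i in 1:15) {
    img <- rand_img(9, 9, 6L)
    expect_equal(regional_minima(img, 8L), o_regional_minima(img, 8L))
    expect_equal(regional_minima(img, 4L), o_regional_minima(img, 4L))
  }
})

test_that("minima imposition leaves exactly the marked minima", {
  g <- matrix(c(5L, 1L, 5L, 9L, 5L, 1L, 5L), 1, 7)
  mk <- matrix(FALSE, 1, 7); mk[1, 4] <- TRUE
  out <- minima_imposition(g, mk)
  expect_identical(which(regional_minima(out, 8L)), 4L)

  img <- matrix(3L, 5, 5)
  expect_true(all(minima_imposition(img, matrix(TRUE, 5, 5)) == 0L))
  expect_error(minima_imposition(img, matrix(FALSE, 5, 5)), "at least one")

  set.seed(17)
  for (i in 1:15) {
    img <- rand_img(8, 8)
    mk <- rand_mask(8, 8, 0.15)
    if (!any(mk)) next
    out <- minima_imposition(img, mk)
    expect_identical(regional_minima(out, 8L), label_components(mk, 8L) > 0L)
  }
})

test_that("immersion watershed partitions the image into one basin per minimum", {
  w <- watershed(matrix(9L, 4, 4))
  expect_equal(max(w), 1L)
  expect_false(any(w == 0L))

  prof <- watershed(matrix(c(0L, 1L, 2L, 1L, 0L), 1, 5))
  expect_identical(as.vector(prof), c(1L, 1L, 0L, 2L, 2L))

  set.seed(18)
  for (i in 1:20) {
    img <- rand_img(9, 9, 8L)
    lab <- watershed(img, 8L)
    n_min <- max(label_components(o_regional_minima(img, 8L), 8L))
    expect_equal(max(lab), n_min)
    expect_true(all(lab >= 0L))
    # each basin is connected
    for (k in seq_len(max(lab))) {
      expect_equal(max(label_components(lab == k, 8L)), 1L)
    }
  }
})

test_that("area filter keeps components inside the inclusive band", {
  m <- matrix(FALSE, 30, 45)
  m[2:6, 2] <- TRUE            # 5 px
  m[10, 4:13] <- TRUE          # 10 px
  m[15:21, 20:29] <- TRUE      # 70 px (7 x 10)
  m[23:29, 34:43] <- TRUE      # 70 px ...
  m[22, 34] <- TRUE            # ... plus 1 = 71 px
  f <- area_filter(m, 10L, 70L)
  lab <- label_components(f, 8L)
  sizes <- tabulate(lab[lab > 0], max(lab))
  expect_setequal(sizes, c(10L, 70L))
  expect_equal(area_filter(matrix(FALSE, 5, 5), 1L, 10L), matrix(FALSE, 5, 5))
  expect_error(area_filter(m, 10L, 5L), "min_px")

  set.seed(19)
  for (i in 1:10) {
    mk <- rand_mask(12, 12, 0.35)
    f <- area_filter(mk, 3L, 8L)
    lab <- label_components(mk, 8L)
    keep <- which(tabulate(lab[lab > 0], max(max(lab), 1)) %in% 3:8)
    expect_identical(f, matrix(lab %in% keep, 12, 12))
  }
})

test_that("hole filling and border-object removal behave as set operations", {
  ring <- matrix(FALSE, 9, 9)
  ring[3:7, 3:7] <- TRUE
  ring[4:6, 4:6] <- FALSE
  disk <- matrix(FALSE, 9, 9); disk[3:7, 3:7] <- TRUE
  expect_identical(fill_holes(ring), disk)
  expect_identical(fill_holes(fill_holes(ring)), fill_holes(ring))

  m <- matrix(FALSE, 8, 8)
  m[3:5, 1:2] <- TRUE   # touches left edge
  m[5:6, 5:6] <- TRUE   # interior
  out <- remove_border_objects(m)
  expect_equal(sum(out), 4L)
  expect_true(all(which(out, arr.ind = TRUE)[, 2] %in% 5:6))
})

test_that("binary labelling and hole filling agree with EBImage", {
  skip_if_not_installed("EBImage")
  set.seed(20)
  for (i in 1:5) {
    mk <- rand_mask(15, 15, 0.3)
    ours <- label_components(mk, 4L)  # bwlabel is 4-connected
    theirs <- EBImage::bwlabel(mk + 0)
    # same partition up to label permutation
    expect_equal(max(ours), max(theirs))
    expect_true(all((ours > 0) == (theirs > 0)))
    for (k in seq_len(max(ours))) {
      expect_equal(length(unique(theirs[ours == k])), 1L)
    }
    expect_identical(fill_holes(mk), EBImage::fillHull(mk + 0) > 0)
  }
})
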