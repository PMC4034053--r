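test_that("default fixtures hit the reference geometry exactly", {
  fx <- fixtures_cached()
  for (nm in c("set1", "set2")) {
    orig <- fx[[nm]]$original
    expect_identical(dim(orig$pixels), c(76L, 76L))
    expect_identical(sum(orig$pixels), 1720L)
    expect_equal(round(white_area_ratio(orig), 2), 0.42)
    expect_equal(round(white_area_ratio(orig, include_margin = TRUE), 2), 0.30)
  }
  # orientation dominance is opposite in the two sets
  b1 <- border_length(fx$set1$original)
  b2 <- border_length(fx$set2$original)
  expect_gt(b1$Bv, b1$Bh)
  expect_gt(b2$Bh, b2$Bv)
  # and a quarter turn flips it
  br <- border_length(rotate90(fx$set1$original))
  expect_gt(br$Bh, br$Bv)
})

test_that("total border length is conserved across every polygon transform", {
  fx <- fixtures_cached()
  for (nm in c("set1", "set2")) {
    totals <- vapply(c("original", "mirror", "contrast", "fg"),
                     function(tr) border_length(fx[[nm]][[tr]])$total,
                     integer(1))
    expect_identical(unname(unique(totals)), totals[["original"]])
  }
})

test_that("polygon generator hits arbitrary white targets deterministically", {
  n <- 16L
  sp <- profile_spec(c(8L, rep(5L, 14L), 8L), "left")
  img1 <- generate_polygon_stimulus(sp, n, 2L, target_white = 100L)
  img2 <- generate_polygon_stimulus(sp, n, 2L, target_white = 100L)
  expect_identical(img1$pixels, img2$pixels)
  expect_identical(sum(img1$pixels), 100L)
  # straight profile at the midline covers exactly half the inner square
  half <- generate_polygon_stimulus(profile_spec(rep(8L, n), "left"), n, 2L)
  expect_equal(white_area_ratio(half), 0.5)
  # unreachable targets fail with the achievable range
  expect_error(generate_polygon_stimulus(sp, n, 2L, target_white = 5L),
               "achievable range")
  expect_error(generate_polygon_stimulus(sp, n, 2L, target_white = 999L),
               "achievable range")
})

test_that("tiny polygon rasterization matches hand enumeration", {
  # n = 4, m = 1, profile p = (2,2,2,2): white occupies columns 1-2 of the
  # inner block in all four inner rows -> 8 white pixels in a 6x6 array
  img <- generate_polygon_stimulus(profile_spec(c(2L, 2L, 2L, 2L), "left"),
                                   4L, 1L, target_white = 8L)
  expect_identical(dim(img$pixels), c(6L, 6L))
  expect_identical(sum(img$pixels), 8L)
  expected <- matrix(0L, 6L, 6L)
  expected[2:5, 2:3] <- 1L
  expect_identical(img$pixels, expected)
})

test_that("mirror, contrast and fg transforms obey their algebra", {
  fx <- fixtures_cached()
  img <- fx$set1$original
  expect_identical(mirror_reverse(mirror_reverse(img))$pixels, img$pixels)
  expect_identical(contrast_reverse(contrast_reverse(img))$pixels, img$pixels)
  expect_identical(sum(mirror_reverse(img)$pixels), sum(img$pixels))
  # contrast complement, margins included
  expect_identical(sum(contrast_reverse(img)$pixels),
                   length(img$pixels) - sum(img$pixels))
  expect_equal(white_area_ratio(contrast_reverse(img), TRUE),
               1 - 1720 / 5776)
  # fg partitions the inner square exactly
  fg <- fg_reverse(img)
  expect_identical(sum(fg$pixels) + sum(img$pixels), img$n * img$n)
  inner <- seq.int(img$m + 1L, img$m + img$n)
  expect_true(all(fg$pixels[inner, inner] + img$pixels[inner, inner] == 1L))
  # margins stay black after fg reversal
  expect_identical(sum(fg$pixels) ,
                   sum(fg$pixels[inner, inner]))
  # four quarter turns are the identity
  expect_identical(
    rotate90(rotate90(rotate90(rotate90(img))))$pixels, img$pixels)
  # single-pixel index maps
  tiny <- binary_image(matrix(c(1L, rep(0L, 8L)), 3L, 3L, byrow = TRUE),
                       3L, 0L)
  expect_identical(which(mirror_reverse(tiny)$pixels == 1L),
                   which(matrix(c(0L,0L,1L, 0L,0L,0L, 0L,0L,0L),
                                3L, 3L, byrow = TRUE) == 1L))
})

test_that("border metrics match brute-force counting and transform rules", {
  # hand-enumerable cases
  uni <- binary_image(matrix(0L, 4L, 4L), 4L, 0L)
  expect_identical(border_length(uni), list(Bh = 0L, Bv = 0L, total = 0L))
  one <- matrix(0L, 5L, 5L); one[3L, 3L] <- 1L
  expect_identical(border_length(binary_image(one, 5L, 0L)),
                   list(Bh = 2L, Bv = 2L, total = 4L))
  blk <- matrix(0L, 6L, 6L); blk[3:4, 3:4] <- 1L
  expect_identical(border_length(binary_image(blk, 6L, 0L)),
                   list(Bh = 4L, Bv = 4L, total = 8L))
  # property: agreement with the brute-force oracle; mirror preserves,
  # contrast preserves, rotation swaps
  set.seed(42)
  for (i in 1:25) {
    px <- random_binary_image(8L)
    img <- binary_image(px, 8L, 0L)
    b <- border_length(img)
    expect_identical(b, oracle_border_length(px))
    expect_identical(border_length(mirror_reverse(img)), b)
    expect_identical(border_length(contrast_reverse(img)), b)
    br <- border_length(rotate90(img))
    expect_identical(br$Bh, b$Bv)
    expect_identical(br$Bv, b$Bh)
  }
})

test_that("circle stimuli rasterize correctly and solve for the area ratio", {
  r <- default_circle_radius()
  disc <- generate_circle_stimulus(r, FALSE)
  expect_lt(abs(white_area_ratio(disc) - 0.42), 0.01)
  # pixel enumeration oracle for the disc area
  ctr <- (64 + 1) / 2
  cnt <- 0L
  for (rr in 1:64) for (cc in 1:64)
    if ((rr - ctr)^2 + (cc - ctr)^2 <= r^2) cnt <- cnt + 1L
  expect_identical(sum(disc$pixels), cnt)
  # connected variant adds the midline bridge without double counting
  conn <- generate_circle_stimulus(r, TRUE)
  bridge_col <- 32L
  extra <- sum((1:64 - ctr)^2 + (bridge_col - ctr)^2 > r^2)
  expect_identical(sum(conn$pixels), cnt + extra)
  # centred disc is exactly mirror-symmetric
  expect_identical(mirror_reverse(disc)$pixels, disc$pixels)
  expect_error(generate_circle_stimulus(40, FALSE), "radius")
})

test_that("make_image_set enforces border conservation for polygons only", {
  fx <- fixtures_cached()
  expect_true(fx$set1$border_equal)
  disc_set <- make_image_set(
    generate_circle_stimulus(default_circle_radius(), FALSE),
    label = "circle-disconnected")
  expect_false(disc_set$border_equal)   # flagged, not an error
  dims <- vapply(c("original", "mirror", "contrast", "fg"),
                 function(tr) nrow(disc_set[[tr]]$pixels), integer(1))
  expect_true(all(dims == dims[[1L]]))
})

test_that("figure_mask picks the smaller region on either polarity", {
  fx <- fixtures_cached()
  img <- fx$set1$original
  expect_identical(unname(figure_mask(img)), img$pixels == 1L)
  expect_identical(unname(figure_mask(contrast_reverse(img))),
                   img$pixels == 1L)   # same polygon, now black
})
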