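cfg <- run_config()

test_that("patch scales recover the printed operating point", {
  ps <- patch_scale(gamma = 4, lambda_s = 0.56, fs = 16, delta_uV = 9)
  expect_equal(round(ps$s_x), 3)
  expect_equal(ps$s_y, 3)
  expect_equal(ps$s, 3L)
  expect_equal(patch_scale(12, 1, 1, 1.0)$s_x, 1)
  expect_warning(patch_scale(4, 1, 16, 9), "differ")
})

test_that("the default keypoint sits at 0.55 s on the zero line", {
  img <- render_plot(standardize_signal(sin(1:16), gamma = 4))
  kp <- default_keypoint(img, cfg)
  expect_equal(kp$x, 35L)
  expect_equal(kp$y, img$zero_row)
  expect_equal(kp$s, 3L)
  kp1 <- default_keypoint(img, run_config(gamma = 1))
  expect_equal(kp1$x, 8L)
})

test_that("gradients are central differences with one-sided borders", {
  img <- matrix(0, 5, 5)
  expect_true(all(gradient_field(img)$magnitude == 0))

  img[3, 3] <- 255
  g <- gradient_field(img)
  expect_equal(g$magnitude[3, 2], 127.5)   # left neighbour: d/dx = +127.5
  expect_equal(g$angle[3, 2], 0)
  expect_equal(g$magnitude[3, 4], 127.5)
  expect_equal(g$angle[3, 4], 180)
  expect_equal(g$magnitude[2, 3], 127.5)   # above: d/dy = +127.5, +y is down
  expect_equal(g$angle[2, 3], 90)
  expect_equal(g$angle[4, 3], 270)
  expect_equal(g$magnitude[3, 3], 0)

  # border pixels use one-sided differences
  edge <- matrix(0, 3, 3); edge[1, 2] <- 255
  ge <- gradient_field(edge)
  expect_equal(ge$magnitude[1, 1], 255)
})

test_that("rotating the image by 90 degrees rotates the angle field", {
  set.seed(21)
  img <- matrix(sample(c(0, 255), 49, TRUE), 7, 7)
  g <- gradient_field(img)
  # counterclockwise rotation in row/col space: (r, c) -> (nc - c + 1, r)
  rot <- t(img)[ncol(img):1, ]
  gr <- gradient_field(rot)
  interior <- 2:6
  for (r in interior) for (c in interior) {
    if (g$magnitude[r, c] == 0) next
    expect_equal(gr$magnitude[ncol(img) - c + 1, r], g$magnitude[r, c])
    expect_equal(gr$angle[ncol(img) - c + 1, r] %% 360,
                 (g$angle[r, c] - 90) %% 360)
  }
})

test_that("an aligned unit gradient lands its whole mass in a single cell", {
  # zero field -> zero descriptor
  zero <- structure(list(magnitude = matrix(0, 36, 36),
                         angle = matrix(0, 36, 36)),
                    class = "gradient_field")
  kp <- keypoint(17, 17, s = 3)
  expect_true(all(hist_descriptor(zero, kp)$h == 0))

  # one gradient of magnitude m exactly at the centre of block (i=1, j=2)
  # with angle exactly at bin 90: all interpolation weights collapse to 1
  # (s = 2 puts block centres at integer pixel offsets +/-3, +/-9)
  s <- 2; bs <- 3 * s
  kp2 <- keypoint(17, 17, s = s)
  m <- 2.5
  f <- zero
  px <- 17 + 3L                      # v_x = +1/2  -> block col j = 2
  py <- 17 - 3L                      # v_y = -1/2  -> block row i = 1
  f$magnitude[py + 1, px + 1] <- m
  f$angle[py + 1, px + 1] <- 90
  d <- hist_descriptor(f, kp2)
  idx <- 8 * (4 * 1 + 2) + (90 / 45) + 1
  expect_equal(d$h[idx], 3 * s * m)
  expect_equal(sum(d$h), 3 * s * m)   # nothing leaks to other cells
})

test_that("the descriptor matches the literal per-pixel oracle", {
  set.seed(33)
  kp <- keypoint(17, 17, s = 3)
  for (rep in 1:10) {
    f <- random_gradient_field()
    got <- hist_descriptor(f, kp)$h
    ref <- oracle_descriptor(f$magnitude, f$angle, 17, 17, 3)
    expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-9)
  }
  # and at a different scale / off-centre keypoint
  f <- random_gradient_field(20, 28)
  kp2 <- keypoint(9, 11, s = 1)
  expect_lt(max(abs(hist_descriptor(f, kp2)$h -
                    oracle_descriptor(f$magnitude, f$angle, 9, 11, 1))) /
              max(abs(hist_descriptor(f, kp2)$h)), 1e-9)
})

test_that("trilinear weights form a partition of unity on interior pixels", {
  # field confined to the interior region |v| <= 3/2 in both axes
  set.seed(44)
  s <- 3; bs <- 3 * s
  mag <- matrix(0, 36, 36)
  ang <- matrix(runif(36 * 36, 0, 360), 36, 36)
  interior <- which(abs(row(mag) - 1 - 17) <= 1.5 * bs &
                    abs(col(mag) - 1 - 17) <= 1.5 * bs)
  mag[interior] <- abs(rnorm(length(interior)))
  f <- structure(list(magnitude = mag, angle = ang), class = "gradient_field")
  d <- hist_descriptor(f, keypoint(17, 17, s = 3))
  expect_equal(sum(d$h), 3 * s * sum(mag), tolerance = 1e-9)
})

test_that("the descriptor is covariant under joint integer translation", {
  set.seed(55)
  f <- random_gradient_field(50, 50)
  f$magnitude[-(20:31), ] <- 0   # confine mass so both views contain it all
  f$magnitude[, -(20:31)] <- 0
  base <- hist_descriptor(crop_field(f, 1:36, 1:36), keypoint(17, 17, 3))$h
  shifted <- hist_descriptor(crop_field(f, 8:43, 6:41), keypoint(17 - 5, 17 - 7, 3))$h
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("horizontally mirroring the field permutes the descriptor", {
  set.seed(66)
  f <- random_gradient_field(35, 35)   # odd size: mirror fixes the centre
  kp <- keypoint(17, 17, 3)
  d <- hist_descriptor(f, kp)$h
  fm <- f
  fm$magnitude <- f$magnitude[, 35:1]
  fm$angle <- (180 - f$angle[, 35:1]) %% 360
  dm <- hist_descriptor(fm, kp)$h
  # block columns flip (j -> 3 - j) and angle bins reflect about the vertical
  perm <- function(h) {
    out <- numeric(128)
    for (i in 0:3) for (j in 0:3) for (b in 0:7) {
      bm <- (4 - b) %% 8   # theta -> 180 - theta
      out[8 * (4 * i + (3 - j)) + bm + 1] <- h[8 * (4 * i + j) + b + 1]
    }
    out
  }
  expect_equal(dm, perm(d), tolerance = 1e-9)
})

test_that("normalization scales to unit maximum and is idempotent", {
  set.seed(77)
  f <- random_gradient_field()
  d <- hist_descriptor(f, keypoint(17, 17, 3))
  n1 <- normalize_descriptor(d)
  expect_equal(max(abs(n1$h)), 1)
  expect_true(all(n1$h >= 0 & n1$h <= 1))
  expect_equal(normalize_descriptor(n1)$h, n1$h)

  zero <- structure(list(magnitude = matrix(0, 36, 36),
                         angle = matrix(0, 36, 36)), class = "gradient_field")
  dz <- normalize_descriptor(hist_descriptor(zero, keypoint(17, 17, 3)))
  expect_true(all(dz$h == 0))
})

test_that("keypoints with no support in the image are rejected", {
  f <- random_gradient_field(10, 10)
  expect_error(hist_descriptor(f, keypoint(500, 500, 3)), "empty patch")
})
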