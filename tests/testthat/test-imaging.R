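# Imaging module: grayscale, smoothing, gradient, NMS, hysteresis,
# boundary tracing, chain-code area, lesion metrics.

test_that("to_grayscale is the clipped weighted channel sum", {
  w <- grayscale_weights(0.30, 0.59, 0.11)
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(to_grayscale(px(255, 255, 255), w)[1, 1], 255)
  expect_equal(to_grayscale(px(100, 100, 100), w)[1, 1], 100)
  expect_equal(to_grayscale(px(200, 100, 50), w)[1, 1], 124.5)
  # uniform-channel pixels are fixed points for any unit-sum weights
  g <- matrix(runif(20, 0, 255), 4, 5)
  expect_equal(to_grayscale(gray_to_rgb(g), w), g)
  expect_equal(to_grayscale(g, w), g)
  expect_error(to_grayscale(matrix(numeric(0), 0, 0)), "empty")
  expect_error(grayscale_weights(alpha = 0.5), "alpha")
})

test_that("gaussian_kernel is normalised, symmetric, peaked at centre", {
  for (sigma in c(0.6, 1, 1.4, 3)) {
    k <- gaussian_kernel(sigma, 2)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_equal(k, t(k))
    expect_equal(k, k[5:1, 5:1])
    expect_equal(which.max(k), 13L)  # centre of 5x5
  }
  k <- gaussian_kernel(1, 1)
  expect_equal(k[2, 2] / k[1, 1], exp(1), tolerance = 1e-12)
  expect_error(gaussian_kernel(0), "sigma")
  expect_error(gaussian_kernel(-1), "sigma")
})

test_that("smooth_image: fixed points, impulse response, range bound", {
  k <- gaussian_kernel(1.4, 2)
  const <- matrix(42, 8, 9)
  expect_equal(smooth_image(const, k), const)
  # impulse away from borders reproduces the kernel
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  expect_equal(smooth_image(imp, k)[3:7, 3:7], k)
  # uniform 3x3 kernel arithmetic
  u <- matrix(1 / 9, 3, 3)
  m <- matrix(10, 3, 3); m[2, 2] <- 100
  expect_equal(smooth_image(m, u)[2, 2], 20)
  # never expands the intensity range
  set.seed(5)
  g <- matrix(runif(400, 0, 255), 20, 20)
  sm <- smooth_image(g, k)
  expect_gte(min(sm), min(g))
  expect_lte(max(sm), max(g))
  expect_error(smooth_image(matrix(0, 2, 2), k), "larger")
})

test_that("image_gradient matches the 2x2 finite-difference stencil", {
  expect_error(image_gradient(matrix(0, 1, 5)), "2x2")
  const <- matrix(7, 6, 6)
  f <- image_gradient(const)
  expect_true(all(f$magnitude == 0))
  # ramp in x (intensity = column index): Gx = 1, Gy = 0
  ramp <- matrix(rep(1:8, each = 6), 6, 8)
  f <- image_gradient(ramp)
  expect_true(all(abs(f$gx - 1) < 1e-12))
  expect_true(all(abs(f$gy) < 1e-12))
  # magnitude identity on a random field
  set.seed(2)
  g <- matrix(runif(100, 0, 255), 10, 10)
  f <- image_gradient(g)
  expect_equal(f$magnitude^2, f$gx^2 + f$gy^2, tolerance = 1e-12)
  expect_equal(dim(f$gx), c(9, 9))
})

test_that("nonmax_suppress keeps ridge maxima and is support-shrinking", {
  # 1-D profile 1,3,5,3,1 across a vertical edge: only the 5 survives
  g <- matrix(rep(c(1, 3, 5, 3, 1), each = 5), 5, 5)
  field <- structure(list(gx = g, gy = g * 0, magnitude = g,
                          direction = g * 0), class = "gradient_field")
  th <- nonmax_suppress(field)
  expect_true(all(th[, 3] == 5))
  expect_true(all(th[, -3] == 0))
  # zero field -> all zeros; single spike retained
  z <- matrix(0, 4, 4)
  fz <- structure(list(gx = z, gy = z, magnitude = z, direction = z),
                  class = "gradient_field")
  expect_true(all(nonmax_suppress(fz) == 0))
  sp <- z; sp[2, 3] <- 9
  fs <- structure(list(gx = sp, gy = z, magnitude = sp, direction = z),
                  class = "gradient_field")
  expect_equal(nonmax_suppress(fs), sp)
  # subset property on random fields
  set.seed(3)
  for (i in 1:5) {
    g <- matrix(runif(15 * 15, 0, 255), 15, 15)
    f <- image_gradient(smooth_image(g, gaussian_kernel(1, 1)))
    th <- nonmax_suppress(f)
    expect_true(all(th[th > 0] == f$magnitude[th > 0]))
    expect_true(all(th == 0 | f$magnitude > 0))
  }
})

test_that("hysteresis_threshold matches the brute-force BFS oracle", {
  expect_error(hysteresis_threshold(matrix(1, 2, 2), 5, 1), "t_low")
  m <- matrix(c(0, 2, 0,
                0, 2, 0,
                0, 9, 0), 3, 3, byrow = TRUE)
  # weak path touching one strong pixel: all retained
  expect_equal(sum(hysteresis_threshold(m, 1, 5)), 3)
  # all below t_low -> empty; all strong -> all nonzero retained
  expect_true(all(hysteresis_threshold(m, 10, 20) == 0))
  expect_equal(sum(hysteresis_threshold(m, 0.5, 1) > 0), 3)
  set.seed(4)
  for (i in 1:20) {
    m <- matrix(rexp(32 * 32, 1 / 20), 32, 32)
    m[m < 5] <- 0
    t_high <- runif(1, 20, 60); t_low <- runif(1, 1, t_high)
    expect_identical(hysteresis_threshold(m, t_low, t_high),
                     hysteresis_oracle(m, t_low, t_high))
  }
})

test_that("trace_boundary produces closed clockwise chains", {
  expect_error(trace_boundary(matrix(0, 3, 3)), "empty")
  two <- matrix(0, 5, 5); two[2, 2] <- 1; two[4, 4] <- 1
  expect_error(trace_boundary(two), "components")
  # single pixel: degenerate closed chain
  one <- matrix(0, 3, 3); one[2, 2] <- 1
  ch <- trace_boundary(one)
  expect_length(ch$codes, 0)
  expect_equal(ch$start, c(2, 2))
  # 2x2 square: 4 codes, zero net displacement
  sq <- matrix(0, 4, 4); sq[2:3, 2:3] <- 1
  ch <- trace_boundary(sq)
  expect_length(ch$codes, 4)
  steps <- prostadss:::.freeman_steps[ch$codes + 1, , drop = FALSE]
  expect_equal(colSums(steps), c(0, 0))
  # closure property on random convex shapes
  set.seed(6)
  for (i in 1:10) {
    mask <- random_convex_mask(32)
    ch <- trace_boundary(mask)
    if (length(ch$codes)) {
      steps <- prostadss:::.freeman_steps[ch$codes + 1, , drop = FALSE]
      expect_equal(colSums(steps), c(0, 0))
      # every chain point is a boundary pixel of the mask
      on_mask <- mask[ch$points]
      expect_true(all(on_mask))
    }
  }
})

test_that("label_chain maps codes to vertical-step signs", {
  expect_equal(label_chain(c(0L, 4L)), c(0L, 0L))
  expect_equal(label_chain(1:3), c(-1L, -1L, -1L))
  expect_equal(label_chain(5:7), c(1L, 1L, 1L))
  expect_error(label_chain(8L), "0..7")
  # label equals the row step actually taken along a traced chain
  sq <- matrix(0, 5, 6); sq[2:4, 2:5] <- 1
  ch <- trace_boundary(sq)
  steps <- prostadss:::.freeman_steps[ch$codes + 1, , drop = FALSE]
  expect_equal(label_chain(ch), sign(steps[, 1]))
})

test_that("chain_area equals the flood-fill pixel count", {
  one <- matrix(0, 3, 3); one[2, 2] <- 1
  expect_equal(chain_area(trace_boundary(one)), 1L)
  sq3 <- matrix(0, 5, 5); sq3[2:4, 2:4] <- 1
  expect_equal(chain_area(trace_boundary(sq3)), 9L)
  # all w x h rectangles, 2 <= w,h <= 10
  for (w in 2:10) for (h in 2:10) {
    r <- matrix(0, h + 4, w + 4); r[3:(2 + h), 3:(2 + w)] <- 1
    expect_identical(chain_area(trace_boundary(r)), as.integer(w * h))
  }
  # random convex shapes against the oracle
  set.seed(7)
  for (i in 1:50) {
    mask <- random_convex_mask(sample(20:64, 1))
    expect_identical(chain_area(trace_boundary(mask)),
                     as.integer(flood_fill_count(mask)))
  }
})

test_that("mean_gray_level is the arithmetic mask mean", {
  g <- matrix(180, 4, 4)
  expect_equal(mean_gray_level(g, g > 0), 180)
  g2 <- matrix(c(100, 200, 0, 0), 2, 2)
  expect_equal(mean_gray_level(g2, g2 > 0), 150)
  g3 <- matrix(c(10, 20, 40, 0), 2, 2)
  expect_equal(mean_gray_level(g3, g3 > 0), 70 / 3)
  expect_error(mean_gray_level(g, g < 0), "empty")
})

test_that("extract_lesion_metrics recovers synthetic lesions", {
  expect_false(extract_lesion_metrics(matrix(100, 32, 32))$informative)
  set.seed(8)
  for (s in c(1, 3, 4)) {
    les <- render_lesion_image(s, default_lesion_params(noise_sd = 0))
    met <- extract_lesion_metrics(les$image)
    expect_lt(abs(met$area_px - les$true_area_px) / les$true_area_px, 0.10)
    # uniform lesion: mean gray near the rendered intensity
    expect_lt(abs(met$mean_gray - les$true_mean_gray) / les$true_mean_gray, 0.15)
  }
  # a large bright lesion passes the screening rule
  set.seed(9)
  les <- render_lesion_image(4, default_lesion_params(noise_sd = 0))
  expect_true(extract_lesion_metrics(les$image)$informative)
})

test_that("plain-text image IO round-trips", {
  set.seed(10)
  g <- matrix(sample(0:255, 48, TRUE), 6, 8)
  tf <- tempfile(fileext = ".pgm")
  write_image(g, tf)
  expect_equal(read_image(tf), g)
  rgb <- array(sample(0:255, 6 * 8 * 3, TRUE), dim = c(6, 8, 3))
  tf2 <- tempfile(fileext = ".ppm")
  write_image(rgb, tf2)
  expect_equal(read_image(tf2), rgb)
  expect_error(read_image(tempfile()), "not found")
})
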