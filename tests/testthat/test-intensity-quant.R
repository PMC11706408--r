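test_that("analytic disk/annulus images give the exact N:C ratio", {
  r <- render_nucleus_image(nucleus_render_params(true_nc_ratio = 2,
                                                  cytoplasm_intensity = 100))
  m <- measure_nc_ratio(r$image, r$center, pixel_size = 0.15)
  expect_equal(m$nc_ratio, 2)
  expect_equal(m$nuclear_fi, 200)
  expect_equal(m$cytoplasmic_fi, 100)
})

test_that("the N:C ratio is invariant to background and gain", {
  r <- render_nucleus_image(nucleus_render_params(true_nc_ratio = 2,
                                                  cytoplasm_intensity = 100))
  m0 <- measure_nc_ratio(r$image, r$center, 0.15)
  m1 <- measure_nc_ratio(r$image + 50, r$center, 0.15, background = 50)
  expect_equal(m1$nc_ratio, m0$nc_ratio)
  m2 <- measure_nc_ratio(r$image * 3.2, r$center, 0.15)
  expect_equal(m2$nc_ratio, m0$nc_ratio)
  # background from rectangles drawn on a padded image region
  img <- r$image + 50
  bg_rois <- list(list(x0 = 0.2, y0 = 0.2, w = 1, h = 1))
  img[rect_mask(dim(img), 0.2, 0.2, 1, 1, 0.15)] <- 50
  m3 <- measure_nc_ratio(img, r$center, 0.15, background = bg_rois)
  expect_equal(m3$background_fi, 50)
})

test_that("neighbour exclusion matches a ground-truth-mask oracle within 1%", {
  p <- nucleus_render_params(true_nc_ratio = 2, neighbor_centers =
                               list(c(9 + 4.6, 9)), noise_sd = 2, seed = 3)
  r <- render_nucleus_image(p)
  m <- measure_nc_ratio(r$image, r$center, 0.15,
                        neighbor_mask = r$neighbor_mask)
  d <- dim(r$image)
  ann <- disk_mask(d, r$center, 2.25 + 1, 0.15) &
    !disk_mask(d, r$center, 2.25, 0.15) & !r$neighbor_mask
  oracle <- mean(r$image[r$nucleus_mask]) / mean(r$image[ann])
  expect_lt(abs(m$nc_ratio / oracle - 1), 0.01)
  # without exclusion the bright neighbour inflates the cytoplasm estimate
  m_no <- measure_nc_ratio(r$image, r$center, 0.15)
  expect_lt(m_no$nc_ratio, m$nc_ratio)
})

test_that("a fully-covered annulus and undefined denominators error or flag", {
  r <- render_nucleus_image(nucleus_render_params())
  expect_error(measure_nc_ratio(r$image, r$center, 0.15,
                                neighbor_mask = matrix(TRUE, nrow(r$image),
                                                       ncol(r$image))),
               "annulus")
  m <- measure_nc_ratio(r$image, r$center, 0.15, background = 1e6)
  expect_true(is.na(m$nc_ratio))
  expect_equal(m$flag, "undefined")
  expect_error(measure_nc_ratio(r$image, c(0.5, 0.5), 0.15), "outside")
})

test_that("pre-mitotic N:C takes the top three eligible frames", {
  t <- seq(0, 30, by = 2)
  nc <- rep(1, length(t))
  nc[t <= 10] <- c(1.0, 1.5, 2.0, 2.5, 1.2, 1.1)
  # NEBD at 20: eligible frames are t <= 10
  expect_equal(as.numeric(premitotic_nc(t, nc, t_nebd = 20)), 2)
  allsame <- premitotic_nc(t, rep(1.3, length(t)), t_nebd = 20)
  expect_equal(as.numeric(allsame), 1.3)
  expect_error(premitotic_nc(t, nc, t_nebd = 5), "no frames")
  # brute-force sort-and-average oracle on random traces
  set.seed(41)
  for (i in 1:20) {
    nc <- runif(16, 0.5, 3)
    got <- as.numeric(premitotic_nc(t, nc, t_nebd = 25))
    elig <- nc[t <= 15]
    expect_equal(got, mean(sort(elig, decreasing = TRUE)[1:3]),
                 tolerance = 1e-12)
  }
})

test_that("pz counting returns 0 on empty stacks and all blobs when easy", {
  empty <- simulate_pz_stack(pz_field_params(0, volume = c(20, 20, 8),
                                             pixel_size = 0.5, snr = Inf,
                                             n_frames = 5))
  expect_equal(count_pz_nuclei(empty$stack, 0.5, 1)$count, 0)
  easy <- simulate_pz_stack(pz_field_params(30, min_spacing = 6,
                                            volume = c(45, 45, 12),
                                            pixel_size = 0.5, snr = Inf,
                                            n_frames = 5, seed = 2))
  res <- count_pz_nuclei(easy$stack, 0.5, 1,
                         blob_diameter = easy$params$blob_fwhm)
  expect_equal(res$count, 30)
  # counting is invariant to intensity rescaling
  res2 <- count_pz_nuclei(easy$stack * 37.5, 0.5, 1,
                          blob_diameter = easy$params$blob_fwhm)
  expect_equal(res2$count, 30)
})

test_that("pz counting validates its inputs", {
  s <- simulate_pz_stack(pz_field_params(3, volume = c(20, 20, 8),
                                         pixel_size = 0.5, n_frames = 3))
  expect_error(count_pz_nuclei(s$stack, 0.5, 1), "fewer than")
  expect_error(count_pz_nuclei(s$stack[, , , 1, drop = FALSE]), "metadata")
})

test_that("mitotic index enforces its invariants", {
  expect_equal(mitotic_index(10, 200), 0.05)
  expect_equal(mitotic_index(0, 200), 0)
  expect_error(mitotic_index(5, 0), "positive")
  expect_error(mitotic_index(201, 200), "between")
})

test_that("depletion FI follows the clamp-and-normalize rules", {
  img <- matrix(10, 80, 80)
  img[rect_mask(dim(img), 2, 2, 4, 4, 0.25)] <- 12
  img[rect_mask(dim(img), 8, 8, 4, 4, 0.25)] <- 14
  rois <- list(list(x0 = 2, y0 = 2, w = 4, h = 4),
               list(x0 = 8, y0 = 8, w = 4, h = 4),
               list(x0 = 14, y0 = 14, w = 4, h = 4))
  res <- measure_depletion_fi(img, rois, 0.25, background_value = 6,
                              reference_group_mean = 12)
  expect_equal(res$fi_raw, 12)
  expect_equal(res$fi_bgsub, 6)
  expect_equal(res$fi_norm, 0.5)
  # at/below background clamps to zero
  res0 <- measure_depletion_fi(img, rois, 0.25, background_value = 12)
  expect_equal(res0$fi_bgsub, 0)
  expect_error(measure_depletion_fi(img, rois, 0.25, 0,
                                    reference_group_mean = 0), "positive")
  # brute-force pixel-mean oracle on a random image
  set.seed(43)
  rimg <- matrix(runif(80 * 80, 0, 100), 80, 80)
  rr <- measure_depletion_fi(rimg, rois, 0.25)
  oracle <- mean(vapply(rois, function(roi)
    mean(rimg[rect_mask(dim(rimg), roi$x0, roi$y0, roi$w, roi$h, 0.25)]),
    numeric(1)))
  expect_equal(rr$fi_raw, oracle, tolerance = 1e-12)
})

test_that("assay ratios convert counts to percentages", {
  res <- assay_ratios(c(none = 18, metaphase = 1, anaphase = 1))
  expect_equal(res$percent, c(90, 5, 5))
  expect_equal(sum(res$percent), 100)
  expect_equal(assay_ratios(c(unhatched = 0, hatched = 120))$percent[1], 0)
  expect_error(assay_ratios(c(a = -1, b = 2)), "non-negative")
})

test_that("the 2x2 exact test matches hypergeometric enumeration", {
  a <- c(none = 18, meta = 1, ana = 1)
  b <- c(none = 12, meta = 5, ana = 3)
  ft <- error_class_test(a, b)
  # brute-force: enumerate all tables with the same margins
  n_err_a <- 2; n_a <- 20; n_err_b <- 8; n_b <- 20
  k <- n_err_a + n_err_b
  probs <- dhyper(0:k, n_a, n_b, k)
  p_oracle <- sum(probs[probs <= dhyper(n_err_a, n_a, n_b, k) *
                          (1 + 1e-7)])
  expect_equal(ft$p.value, p_oracle, tolerance = 1e-9)
})
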