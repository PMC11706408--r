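landmarks_for <- function(t_nebd, t_s, t_ao)
  score_landmarks_from_variance(
    data.frame(t = c(0, t_nebd, (t_nebd + t_ao) / 2, t_ao, t_ao + 1),
               variance = c(0, 0, 1, 0.9, 0)))

fixed_landmarks <- function(t_nebd, t_s, t_ao) {
  lm <- landmarks_for(t_nebd, t_s, t_ao)
  lm$t_nebd <- t_nebd; lm$t_s <- t_s; lm$t_ao <- t_ao
  lm$duration <- t_ao - t_s
  lm
}

test_that("degenerate constant-length mitosis yields C=7, D=0, E=0, F=0", {
  t <- (0:39) * 0.5
  s <- data.frame(t = t, length = rep(7, 40))
  axes <- data.frame(t = t, ux = 1, uy = 0, uz = 0)
  lm <- fixed_landmarks(5, 7, 11.5)
  fx <- extract_features(s, axes, lm, frame_interval = 0.5, seed = 1)
  expect_equal(fx$C_mean_length, 7)
  expect_equal(fx$D_length_variance, 0)
  expect_equal(fx$E_length_fluctuation, 0)
  expect_equal(fx$F_rotation, 0)
  expect_equal(fx$B_duration, 4.5)
})

test_that("exactly linear anaphase recovers its slope as G", {
  t <- (0:39) * 0.5
  len <- ifelse(t <= 10, 7, 7 + 1.2 * (t - 10))
  s <- data.frame(t = t, length = len)
  lm <- fixed_landmarks(5, 7, 10)
  fx <- extract_features(s, NULL, lm, frame_interval = 0.5, seed = 1)
  expect_equal(fx$G_elongation_rate, 1.2, tolerance = 1e-10)
})

test_that("feature I takes the second-largest post-telophase length", {
  t <- (0:45) * 0.5
  len <- rep(7, length(t))
  # three frames at least 7 min after anaphase onset (t_ao = 10)
  len[t >= 17] <- 7
  len[t == 17] <- 14; len[t == 17.5] <- 15; len[t == 18] <- 13
  len[t > 18] <- 5
  s <- data.frame(t = t, length = len)
  lm <- fixed_landmarks(5, 7, 10)
  fx <- extract_features(s, NULL, lm, frame_interval = 0.5, seed = 1)
  expect_equal(fx$I_pole_sep_telophase, 14 / fx$C_mean_length * 100)
})

test_that("an axis flip between frames contributes zero rotation", {
  t <- (0:39) * 0.5
  s <- data.frame(t = t, length = rep(7, 40))
  axes <- data.frame(t = t, ux = rep(c(1, -1), 20), uy = 0, uz = 0)
  lm <- fixed_landmarks(5, 7, 11.5)
  fx <- extract_features(s, axes, lm, frame_interval = 0.5, seed = 1)
  expect_equal(fx$F_rotation, 0)
})

test_that("missing windows flag the feature but keep the others", {
  # series starting at NEBD: no pre-NEBD frames for A; ends at anaphase + 1
  t <- seq(5, 12.5, by = 0.5)
  s <- data.frame(t = t, length = c(6, 5, rep(4, 12), 5, 6))
  lm <- fixed_landmarks(5, 6, 11.5)
  fx <- extract_features(s, NULL, lm, frame_interval = 0.5, seed = 1)
  expect_true(is.na(fx$A_pole_sep_pre_nebd))
  expect_true(is.na(fx$I_pole_sep_telophase))
  expect_match(fx$flags, "A_absent")
  expect_match(fx$flags, "I_absent")
  expect_false(is.na(fx$C_mean_length))
})

test_that("features match brute-force recomputation on simulated cells", {
  set.seed(55)
  for (i in 1:100) {
    dur <- runif(1, 3, 12)
    p <- spindle_sim_params(t_nebd = 5, t_s = 7, t_ao = 7 + dur,
                            n_frames = ceiling((7 + dur + 9) / 0.5),
                            seed = sample.int(1e6, 1))
    sim <- simulate_spindle_track(p)
    s <- spindle_length_series(sim$track)
    axes <- spindle_axes(sim$track)
    lmk <- fixed_landmarks(p$t_nebd, p$t_s, p$t_ao)
    seed_i <- sample.int(1e6, 1)
    fx <- extract_features(s, axes, lmk, frame_interval = 0.5, seed = seed_i)

    mit <- which(s$t >= p$t_s & s$t <= p$t_ao)
    C <- mean(s$length[mit])
    expect_equal(fx$C_mean_length, C, tolerance = 1e-12)

    # A: top 3 in (t_nebd - 3, t_nebd]
    pre <- which(s$t > p$t_nebd - 3 & s$t <= p$t_nebd)
    expect_equal(fx$A_pole_sep_pre_nebd,
                 mean(sort(s$length[pre], decreasing = TRUE)[1:3]),
                 tolerance = 1e-12)

    # D over the identical seeded subsample
    norm <- s$length[mit] / C
    if (length(norm) >= 8) {
      set.seed(seed_i)
      idx <- sample.int(length(norm), 7)
      expect_equal(fx$D_length_variance, sd(norm[idx]), tolerance = 1e-12)
    }

    # E: mean |dL| as % of C per minute
    expect_equal(fx$E_length_fluctuation,
                 mean(abs(diff(s$length[mit]))) / C * 100 / 0.5,
                 tolerance = 1e-12)

    # F: brute-force per-pair angle accumulation
    aidx <- which(axes$t >= p$t_s & axes$t <= p$t_ao)
    u <- as.matrix(axes[aidx, c("ux", "uy", "uz")])
    angs <- vapply(seq_len(nrow(u) - 1),
                   function(k) oracle_angle(u[k, ], u[k + 1, ]), numeric(1))
    expect_equal(fx$F_rotation, mean(angs) / 0.5, tolerance = 1e-8)

    # G: least-squares slope on the anaphase window
    ana <- which(s$t >= p$t_ao & s$t <= p$t_ao + 2.5)
    expect_equal(fx$G_elongation_rate,
                 unname(coef(stats::lm(s$length[ana] ~ s$t[ana]))[2]),
                 tolerance = 1e-10)

    # I: second largest at >= t_ao + 7 min
    telo <- which(s$t >= p$t_ao + 7)
    expect_equal(fx$I_pole_sep_telophase,
                 sort(s$length[telo], decreasing = TRUE)[2] * 100 / C,
                 tolerance = 1e-12)
  }
})

test_that("noise-free simulations recover the generating rates exactly", {
  p <- spindle_sim_params(plateau_noise_sd = 0, rotation_rate_sd = 0,
                          centroid_drift_sd = 0, elongation_rate = 1.3,
                          telophase_peak = 9, seed = 4)
  sim <- simulate_spindle_track(p)
  s <- spindle_length_series(sim$track)
  lm <- score_landmarks_from_length(s)
  fx <- extract_features(s, spindle_axes(sim$track), lm,
                         frame_interval = 0.5, seed = 1)
  expect_equal(fx$G_elongation_rate, 1.3, tolerance = 1e-8)
  expect_equal(fx$B_duration, p$t_ao - p$t_s)
  expect_equal(fx$A_pole_sep_pre_nebd, p$pre_nebd_separation,
               tolerance = 1e-10)
})

test_that("unit rescaling scales A, C, G and leaves D, E, I unchanged", {
  sim <- simulate_spindle_track(spindle_sim_params(seed = 21))
  s <- spindle_length_series(sim$track)
  axes <- spindle_axes(sim$track)
  lm <- fixed_landmarks(5, 7, 11.5)
  f1 <- extract_features(s, axes, lm, frame_interval = 0.5, seed = 2)
  s2 <- transform(s, length = length * 1000)
  f2 <- extract_features(s2, axes, lm, frame_interval = 0.5, seed = 2)
  expect_equal(f2$A_pole_sep_pre_nebd, 1000 * f1$A_pole_sep_pre_nebd)
  expect_equal(f2$C_mean_length, 1000 * f1$C_mean_length)
  expect_equal(f2$G_elongation_rate, 1000 * f1$G_elongation_rate)
  expect_equal(f2$D_length_variance, f1$D_length_variance, tolerance = 1e-9)
  expect_equal(f2$E_length_fluctuation, f1$E_length_fluctuation,
               tolerance = 1e-9)
  expect_equal(f2$I_pole_sep_telophase, f1$I_pole_sep_telophase,
               tolerance = 1e-9)
})

test_that("F and H are invariant under global rotation of coordinates", {
  sim <- simulate_spindle_track(spindle_sim_params(seed = 31))
  s <- spindle_length_series(sim$track)
  axes <- spindle_axes(sim$track)
  lm <- fixed_landmarks(5, 7, 11.5)
  f1 <- extract_features(s, axes, lm, frame_interval = 0.5, seed = 2)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  u <- as.matrix(axes[, c("ux", "uy", "uz")]) %*% t(R)
  axes2 <- data.frame(t = axes$t, ux = u[, 1], uy = u[, 2], uz = u[, 3])
  f2 <- extract_features(s, axes2, lm, frame_interval = 0.5, seed = 2)
  expect_equal(f2$F_rotation, f1$F_rotation, tolerance = 1e-8)
  expect_equal(f2$H_rotation_anaphase, f1$H_rotation_anaphase,
               tolerance = 1e-8)
})
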