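const_cal <- function(value, rows = 8, cols = 8, bands = 3,
                      wavelengths = c(505, 660, 830)) {
  d <- c(rows, cols, bands)
  structure(list(data = array(value, d), validity_mask = array(TRUE, d),
                 band_wavelengths = wavelengths, meta = list(bit_depth = 10L)),
            class = "calibrated_cube")
}

test_that("signature extraction averages ROI pixels per band", {
  cal <- const_cal(0.5)
  roi <- matrix(TRUE, 8, 8)
  sig <- extract_signature(cal, roi)
  expect_equal(sig$mean, rep(0.5, 3))
  expect_equal(sig$sd, rep(0, 3))
  expect_equal(sig$n, rep(64L, 3))
  # single-pixel ROI: mean is that pixel, sd 0
  cal$data[3, 4, ] <- c(0.1, 0.2, 0.3)
  one <- matrix(FALSE, 8, 8); one[3, 4] <- TRUE
  sig1 <- extract_signature(cal, one)
  expect_equal(sig1$mean, c(0.1, 0.2, 0.3))
  expect_equal(sig1$sd, rep(0, 3))
  expect_error(extract_signature(cal, matrix(FALSE, 8, 8)), "empty")
  # invalid pixel-bands do not contribute
  cal$validity_mask[3, 4, 1] <- FALSE
  cal$data[3, 4, 1] <- NA
  sigv <- extract_signature(cal, one)
  expect_identical(sigv$n[1], 0L)
  expect_true(is.na(sigv$mean[1]))
})

test_that("noiseless pipeline signatures match the phantom ground truth", {
  sess <- make_session(rows = 32, cols = 32, seed = 2)
  cal <- flat_field_calibrate(sess$cube, sess$dark, sess$white)
  gt <- phantom_band_truth(sess$phantom, sess$array, sess$camera)
  denom <- sweep(sess$white$data, 1:2, sess$dark$data, `-`)
  for (lab in 1:2) {
    roi <- sess$phantom$label_map == lab & !sess$phantom$glare_mask
    sig <- extract_signature(cal, roi)
    # per-band tolerance: one quantization step at the weakest ROI pixel
    for (k in 1:18) {
      step <- 1 / min(denom[, , k][roi])
      expect_lt(abs(sig$mean[k] - gt[lab, k] / 0.99), step)
    }
  }
})

test_that("min-max normalization is exact, affine-invariant and idempotent", {
  sig <- spectral_signature(c(505, 660, 830), c(2, 4, 6))
  ns <- normalize_signature(sig)
  expect_equal(ns$normalized, c(0, 0.5, 1))
  expect_error(normalize_signature(spectral_signature(c(505, 660), c(1, 1))),
               "degenerate")
  expect_error(normalize_signature(spectral_signature(505, 1)), "2 bands")
  for (s in 1:5) {
    vals <- withr::with_seed(s, runif(18))
    a <- withr::with_seed(s + 10, runif(1, 0.1, 5))
    b <- withr::with_seed(s + 20, runif(1, -2, 2))
    n1 <- normalize_signature(spectral_signature(1:18, vals))$normalized
    n2 <- normalize_signature(spectral_signature(1:18, a * vals + b))$normalized
    expect_equal(n1, n2)
    expect_equal(min(n1), 0); expect_equal(max(n1), 1)
    # idempotence: normalizing the normalized curve changes nothing
    n3 <- normalize_signature(spectral_signature(1:18, n1))$normalized
    expect_equal(n3, n1)
  }
})

test_that("snr_db matches its closed forms and is scale invariant", {
  v <- c(9, 10, 11, 10)  # mean 10
  expect_equal(snr_db(rep(c(5, 15), 50)),
               20 * log10(mean(rep(c(5, 15), 50)) / sd(rep(c(5, 15), 50))))
  x <- withr::with_seed(1, rnorm(500, 100, 10))
  expect_equal(snr_db(x), 20 * log10(mean(x) / sd(x)))
  expect_equal(snr_db(10 * x), snr_db(x))
  expect_equal(snr_db(0.01 * x), snr_db(x))
  # mu = sigma -> 0 dB; mu/sigma = 10 -> 20 dB
  y <- withr::with_seed(2, rnorm(2e4, 50, 5))
  expect_equal(snr_db(y), 20, tolerance = 0.2)
  expect_error(snr_db(rep(1, 10)), "infinite")
  expect_error(snr_db(c(-5, -4, -6)), "mean")
})

test_that("group comparison matches a textbook pooled-t computation", {
  a_vals <- c(0.10, 0.20, 0.15)
  b_vals <- c(0.30, 0.25, 0.35)
  ga <- lapply(a_vals, function(v) spectral_signature(c(505, 660), c(v, v + 0.3)))
  gb <- lapply(b_vals, function(v) spectral_signature(c(505, 660), c(v, v + 0.1)))
  cmp <- compare_groups(ga, gb, direction = "greater", normalize = FALSE)
  # hand computation: pooled two-sample t with n1 = n2 = 3, df = 4
  sp2 <- (2 * var(a_vals) + 2 * var(b_vals)) / 4
  t_hand <- (mean(a_vals) - mean(b_vals)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(cmp$t[1], t_hand)
  expect_equal(cmp$p[1], pt(t_hand, df = 4, lower.tail = FALSE))
  expect_false(cmp$significant[1])  # a < b, wrong tail
  cmp_less <- compare_groups(ga, gb, direction = "less", normalize = FALSE)
  expect_equal(cmp_less$p[1], pt(t_hand, df = 4))
  expect_true(cmp_less$significant[1])
})

test_that("identical groups give t = 0 and one-tailed p = 0.5 everywhere", {
  wl <- band_wavelengths(led_array_default())
  g <- random_signatures(4, wl, base = seq(0.2, 0.8, length.out = 18),
                         sd = 0.05, seed = 3)
  cmp <- compare_groups(g, g, direction = "greater", normalize = FALSE)
  expect_equal(cmp$t, rep(0, 18))
  expect_equal(cmp$p, rep(0.5, 18))
  expect_false(any(cmp$significant))
})

test_that("planted band effects are recovered at exactly the planted bands", {
  wl <- band_wavelengths(led_array_default())
  base <- rep(0.4, 18)
  shift <- rep(0, 18); shift[wl %in% c(505, 660)] <- 0.3  # 6 sigma at 0.05
  ga <- random_signatures(10, wl, base + shift, sd = 0.05, seed = 21)
  gb <- random_signatures(10, wl, base, sd = 0.05, seed = 22)
  # exact set recovery needs family-wise control across the 18 bands; the
  # planted 6-sigma effects survive Bonferroni easily
  cmp <- compare_groups(ga, gb, direction = "greater", normalize = FALSE,
                        correction = "bonferroni")
  expect_identical(which(cmp$significant), which(wl %in% c(505, 660)))
  # without correction the planted bands are still always flagged
  cmp0 <- compare_groups(ga, gb, direction = "greater", normalize = FALSE)
  expect_true(all(cmp0$significant[wl %in% c(505, 660)]))
})

test_that("power grows with effect size and with group size", {
  wl <- c(505, 660, 830)
  power_at <- function(delta, n, nrep = 60) {
    hits <- vapply(seq_len(nrep), function(r) {
      ga <- random_signatures(n, wl, c(0.4 + delta, 0.4, 0.4), sd = 0.05,
                              seed = 1000 + r)
      gb <- random_signatures(n, wl, c(0.4, 0.4, 0.4), sd = 0.05,
                              seed = 5000 + r)
      compare_groups(ga, gb, direction = "greater",
                     normalize = FALSE)$significant[1]
    }, logical(1))
    mean(hits)
  }
  p_small <- power_at(0.02, 5)
  p_mid <- power_at(0.05, 5)
  p_big <- power_at(0.10, 5)
  expect_lte(p_small, p_mid + 0.1)
  expect_lt(p_small, p_big)
  expect_lte(power_at(0.05, 3), power_at(0.05, 12) + 0.1)
})

test_that("comparison options guard their preconditions", {
  wl <- c(505, 660)
  g2 <- random_signatures(2, wl, c(0.3, 0.5), seed = 1)
  expect_error(compare_groups(g2[1], g2, direction = "greater"), ">= 2")
  expect_warning(compare_groups(g2, g2, direction = "auto",
                                normalize = FALSE),
                 "inflated|anti-conservative")
  g3 <- random_signatures(3, c(505, 660, 830), c(0.2, 0.5, 0.9), seed = 2)
  g4 <- random_signatures(3, c(505, 660, 830), c(0.2, 0.5, 0.9), seed = 3)
  bonf <- compare_groups(g3, g4, direction = "greater",
                         correction = "bonferroni", normalize = FALSE)
  expect_true(all(bonf$p_adj >= bonf$p))
})
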