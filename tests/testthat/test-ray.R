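synthetic_scan <- function(scales, norm) {
  structure(list(scales = scales, mean_Ca = norm, norm_Ca = norm,
                 Ca_target = 1, t_total = 15000, burnin = 5000),
            class = "ray_scan")
}

test_that("crossing detection applies the slope-sign stability rule", {
  s <- seq(0.1, 3, length.out = 30)
  # strictly monotone increasing through the target: one stable point
  fp <- find_fixed_points(synthetic_scan(s, 0.2 + 0.6 * s))
  expect_equal(nrow(fp), 1)
  expect_true(fp$stable)
  # N-shaped curve crossing three times: stable, unstable, stable
  y <- 1 + 0.3 * (s - 0.5) * (s - 1.5) * (s - 2.5)
  fp3 <- find_fixed_points(synthetic_scan(s, y))
  expect_equal(nrow(fp3), 3)
  expect_identical(fp3$stable, c(TRUE, FALSE, TRUE))
  # sub-noise-floor wiggles around the target are not crossings
  yw <- 0.2 + 0.6 * s
  yw[10] <- 1.01; yw[11] <- 0.99 # jitter inside the 3% floor
  expect_equal(nrow(find_fixed_points(synthetic_scan(s, yw))), 1)
})

test_that("the reference ray scan is self-consistent at scale one", {
  tg <- ref_targets_fx()
  scan <- fixture("ref_scan",
                  scan_ray(ref_model_fx(), Ca_target = tg$Ca_target))
  expect_true(1 %in% scan$scales)
  expect_equal(scan$norm_Ca[scan$scales == 1], 1, tolerance = 0.02)
  # vanishing conductances leave only resting calcium
  expect_lt(scan$norm_Ca[1], 0.05)
  fp <- find_fixed_points(scan, ref_model_fx())
  expect_equal(sum(fp$stable), 1)
  expect_lt(abs(fp$scale[fp$stable] - 1), 0.05)
})

test_that("coarse-grid crossings match a dense brute-force scan", {
  tg <- ref_targets_fx()
  db <- acc_db_fx()
  set.seed(5)
  for (k in sample(seq_along(db$models), 3)) {
    rec <- db$models[[k]]
    model <- with_gbar(db$template, rec$gbar)
    coarse <- scan_ray(model, Ca_target = rec$mean_Ca)
    dense <- scan_ray(model, Ca_target = rec$mean_Ca,
                      scales = ray_scales(80))
    fp_c <- find_fixed_points(coarse)
    fp_d <- find_fixed_points(dense)
    expect_equal(sum(fp_c$stable), sum(fp_d$stable))
  }
})
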