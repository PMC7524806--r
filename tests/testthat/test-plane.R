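test_that("plane coordinates map back to the reference model exactly", {
  m <- ref_model_fx()
  pl <- plane_def(m)
  expect_equal(plane_gbar(pl, pl$x_ref, pl$y_ref), m$gbar)
  # points on the diagonal scale all densities uniformly
  g2 <- plane_gbar(pl, 2 * pl$x_ref, 2 * pl$y_ref)
  expect_equal(unname(g2), unname(2 * m$gbar))
  # the three standard projections are valid partitions
  for (pl2 in standard_planes(m)) {
    expect_setequal(c(pl2$group_x, pl2$group_y), channel_names())
  }
})

test_that("the adaptive sampler recovers an analytic level set", {
  pl <- plane_def(ref_model_fx())
  f <- function(x, y) x / pl$x_ref + y / pl$y_ref
  map <- adaptive_level_set(f, pl, target = 1, budget = 120, seed = 3)
  seg <- map$level_set
  expect_gt(nrow(seg), 10)
  pts <- rbind(cbind(seg$x1, seg$y1), cbind(seg$x2, seg$y2))
  err <- abs(pts[, 1] / pl$x_ref + pts[, 2] / pl$y_ref - 1)
  expect_lt(max(err), 1e-9) # linear field: interpolation is exact
  expect_identical(diagonal_crossings(map), 1L)
})

test_that("refinement concentrates samples near the level set", {
  pl <- plane_def(ref_model_fx())
  f <- function(x, y) x / pl$x_ref + y / pl$y_ref
  n_init <- 25
  map <- adaptive_level_set(f, pl, target = 1, budget = 125, seed = 3,
                            n_init = n_init)
  post <- map$points[-seq_len(n_init), ]
  # distance from the line x + y = 1 in normalised coordinates
  d <- abs(post$x / pl$x_ref + post$y / pl$y_ref - 1) / sqrt(2)
  expect_gte(mean(d < 0.05 * 2.49 * sqrt(2)), 0.6)
})

test_that("a missing target level yields an empty set with a warning", {
  pl <- plane_def(ref_model_fx())
  f <- function(x, y) 0
  expect_warning(
    map <- adaptive_level_set(f, pl, target = 1, budget = 30, seed = 1),
    "no level-set"
  )
  expect_identical(nrow(map$level_set), 0L)
  expect_identical(diagonal_crossings(map), 0L)
})

test_that("boundary-targeted basin sampling agrees with a brute-force grid", {
  pl <- plane_def(ref_model_fx())
  truth <- function(x, y) {
    if (x / pl$x_ref + y / pl$y_ref > 1) "high" else "low"
  }
  map <- basin_map(truth, pl, budget = 90, n_init = 25, seed = 2)
  xs <- seq(pl$xlim[1], pl$xlim[2], length.out = 21)
  ys <- seq(pl$ylim[1], pl$ylim[2], length.out = 21)
  agree <- outer(xs, ys, Vectorize(function(x, y) {
    basin_label_at(map, x, y) == truth(x, y)
  }))
  expect_gte(mean(agree), 0.95)
})

test_that("robustness segmentation pairs acute and compensated outcomes", {
  acute <- c("canonical", "other_bursting", "silent", "canonical")
  basin <- c("canonical", "canonical", "silent", "tonic_or_one_spike")
  expect_identical(
    segment_robustness(acute, basin),
    c("robust_restorative", "sensitive_restorative",
      "sensitive_pathological", "robust_pathological")
  )
})
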