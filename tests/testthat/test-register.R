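test_that("registering an image onto itself yields the identity", {
  s <- generate_slice(clean_params(n_slices = 2, seed = 3), 1)
  m <- s$masks$foreground * 1
  t <- suppressWarnings(estimate_rigid(m, m))
  expect_lt(abs(t$angle) * 180 / pi, 0.05)
  expect_lt(sqrt(t$tx^2 + t$ty^2), 0.1)
})

test_that("a known rigid perturbation is recovered within tolerance", {
  s <- generate_slice(clean_params(n_slices = 2, seed = 3), 1)
  m <- s$masks$foreground * 1
  ctr <- image_center(m)
  t_true <- rigid2d(5 * pi / 180, 8, -3, ctr)
  mov <- resample_slice(m, t_true, fill = 0)
  t_est <- suppressWarnings(estimate_rigid(m, mov))
  err <- histostack:::rigid2d_error(t_est, rigid2d_invert(t_true))
  expect_lt(err[["angle_deg"]], 0.5)
  expect_lt(err[["trans_px"]], 0.5)

  # exhaustive grid search at 0.25 deg / 0.25 px as the independent oracle
  small_f <- histostack:::downsample2(m)
  small_m <- histostack:::downsample2(mov)
  ctr_s <- image_center(small_f)
  grid <- expand.grid(a = (-5 + seq(-1.5, 1.5, by = 0.25)) * pi / 180,
                      tx = seq(-5, -3, by = 0.25),
                      ty = seq(0.5, 2.5, by = 0.25))
  mse <- vapply(seq_len(nrow(grid)), function(i) {
    w <- resample_slice(small_m,
                        rigid2d(grid$a[i], grid$tx[i], grid$ty[i], ctr_s),
                        fill = 0)
    mean((w - small_f)^2)
  }, 0)
  best <- grid[which.min(mse), ]
  expect_lt(abs(best$a - t_est$angle) * 180 / pi, 0.5)
  expect_lt(abs(best$tx * 2 - t_est$tx), 0.75)
  expect_lt(abs(best$ty * 2 - t_est$ty), 0.75)
})

test_that("a 180-degree flip of a lesioned annulus is recovered", {
  s <- generate_slice(clean_params(n_slices = 2, seed = 8), 1)
  m <- s$masks$retina * 1  # annulus with the lesion notch
  ctr <- image_center(m)
  mov <- resample_slice(m, rigid2d(pi, 0, 0, ctr), fill = 0)
  t_est <- suppressWarnings(estimate_rigid(m, mov))
  expect_lt(abs(abs(t_est$angle) * 180 / pi - 180), 0.5)
})

test_that("degenerate moving images are rejected", {
  f <- rand_img(32, 32)
  expect_error(suppressWarnings(estimate_rigid(f, matrix(0.5, 32, 32))),
               "degenerate")
})

test_that("chaining pairwise transforms to a reference behaves algebraically", {
  ctr <- c(16.5, 16.5)
  ident <- lapply(1:4, function(i) rigid2d(0, 0, 0, ctr))
  for (t in chain_to_reference(ident, 1))
    expect_true(rigid2d_is_identity(t))
  # pure unit translations, reference 0 -> slice 5 accumulates (4, 0)
  shifts <- lapply(1:4, function(i) rigid2d(0, 1, 0, ctr))
  abs_t <- chain_to_reference(shifts, reference_index = 1)
  expect_equal(abs_t[[5]]$tx, 4)
  expect_equal(abs_t[[5]]$ty, 0)
  # random chain: absolute transforms are consistent with pairwise ones
  set.seed(11)
  pw <- lapply(1:6, function(i)
    rigid2d(runif(1, -0.3, 0.3), runif(1, -3, 3), runif(1, -3, 3), ctr))
  abs_t <- chain_to_reference(pw, reference_index = 4)
  expect_true(rigid2d_is_identity(abs_t[[4]], tol = 1e-12))
  for (i in 1:6) {
    # abs[i] should equal abs[i+1] composed with the pairwise map i+1 -> i
    lhs <- abs_t[[i]]
    rhs <- rigid2d_compose(abs_t[[i + 1]], rigid2d_invert(pw[[i]]))
    d <- histostack:::rigid2d_error(lhs, rhs)
    expect_lt(d[["angle_deg"]], 1e-9)
    expect_lt(d[["trans_px"]], 1e-9)
  }
})

test_that("resampling: identity is exact, integer shifts are exact, rotations round-trip", {
  s <- generate_slice(clean_params(n_slices = 2, seed = 3), 1)
  ctr <- image_center(s$rgb)
  expect_identical(resample_slice(s$rgb, rigid2d(0, 0, 0, ctr)), s$rgb)
  sh <- resample_slice(s$rgb, rigid2d(0, 5, 0, ctr), fill = 0)
  expect_equal(sh[, 6:192, ], s$rgb[, 1:187, ])
  expect_true(all(sh[, 1:5, ] == 0))
  th <- 17 * pi / 180
  rt <- resample_slice(resample_slice(s$rgb, rigid2d(th, 0, 0, ctr)),
                       rigid2d(-th, 0, 0, ctr))
  fg <- s$masks$foreground
  expect_lt(mean(abs(to_gray(rt)[fg] - to_gray(s$rgb)[fg])), 2 / 255)
})

test_that("run_strategy: jitter-free stacks give identity transforms", {
  gs <- generate_stack(clean_params(n_slices = 5, seed = 2))
  masks <- lapply(gs$stack$slices, segment_slice)
  for (strat in c("unregistered", "r_binary")) {
    run <- suppressWarnings(run_strategy(gs$stack, masks, strat))
    for (t in run$transforms) {
      expect_lt(abs(t$angle) * 180 / pi, 0.1)
      expect_lt(sqrt(t$tx^2 + t$ty^2), 0.25)
    }
  }
})

test_that("run_strategy recovers ground-truth transforms on a jittered clean stack", {
  p <- phantom_params(n_slices = 8, crack_probability = 0, debris_density = 0,
                      seed = 31)
  gs <- generate_stack(p)
  masks <- lapply(gs$stack$slices, segment_slice)
  run <- suppressWarnings(run_strategy(gs$stack, masks, "r_binary"))
  te <- transform_errors(run, gs$truth)
  expect_true(all(te$angle_err_deg < 1))
  expect_true(all(te$trans_err_px < 1))
})

test_that("mask-dependent strategies demand masks", {
  gs <- generate_stack(clean_params(n_slices = 3, seed = 2))
  expect_error(run_strategy(gs$stack, NULL, "r_binary"), "mask")
  expect_error(run_strategy(gs$stack, NULL, "r_segmented"), "mask")
})
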