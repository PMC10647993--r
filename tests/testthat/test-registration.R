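test_that("identical volumes register to a numerically zero field", {
  ph <- fixture_clean_phantom()
  st <- ph$study
  reg <- register_exp_to_insp(st, fixed = st$insp, moving = st$insp)
  expect_equal(max(field_magnitude(reg$field)), 0)
  expect_equal(reg$exp_registered, st$insp, ignore_attr = TRUE)
  expect_equal(reg$mse_after, reg$mse_before)
})

test_that("a known smooth warp is recovered to sub-voxel mean residual", {
  ph <- fixture_warped_phantom()
  st <- ph$study
  # self-consistency: the warped expiration against its own pre-warp volume
  reg <- register_exp_to_insp(st, fixed = ph$truth$exp_prewarp, moving = st$exp)
  expect_true(reg$converged)
  res <- field_residual(reg$field, ph$truth$alignment_field, st$lung_mask)
  expect_lt(res, 0.5)
  expect_lte(reg$mse_after, reg$mse_before)
})

test_that("registration without correspondence signal returns identity", {
  # inspiration and expiration textures are drawn independently, so an
  # unwarped pair carries no voxel-wise matching signal: the gate must fire
  ph <- generate_phantom_pair(phantom_config(dim = c(40, 40, 40), seed = 12,
                                             noise_sd = 10,
                                             class_fractions = c(0.25, 0.25, 0.25, 0.25)))
  expect_warning(reg <- register_exp_to_insp(ph$study), "correspondence")
  expect_equal(max(field_magnitude(reg$field)), 0)
  # masked MSE unchanged relative to identity (within 5% trivially)
  expect_equal(reg$mse_after, reg$mse_before)
})

test_that("resampling with a zero or integer-shift field is exact", {
  ph <- fixture_clean_phantom()
  st <- ph$study
  d <- dim(st$insp)
  zero <- displacement_field(array(0, d), array(0, d), array(0, d))
  out <- apply_displacement_field(st, zero)
  expect_equal(out$exp_registered, st$exp, ignore_attr = TRUE)
  expect_identical(attr(out, "n_invalid"), 0L)
  # +1 voxel along axis 3: interior slices shift exactly
  shift <- displacement_field(array(0, d), array(0, d), array(1, d))
  out2 <- apply_displacement_field(st, shift)
  expect_equal(out2$exp_registered[, , 1:(d[3] - 1)], st$exp[, , 2:d[3]],
               ignore_attr = TRUE)
  # samples beyond the last slice are invalid and leave the lung mask
  expect_true(all(!out2$lung_mask[, , d[3]]))
})

test_that("the stored alignment field undoes the warp on smooth content", {
  # warp-then-align recovery is assessed on a smooth volume: on the
  # phantom's voxel-scale stochastic texture, trilinear interpolation error
  # dominates any HU-level comparison regardless of geometric accuracy
  ph <- fixture_warped_phantom()
  st <- ph$study
  u <- ph$truth$alignment_field
  w <- invert_displacement_field(u)
  set.seed(1)
  smooth_vol <- smooth_volume(array(rnorm(prod(dim(st$insp)), sd = 100),
                                    dim(st$insp)), 4)
  warped <- warp_volume(smooth_vol, w)
  recovered <- warp_volume(warped, u)
  m <- st$lung_mask
  warp_err <- mean(abs(warped - smooth_vol)[m])
  recov_err <- mean(abs(recovered - smooth_vol)[m])
  expect_lt(recov_err, 0.5 * warp_err)
})

test_that("trilinear resampling preserves the HU range", {
  ph <- fixture_warped_phantom()
  st <- ph$study
  rng <- range(st$exp)
  out <- apply_displacement_field(st, ph$truth$alignment_field)
  expect_gte(min(out$exp_registered), rng[1] - 1)
  expect_lte(max(out$exp_registered), rng[2] + 1)
})

test_that("field inversion composes to near-identity", {
  ph <- fixture_warped_phantom()
  u <- ph$truth$alignment_field
  w <- invert_displacement_field(u)
  d <- dim(u$d1)
  g <- list(i = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
            j = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
            k = array(rep(seq_len(d[3]), each = d[1] * d[2]), d))
  # x + w(x) + u(x + w(x)) should return to x
  xs <- g$i + w$d1; ys <- g$j + w$d2; zs <- g$k + w$d3
  r1 <- w$d1 + interp_trilinear(u$d1, xs, ys, zs)
  r2 <- w$d2 + interp_trilinear(u$d2, xs, ys, zs)
  r3 <- w$d3 + interp_trilinear(u$d3, xs, ys, zs)
  err <- sqrt(r1^2 + r2^2 + r3^2)
  expect_lt(mean(err[ph$study$lung_mask]), 0.05)
})

test_that("mismatched grids and spacings are input errors", {
  ph <- fixture_clean_phantom()
  st <- ph$study
  other <- array(0, c(32, 32, 32))
  expect_error(register_exp_to_insp(st, moving = other), "grid")
  expect_error(register_exp_to_insp(st, fixed = with_spacing(st$insp, c(2, 2, 2))),
               "spacing")
  bad <- displacement_field(array(0, c(32, 32, 32)), array(0, c(32, 32, 32)),
                            array(0, c(32, 32, 32)))
  expect_error(apply_displacement_field(st, bad), "grid")
})

test_that("displacement fields survive a NIfTI round trip", {
  ph <- fixture_warped_phantom()
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_displacement_field(ph$truth$alignment_field, path, ph$study$spacing)
  back <- read_displacement_field(path)
  expect_equal(back$d1, ph$truth$alignment_field$d1, tolerance = 1e-6)
  expect_equal(back$d3, ph$truth$alignment_field$d3, tolerance = 1e-6)
})
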