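# Key-slice selection, normalization, cropping/resizing, phase adaptation
# and augmentation.

test_that("key-slice selection maximizes in-slice tumor area with low-index ties", {
  vol <- array(seq_len(4 * 4 * 4), c(4, 4, 4))
  mk <- array(0, c(4, 4, 4))
  mk[1:2, 1:3, 2] <- 1  # area 6
  mk[1, 1:3, 3] <- 1    # area 3
  st <- select_key_slice(list(vol, vol), list(mk, mk))
  expect_identical(st$slice_index, c(2L, 2L))
  expect_identical(st$values[, , 1], vol[, , 2])

  tie <- array(0, c(4, 4, 4))
  tie[1:2, 1, 2] <- 1
  tie[1:2, 1, 3] <- 1  # same area in slices 2 and 3
  expect_identical(select_key_slice(list(vol), list(tie))$slice_index, 2L)

  expect_error(select_key_slice(list(vol), list(array(0, c(4, 4, 4)))),
               "no tumor delineated")
})

test_that("normalization statistics pool all tumor voxels across phases", {
  v <- array(0, c(2, 2, 5))
  v[1, 1, ] <- 1; v[2, 1, ] <- 3
  m <- matrix(FALSE, 2, 2); m[1:2, 1] <- TRUE
  st <- fit_norm_stats(list(v), list(m))
  expect_equal(st$mu, 2)
  expect_equal(st$sigma, 1)  # population sd of {1,3} repeated
  expect_equal(st$n_voxels, 10L)

  # constant tumor intensity is degenerate
  vc <- array(5, c(2, 2, 5))
  expect_error(fit_norm_stats(list(vc), list(m)), "degenerate")
})

test_that("training statistics are independent of other splits", {
  co <- shared_phantom()
  tr <- co$samples[1:6]
  s1 <- fit_norm_stats(lapply(tr, `[[`, "phases"),
                       lapply(tr, `[[`, "tumor_mask"))
  s2 <- fit_norm_stats(lapply(tr, `[[`, "phases"),
                       lapply(tr, `[[`, "tumor_mask"))
  expect_identical(s1$mu, s2$mu)
})

test_that("z-normalization matches the closed form and standardizes its support", {
  st <- structure(list(mu = 100, sigma = 20), class = "norm_stats")
  v <- array(140, c(3, 3, 2))
  z <- znormalize(phase_stack(v), st)
  expect_equal(z$values[1, 1, 1], 2.0)
  expect_true(z$normalized)
  v2 <- array(100, c(3, 3, 2))
  expect_equal(znormalize(phase_stack(v2), st)$values[2, 2, 1], 0)

  # voxels that defined the stats standardize to mean 0, variance 1
  co <- shared_phantom()
  tr <- co$samples[1:5]
  stats <- fit_norm_stats(lapply(tr, `[[`, "phases"),
                          lapply(tr, `[[`, "tumor_mask"))
  zvox <- unlist(lapply(tr, function(s) {
    zn <- znormalize(phase_stack(s$phases), stats)
    apply(zn$values, 3, function(p) p[s$tumor_mask])
  }))
  expect_equal(mean(zvox), 0, tolerance = 1e-10)
  expect_equal(mean(zvox^2), 1, tolerance = 1e-10)
})

test_that("crop_and_resize emits the canonical spatial shape", {
  co <- shared_phantom()
  s <- co$samples[[1]]
  out <- crop_and_resize(phase_stack(s$phases), s$roi)
  expect_identical(dim(out$values), c(224L, 224L, dim(s$phases)[3]))

  # constant image stays constant under bilinear interpolation
  cst <- phase_stack(array(3.7, c(64, 64, 2)))
  rz <- crop_and_resize(cst, roi_box(0, 64, 0, 64), target_side = 50)
  expect_equal(range(rz$values), c(3.7, 3.7))

  # ROI already at target size is an identity
  idt <- phase_stack(array(rnorm(64 * 64 * 2), c(64, 64, 2)))
  same <- crop_and_resize(idt, roi_box(0, 64, 0, 64), target_side = 64)
  expect_equal(same$values, idt$values, tolerance = 1e-12)

  expect_error(crop_and_resize(idt, roi_box(0, 100, 0, 64)), "bounds")
})

test_that("roi_box enforces the half-open convention", {
  expect_error(roi_box(5, 5, 0, 4), "stop must exceed start")
  expect_error(roi_box(-1, 5, 0, 4), "negative")
  b <- roi_box(0, 10, 2, 6)
  expect_identical(b$row_stop, 10L)
})

test_that("phase-count adaptation maps 4 acquired phases onto the 5-phase grid", {
  v5 <- phase_stack(array(rnorm(8 * 8 * 5), c(8, 8, 5)))
  expect_identical(adapt_phase_count(v5)$values, v5$values)

  v4 <- array(0, c(8, 8, 4))
  for (p in 1:4) v4[, , p] <- p
  out <- adapt_phase_count(phase_stack(v4), times = c(0, 30, 90, 300))
  expect_identical(dim(out$values), c(8L, 8L, 5L))
  # canonical 60 s phase copies the nearest acquired phase (30 s)
  expect_equal(as.numeric(out$values[, , 3]), rep(2, 64))
  expect_equal(as.numeric(out$values[, , 5]), rep(4, 64))

  # explicit projection: duplicate phase 2 into slot 3
  P <- matrix(0, 5, 4); P[1, 1] <- 1; P[2, 2] <- 1; P[3, 2] <- 1
  P[4, 3] <- 1; P[5, 4] <- 1
  out2 <- adapt_phase_count(phase_stack(v4), projection = P)
  expect_equal(out2$values[, , 3], out2$values[, , 2])

  expect_error(adapt_phase_count(phase_stack(array(0, c(4, 4, 1)))),
               "at least 2")
})

test_that("augmentation is seeded, identity-able, and temporally coherent", {
  st <- phase_stack(array(rnorm(48 * 48 * 5), c(48, 48, 5)), normalized = TRUE)
  off <- augment_policy(p_rotate = 0, p_scale = 0, p_translate = 0,
                        p_rician = 0, p_gaussian = 0)
  expect_identical(augment(st, off, seed = 3)$values, st$values)

  on <- augment_policy(p_rotate = 1, p_scale = 1, p_translate = 1,
                       p_rician = 1, p_gaussian = 1)
  a <- augment(st, on, seed = 5)
  b <- augment(st, on, seed = 5)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, st$values))

  # a full turn (two 180-degree rotations) is the identity up to
  # interpolation error
  th <- pi
  a180 <- st$values
  for (rep in 1:2) {
    for (p in 1:5) {
      a180[, , p] <- windmri:::cpp_warp_affine(a180[, , p],
        c(cos(th), -sin(th), sin(th), cos(th)), c(0, 0), 0, TRUE)
    }
  }
  # boundary pixels can fall to the fill value through float jitter
  expect_equal(a180[2:47, 2:47, ], st$values[2:47, 2:47, ], tolerance = 1e-8)

  # temporal coherence: phase-constant stacks stay phase-constant
  base <- matrix(rnorm(48 * 48), 48, 48)
  pc <- phase_stack(array(rep(base, 5), c(48, 48, 5)), normalized = TRUE)
  geom <- augment_policy(p_rotate = 1, p_scale = 1, p_translate = 1,
                         p_rician = 0, p_gaussian = 0)
  ag <- augment(pc, geom, seed = 8)
  for (p in 2:5) expect_identical(ag$values[, , p], ag$values[, , 1])
})

test_that("mosaic augmentation tiles quadrants from four sources", {
  sts <- lapply(1:4, function(i) phase_stack(array(i, c(8, 8, 2))))
  mo <- augment_mosaic(sts, seed = 2)
  vals <- c(mo$values[2, 2, 1], mo$values[2, 7, 1],
            mo$values[7, 2, 1], mo$values[7, 7, 1])
  expect_equal(sort(vals), c(1, 2, 3, 4))
})

test_that("the preprocessing pipeline emits the canonical model input", {
  co <- shared_phantom()
  tr <- co$samples[1:5]
  stats <- fit_norm_stats(lapply(tr, `[[`, "phases"),
                          lapply(tr, `[[`, "tumor_mask"))
  ps <- preprocess_sample(co$samples[[6]], stats)
  expect_identical(dim(ps$values), c(224L, 224L, 5L))
  expect_true(ps$normalized)
  # shape contract is idempotent under re-application
  ps2 <- adapt_phase_count(crop_and_resize(ps, roi_box(0, 224, 0, 224)), 5)
  expect_identical(dim(ps2$values), dim(ps$values))
})
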