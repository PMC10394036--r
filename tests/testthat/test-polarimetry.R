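test_that("forward model matches hand-evaluated intensities", {
  opt <- fibril_optics(chi_xxx = 2, chi_xyy = 1, k_scale = 1)
  expect_equal(forward_intensity(opt, 30, 30), 4)    # aligned: chi_xxx^2
  expect_equal(forward_intensity(opt, 0, 90), 1)     # crossed: chi_xyy^2
  expect_equal(forward_intensity(opt, 0, 45), 3.25)  # (0.5*2+0.5*1)^2 + 1
  # period 180 in both angles
  expect_equal(forward_intensity(opt, 10, 70),
               forward_intensity(opt, 190, 250))
})

test_that("closed-form harmonic coefficients agree with quadrature", {
  expect_equal(unname(coefficients_from_optics(fibril_optics(1, 1, 1))),
               c(1.5, 0, -0.5), tolerance = 1e-12)
  co <- coefficients_from_optics(fibril_optics(2, 1, 1))
  expect_equal(unname(co), c(2.875, 1.5, -0.375), tolerance = 1e-12)
  expect_equal(sum(co), forward_intensity(fibril_optics(2, 1, 1), 0, 0))
  set.seed(7)
  for (i in 1:100) {
    opt <- fibril_optics(runif(1, 0.2, 5), runif(1, 0.2, 5), runif(1, 0.1, 10))
    expect_lt(max(abs(coefficients_from_optics(opt) - quad_coefficients(opt))),
              1e-10)
  }
})

test_that("spatial pre-averaging behaves as a uniform box filter", {
  proto <- acquisition_protocol()
  stk <- single_fibril_stack(20, ny = 12, nx = 12)
  expect_equal(smooth_stack(stk, 1)$counts, stk$counts)   # identity window
  sm <- smooth_stack(stk, 6)
  expect_equal(sm$counts, stk$counts, tolerance = 1e-12)  # constant frames
  # single bright pixel spreads into a w x w plateau of value total/w^2
  counts <- array(0, c(1, length(proto$angles_deg), 12, 12))
  counts[1, , 6, 6] <- 36
  plateau <- smooth_stack(pshg_stack(counts, proto), 6)$counts[1, 1, , ]
  expect_equal(sort(unique(round(as.numeric(plateau), 12))), c(0, 1))
  expect_equal(sum(plateau), 36)
  expect_error(smooth_stack(single_fibril_stack(0, ny = 4, nx = 4), 6),
               "window")
})

test_that("noise-free single-fibril series is recovered exactly", {
  for (phi in c(0, 12.34, 30, 77, 151.7)) {
    m <- extract_orientation(single_fibril_stack(phi))
    expect_equal(m$phi_deg[1, 1, 1], phi, tolerance = 1e-9)
    expect_equal(m$r2[1, 1, 1], 1, tolerance = 1e-12)
    expect_true(all(m$valid))
  }
  # a0/a2/a4 content round-trips through the harmonic projection
  opt <- fibril_optics(2, 1, 1)
  m <- extract_orientation(single_fibril_stack(40, optics = opt))
  co <- coefficients_from_optics(opt)
  expect_equal(m$a0[1, 1, 1], co[["a0"]], tolerance = 1e-12)
  expect_equal(m$c2_amp[1, 1, 1], co[["a2"]], tolerance = 1e-10)
  expect_equal(m$c4_amp[1, 1, 1], abs(co[["a4"]]), tolerance = 1e-10)
})

test_that("angle-independent pixels are flagged invalid, not assigned", {
  proto <- acquisition_protocol()
  counts <- array(5, c(1, 18, 2, 2))  # constant series: undefined phase
  m <- extract_orientation(pshg_stack(counts, proto))
  expect_false(any(m$valid))
  expect_true(all(is.na(m$phi_deg)))
  counts0 <- array(0, c(1, 18, 2, 2))  # dark pixel
  expect_false(any(extract_orientation(pshg_stack(counts0, proto))$valid))
})

test_that("extraction rejects non-uniform or sparse angle grids", {
  counts <- array(1, c(1, 8, 2, 2))
  expect_error(pshg_stack(counts, acquisition_protocol(seq(0, 157.5, by = 22.5))) |>
                 extract_orientation(), "9")
  bad <- acquisition_protocol(c(seq(0, 160, by = 10), 171))
  counts <- array(1, c(1, 18, 2, 2))
  expect_error(extract_orientation(pshg_stack(counts, bad)), "uniform")
})

test_that("an equal lamellar crossing halves R2 and breaks the phase lock", {
  m <- extract_orientation(mixed_fibril_stack(0, 60))
  expect_equal(m$phi_deg[1, 1, 1], 30, tolerance = 1e-9)
  expect_equal(m$r2[1, 1, 1], 0.5, tolerance = 1e-9)
  expect_equal(phi2_phi4_discrepancy(m)[1, 1, 1], 45, tolerance = 1e-9)
  # single fibrils keep the 4th-harmonic phase locked to 4*phi + 180
  for (phi in c(5, 77, 120))
    expect_equal(phi2_phi4_discrepancy(
      extract_orientation(single_fibril_stack(phi)))[1, 1, 1],
      0, tolerance = 1e-8)
})

test_that("R2 filtering removes crossings but keeps clean pixels", {
  good <- extract_orientation(single_fibril_stack(25))
  expect_equal(filter_by_r2(good, 0.7)$valid, good$valid)
  bad <- extract_orientation(mixed_fibril_stack(0, 60))
  expect_false(any(filter_by_r2(bad, 0.7)$valid))
  expect_true(all(filter_by_r2(bad, 0.4)$valid))  # below the crossing's 0.5
})

test_that("shifting the physical polarization angles shifts phi oppositely", {
  proto <- acquisition_protocol()
  opt <- fibril_optics()
  for (delta in c(4.5, 30, 121.25)) {
    counts <- array(0, c(1, 18, 1, 1))
    for (t in 1:18)
      counts[1, t, 1, 1] <- forward_intensity(opt, 50,
                                              proto$angles_deg[t] + delta)
    m <- extract_orientation(pshg_stack(counts, proto))
    expect_equal(m$phi_deg[1, 1, 1], (50 - delta) %% 180, tolerance = 1e-9)
  }
})

test_that("mean SHG equals the arithmetic mean of the angle series", {
  set.seed(3)
  proto <- acquisition_protocol()
  counts <- array(rpois(18 * 16, 40), c(1, 18, 4, 4))
  m <- extract_orientation(pshg_stack(counts, proto))
  expect_equal(as.numeric(m$mean_shg[1, , ]),
               as.numeric(apply(counts[1, , , ], c(2, 3), mean)))
  expect_true(all(m$r2 <= 1 + 1e-12, na.rm = TRUE))
})

test_that("orientation noise scales as one over sqrt(photon count)", {
  sds <- vapply(c(10, 1000), function(a0) {
    ph <- flat_phantom(65, nx = 48, ny = 48, mean_counts = a0)
    stk <- render_epi_stack(ph, noise = TRUE, seed = 99)
    m <- extract_orientation(stk)
    pshg:::circular_sd_axial(m$phi_deg[1, , ][m$valid[1, , ]])
  }, numeric(1))
  expect_gt(sds[1] / sds[2], 7)   # two decades of a0: ratio ~ 10
  expect_lt(sds[1] / sds[2], 13)
})
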