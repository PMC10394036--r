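test_that("degenerate single-lamella phantom is constant and pure", {
  ph <- flat_phantom(30, nx = 8, ny = 8)
  expect_true(all(ph$phi_deg == 30))
  expect_true(all(ph$mix_fraction == 0))
  expect_true(all(orientation_field(ph) == 30))
  expect_true(all(amplitude_field(ph) == 1))
})

test_that("lamella count on a 60 um stroma with 1-3 um lamellae is 20-60", {
  for (seed in 1:5) {
    spec <- phantom_spec(stroma_thickness_um = 60, nx = 4, ny = 4,
                         keratocyte_density = 0, stria_count = 0, seed = seed)
    n <- length(build_phantom(spec)$lamella_phi_deg)
    expect_gte(n, 20)
    expect_lte(n, 60)
    # brute-force check of the partition itself
    ph <- build_phantom(spec)
    expect_equal(ph$boundaries_um[n], 60)
    th <- diff(c(0, ph$boundaries_um))
    expect_true(all(th[-n] >= 1 & th[-n] <= 3))
  }
})

test_that("phantom construction is deterministic given the seed", {
  spec <- phantom_spec(stroma_thickness_um = 40, nx = 16, ny = 16, seed = 11)
  expect_identical(build_phantom(spec), build_phantom(spec))
  stk1 <- render_epi_stack(build_phantom(spec), noise = TRUE, seed = 5)
  stk2 <- render_epi_stack(build_phantom(spec), noise = TRUE, seed = 5)
  expect_identical(stk1$counts, stk2$counts)
})

test_that("invalid lamella thickness range is rejected", {
  expect_error(phantom_spec(stroma_thickness_um = 2,
                            lamella_thickness_range_um = c(5, 6)),
               "exceeds")
})

test_that("partial-volume voxels mix the two straddled lamellae", {
  spec <- phantom_spec(stroma_thickness_um = 30, nx = 4, ny = 4,
                       keratocyte_density = 0, stria_count = 0, seed = 3)
  ph <- build_phantom(spec)
  expect_true(all(ph$mix_fraction >= 0 & ph$mix_fraction <= 0.5))
  mixed <- which(ph$mix_fraction > 0)
  expect_gt(length(mixed), 0)
  # rendered mixed plane equals the weighted sum of the two pure curves
  proto <- acquisition_protocol()
  opt <- fibril_optics()
  stk <- render_epi_stack(ph, opt, proto, noise = FALSE, mean_counts = NULL)
  k <- mixed[1]; f <- ph$mix_fraction[k]
  expected <- (1 - f) * forward_intensity(opt, ph$phi_deg[k], proto$angles_deg) +
    f * forward_intensity(opt, ph$phi2_deg[k], proto$angles_deg)
  expect_equal(stk$counts[k, , 1, 1], expected, tolerance = 1e-12)
})

test_that("equal 0/90 mix renders the mean of the two pure curves", {
  ph <- flat_phantom(0, nx = 2, ny = 2)
  ph$phi2_deg[] <- 90
  ph$mix_fraction[] <- 0.5
  proto <- acquisition_protocol()
  opt <- fibril_optics()  # ratio 1.4
  stk <- render_epi_stack(ph, opt, proto, noise = FALSE, mean_counts = NULL)
  expected <- 0.5 * (forward_intensity(opt, 0, proto$angles_deg) +
                       forward_intensity(opt, 90, proto$angles_deg))
  expect_equal(stk$counts[1, , 1, 1], expected, tolerance = 1e-12)
})

test_that("void voxels emit nothing at any polarization", {
  spec <- phantom_spec(stroma_thickness_um = 20, nx = 24, ny = 24,
                       keratocyte_density = 5e-4, stria_count = 1, seed = 8)
  ph <- build_phantom(spec)
  expect_gt(sum(ph$void_mask), 0)
  stk <- render_epi_stack(ph, noise = FALSE)
  for (t in c(1, 9, 18)) {
    frame <- stk$counts[, t, , ]
    expect_true(all(frame[ph$void_mask] == 0))
  }
})

test_that("noise-off render then extraction round-trips ground truth", {
  spec <- phantom_spec(stroma_thickness_um = 12, nx = 8, ny = 8,
                       keratocyte_density = 1e-4, stria_count = 0, seed = 21)
  ph <- build_phantom(spec)
  stk <- render_epi_stack(ph, noise = FALSE)
  m <- extract_orientation(stk)
  pure <- which(ph$mix_fraction == 0)
  for (k in pure) {
    ok <- !ph$void_mask[k, , ]
    expect_lt(max(abs(m$phi_deg[k, , ][ok] - ph$phi_deg[k])), 1e-6)
  }
})

test_that("the Poisson render is unbiased around the noise-off mean", {
  ph <- flat_phantom(40, nx = 2, ny = 2, mean_counts = 100)
  clean <- render_epi_stack(ph, noise = FALSE)$counts
  acc <- array(0, dim(clean))
  n_rep <- 3000
  set.seed(17)
  for (i in seq_len(n_rep))
    acc <- acc + render_epi_stack(ph, noise = TRUE)$counts
  expect_lt(max(abs(acc / n_rep - clean) / clean), 0.01)
})

test_that("lamella orientations converge to the configured mixture law", {
  law <- vm_mixture(0.3, 0.35, 20, 4, 0.35, 110, 4)
  l1_to_law <- function(n_um) {
    spec <- phantom_spec(stroma_thickness_um = n_um, orientation_law = law,
                         nx = 2, ny = 2, keratocyte_density = 0,
                         stria_count = 0, seed = 33)
    ph <- build_phantom(spec)
    h <- orientation_histogram(ph$lamella_phi_deg)
    l1_distance(h, binned_mixture(law), normalized = FALSE)
  }
  d_small <- l1_to_law(100)    # ~50 lamellae
  d_large <- l1_to_law(4000)   # ~2000 lamellae
  expect_lt(d_large, d_small)
  expect_lt(d_large, 0.35)
})

test_that("striated renderings encode the local ground-truth orientation", {
  img45 <- render_stripes(matrix(45, 48, 48), period_um = 5)
  st <- structure_tensor(img45)
  inner <- st$orientation_deg[9:40, 9:40]
  expect_lt(max(angular_difference(inner, 45)), 0.5)
  # 0-degree stripes vary only along y
  img0 <- render_stripes(matrix(0, 32, 32), period_um = 5)
  expect_equal(max(apply(img0, 1, function(r) diff(range(r)))), 0)
  # two half-planes recover their own orientation on each side
  phi <- cbind(matrix(0, 48, 24), matrix(90, 48, 24))
  st2 <- structure_tensor(render_stripes(phi, 5))
  expect_lt(max(angular_difference(st2$orientation_deg[9:40, 5:18], 0)), 1)
  expect_lt(max(angular_difference(st2$orientation_deg[9:40, 31:44], 90)), 1)
  # voids render dark
  ph <- flat_phantom(10, nx = 16, ny = 16)
  ph$void_mask[1, 3, 3] <- TRUE
  expect_equal(render_trans_image(ph, 5, 1)[3, 3], 0)
})
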