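test_that("histograms bin valid orientations into 1-degree bins", {
  d <- orientation_histogram(rep(30.4, 50))
  expect_equal(d$density[31], 1)     # bin [30, 31)
  expect_equal(sum(d$density), 1)
  d2 <- orientation_histogram(c(rep(0, 25), rep(90, 25)))
  expect_equal(d2$density[c(1, 91)], c(0.5, 0.5))
  # wrap-around: 180 and 360.5 land in bin [0, 1)
  expect_equal(orientation_histogram(c(180, 360.5))$density[1], 1)
  # empty input is flagged, not NaN
  e <- orientation_histogram(numeric(0))
  expect_true(e$empty)
  expect_false(anyNA(e$density))
})

test_that("sampled phantom histograms converge to the mixture law", {
  law <- cornea_orientation_laws()$full
  h <- orientation_histogram(sample_mixture(law, 1e5, seed = 12))
  expect_lt(l1_distance(h, binned_mixture(law), normalized = FALSE), 0.05)
})

test_that("depth ranges split into equal thirds, remainder posterior", {
  sp <- split_thirds(0, 300)
  expect_equal(sp$anterior, c(0, 100))
  expect_equal(sp$middle, c(100, 200))
  expect_equal(sp$posterior, c(200, 300))
  idx <- split_thirds(0, 10, n_slices = 10)
  expect_equal(lengths(idx), c(anterior = 3L, middle = 3L, posterior = 4L))
  expect_equal(unname(unlist(idx)), 1:10)
  expect_error(split_thirds(0, 1, n_slices = 1), "at least 3")
  expect_error(split_thirds(5, 5))
})

test_that("L1 distance has the documented normalization and extremes", {
  d <- lumpy_distribution()
  expect_equal(l1_distance(d, d), 0)
  delta1 <- orientation_distribution(c(1, rep(0, 179)))
  delta2 <- orientation_distribution(c(rep(0, 90), 1, rep(0, 89)))
  expect_equal(l1_distance(delta1, delta2, normalized = FALSE), 2)
  expect_equal(l1_distance(delta1, delta2), 1)
  unif <- orientation_distribution(rep(1, 180))
  expect_equal(l1_distance(unif, delta1, normalized = FALSE),
               2 * (1 - 1 / 180))
})

test_that("L1 distance is a metric on histograms", {
  set.seed(9)
  for (i in 1:25) {
    a <- orientation_distribution(runif(180))
    b <- orientation_distribution(runif(180))
    c_ <- orientation_distribution(runif(180))
    expect_equal(l1_distance(a, b), l1_distance(b, a))
    expect_gte(l1_distance(a, b) + l1_distance(b, c_) - l1_distance(a, c_),
               -1e-12)
  }
})

test_that("registration inverts any circular shift", {
  d <- lumpy_distribution()
  expect_equal(register_distributions(d, d), 0)
  expect_equal(register_distributions(d, roll_dist(d, 90)), 90)
  for (k in c(1, 13, 45, 135, 179))
    expect_equal(register_distributions(d, roll_dist(d, k)), k)
  # robust to mild bin-level noise
  set.seed(4)
  noisy <- orientation_distribution(
    pmax(roll_dist(d, 90)$density + rnorm(180, 0, 0.01 * max(d$density)), 0))
  expect_lte(angular_difference(register_distributions(d, noisy), 90), 1)
})

test_that("normalized distance is invariant under joint rotation", {
  a <- lumpy_distribution(1)
  b <- lumpy_distribution(2)
  base <- l1_distance(a, b)
  for (k in c(10, 90, 170))
    expect_equal(l1_distance(roll_dist(a, k), roll_dist(b, k)), base)
})

test_that("distance profiles vanish for identical stacks and register shifts", {
  spec <- phantom_spec(stroma_thickness_um = 30, nx = 16, ny = 16,
                       keratocyte_density = 0, stria_count = 0, seed = 6)
  ph <- build_phantom(spec)
  m <- extract_orientation(render_epi_stack(ph, noise = FALSE))
  prof <- distance_profile(m, m, shift_deg = 0)
  expect_true(all(prof$distance == 0))
  expect_true(all(prof$distance >= 0 & prof$distance <= 1))
  # same maps rotated by 90 degrees: after registration the profile ~ 0
  ph90 <- rotate_phantom_90(ph)
  m90 <- extract_orientation(render_epi_stack(ph90, noise = FALSE))
  h1 <- orientation_histogram(m, 1:10)
  h2 <- orientation_histogram(m90, 1:10)
  shift <- register_distributions(h1, h2)
  expect_equal(shift, 90)
  prof90 <- distance_profile(m, m90, shift_deg = shift)
  expect_lt(max(prof90$distance), 1e-9)
  expect_error(distance_profile(m, extract_orientation(
    render_epi_stack(build_phantom(phantom_spec(stroma_thickness_um = 10,
                                                nx = 16, ny = 16, seed = 1)),
    noise = FALSE)), 0), "z grid")
})

test_that("disjoint per-depth supports give unit normalized distance", {
  mk <- function(phi) {
    ph <- flat_phantom(phi, nx = 8, ny = 8, nz_um = 5)
    ph$phi_deg[] <- phi
    extract_orientation(render_epi_stack(ph, noise = FALSE))
  }
  prof <- distance_profile(mk(10), mk(120), shift_deg = 0)
  expect_true(all(prof$distance == 1))
})

test_that("perpendicular averaging restores the shared truth", {
  d <- lumpy_distribution()
  # consistent acquisitions: second is the first seen in a frame rotated 90
  avg <- average_perpendicular(d, roll_dist(d, 90))
  expect_equal(avg$density, d$density, tolerance = 1e-12)
  # two deltas that coincide after rotation collapse onto one
  delta0 <- orientation_distribution(c(1, rep(0, 179)))
  avg2 <- average_perpendicular(delta0, roll_dist(delta0, 90))
  expect_equal(avg2$density[1], 1)
  # opposite distortions +g / -g around a shared truth cancel; g is chosen
  # with zero truth-weighted mean so both inputs stay valid densities
  truth <- binned_mixture(cornea_orientation_laws()$posterior)
  g <- 0.5 * cos(4 * pi * (0:179 + 0.5) / 180)
  g <- g - sum(truth$density * g)
  d1 <- orientation_distribution(truth$density * (1 + g))
  d2 <- orientation_distribution(truth$density * (1 - g))
  avg3 <- average_perpendicular(d1, roll_dist(d2, 90))
  expect_lt(l1_distance(avg3, truth),
            min(l1_distance(d1, truth),
                l1_distance(roll_dist(roll_dist(d2, 90), -90), truth)))
})
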