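test_that("group presets carry the per-stack study statistics", {
  expect_equal(group_preset("control")$frac_nonsynaptic, 4 / 75)
  expect_equal(group_preset("control")$ribbon_multiplicity_probs,
               c(69, 2, 0) / 71)
  expect_equal(group_preset("day1")$frac_nonsynaptic, 37 / 59)
  expect_equal(group_preset("day1")$frac_contact_among_nonsynaptic,
               21 / 37)
  expect_equal(group_preset("day1")$n_fibers, 59L)
  expect_equal(sum(group_preset("week1")$ribbon_multiplicity_probs), 1)
  expect_equal(group_preset("week1")$frac_contact_among_nonsynaptic,
               15 / 31)
  expect_equal(group_preset("day1")$retraction_distance_mean_um, 2.1)
  expect_error(group_preset("day3"), "arg")
})

test_that("largest-remainder apportionment plants exact counts", {
  expect_equal(apportion <- anfmorph:::apportion(59, c(22, 37) / 59),
               c(22L, 37L))
  expect_equal(anfmorph:::apportion(22, c(15, 5, 2) / 22), c(15L, 5L, 2L))
  # property: sums preserved and counts within floor/ceiling of quotas
  set.seed(3)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    p <- runif(k); p <- p / sum(p)
    n <- sample(1:200, 1)
    a <- anfmorph:::apportion(n, p)
    expect_equal(sum(a), n)
    expect_true(all(a >= floor(n * p) & a <= ceiling(n * p)))
  }
})

test_that("the phantom is deterministic in its seed and seed-isolated", {
  cfg <- phantom_config(n_fibers = 4, n_ihc = 1,
                        dims = c(192L, 192L, 320L), ihc_radius_um = 2.6,
                        frac_nonsynaptic = 0.25,
                        frac_contact_among_nonsynaptic = 1)
  p1 <- generate_phantom(cfg, seed = 5)
  p2 <- generate_phantom(cfg, seed = 5)
  expect_identical(p1$volume$labels, p2$volume$labels)
  expect_identical(p1$annotations$efferent, p2$annotations$efferent)
  p3 <- generate_phantom(cfg, seed = 6)
  expect_false(identical(p1$volume$labels, p3$volume$labels))
  # different seeds move objects but never change planted counts
  expect_identical(p1$truth$counts, p3$truth$counts)
})

test_that("planted objects recover their analytic geometry", {
  ph <- small_phantom()
  # ribbon voxel volumes within 10% of the analytic flattened cylinder
  for (rb in ph$truth$ribbons) {
    gvol <- rb$n_voxels * voxel_volume(ph$volume$geometry)
    expect_lt(abs(gvol - rb$analytic_volume_nm3) / rb$analytic_volume_nm3,
              0.10)
  }
  # planted plaque areas recomputed from the annotated traces are exact
  eff <- ph$annotations$efferent
  crit <- efferent_criteria()
  plq <- score_contacts(eff, crit, ph$volume$geometry)
  truth_area <- unlist(lapply(ph$truth$efferent,
                              function(x) x$plaque_areas_um2))
  expect_equal(sort(plq$surface_area_um2), sort(truth_area),
               tolerance = 1e-4)
})

test_that("impossible geometry is reported, not silently clipped", {
  suppressWarnings(expect_error(
    generate_phantom(
      phantom_config(n_fibers = 60, n_ihc = 1, dims = c(96L, 96L, 320L),
                     ihc_radius_um = 1.2), seed = 1),
    "overflow|attachment"))
})

test_that("phantom config invariants reject invalid parameters", {
  expect_error(phantom_config(frac_nonsynaptic = 1.2), "\\[0, 1\\]")
  expect_error(phantom_config(ribbon_multiplicity_probs = c(0.5, 0.5, 0.5)),
               "summing")
  expect_error(phantom_config(n_fibers = 0), "n_fibers")
  expect_error(phantom_config(fiber_radius_nm = -5), "positive")
})
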