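# construct a contact table: one row per slice with a straight 500-nm
# trace and `nv` vesicles within reach (or too few / too far)
make_contact <- function(slices, nv = 6, far = FALSE, apposition = TRUE,
                         thickening = TRUE, contact_id = 1,
                         geometry = voxel_geometry(dx = 40, dy = 40,
                                                   dz = 20)) {
  dx <- geometry$dx
  rows <- lapply(seq_along(slices), function(i) {
    off_nm <- if (far) 100 else 40              # vs 2 x 35 nm = 70 limit
    nvi <- if (is.list(nv)) nv[[i]] else nv
    ves <- if (nvi > 0) {
      cols <- 5 + seq(0.15, 0.85, length.out = nvi) * 500 / dx
      paste(sprintf("%.3f,%.3f", 10 + off_nm / dx, cols),
            collapse = ";")
    } else ""
    data.frame(contact_id = contact_id, efferent_id = 9L,
               fiber_id = 101L, slice_index = slices[i],
               apposition = apposition, thickening = thickening,
               vesicle_points = ves,
               trace = sprintf("10,%0.4f;10,%0.4f", 5, 5 + 500 / dx))
  })
  do.call(rbind, rows)
}

test_that("five consecutive qualifying slices form exactly one plaque", {
  g <- voxel_geometry(dx = 40, dy = 40, dz = 20)
  crit <- efferent_criteria()
  p5 <- score_contact(make_contact(10:14), crit, g)
  expect_equal(nrow(p5), 1)
  expect_equal(p5$n_slices, 5)
  p4 <- score_contact(make_contact(10:13), crit, g)
  expect_equal(nrow(p4), 0)
  # a 4-vesicle slice breaks the run
  broken <- score_contact(make_contact(10:14, nv = list(6, 6, 4, 6, 6)),
                          crit, g)
  expect_equal(nrow(broken), 0)
  # vesicles beyond two vesicle-diameters do not count
  too_far <- score_contact(make_contact(10:14, far = TRUE), crit, g)
  expect_equal(nrow(too_far), 0)
  # a gap splits runs: 5 + 4 qualifying slices -> one plaque
  split <- score_contact(make_contact(c(10:14, 16:19)), crit, g)
  expect_equal(nrow(split), 1)
  expect_equal(split$slice_start, 10)
})

test_that("plaque area is trace length times slice thickness", {
  g <- voxel_geometry(dx = 40, dy = 40, dz = 20)
  tr <- rbind(c(10, 5), c(10, 5 + 500 / 40))   # straight 500-nm segment
  expect_equal(plaque_area(list(tr), g), 500 * 20 / 1e6)  # 0.01 um^2
  expect_equal(plaque_area(rep(list(tr), 10), g), 0.1)
  expect_warning(a0 <- plaque_area(list(), g), "no traces")
  expect_equal(a0, 0)
})

test_that("per-fiber summaries add plaques exactly", {
  plq <- data.frame(fiber_id = c(101, 101), plaque_id = 1:2,
                    surface_area_um2 = c(0.1, 0.3))
  s <- summarize_efferent(c(101, 102), plq)
  expect_equal(s$total_area_um2, c(0.4, 0))
  expect_equal(s$plaque_count, c(2L, 0L))
  expect_equal(s$mean_plaque_area_um2, c(0.2, NA))
  expect_error(summarize_efferent(c(102), plq), "unknown fiber")
})

test_that("scoring is monotone in added slices and vesicle threshold", {
  g <- voxel_geometry(dx = 40, dy = 40, dz = 20)
  crit <- efferent_criteria()
  base <- make_contact(10:15)
  more <- make_contact(10:16)
  p_base <- score_contact(base, crit, g)
  p_more <- score_contact(more, crit, g)
  expect_gte(nrow(p_more), nrow(p_base))
  expect_gte(sum(p_more$surface_area_um2), sum(p_base$surface_area_um2))
  # raising min_vesicles never increases plaques
  strict <- efferent_criteria(min_vesicles = 7)
  p_strict <- score_contact(base, strict, g)
  expect_lte(nrow(p_strict), nrow(p_base))
  expect_lte(sum(p_strict$surface_area_um2),
             sum(p_base$surface_area_um2))
})

test_that("toggling the thickening criterion reclassifies only its own
          failures", {
  g <- voxel_geometry(dx = 40, dy = 40, dz = 20)
  ok <- make_contact(10:14, contact_id = 1)
  no_thick <- make_contact(20:24, thickening = FALSE, contact_id = 2)
  no_appos <- make_contact(30:34, apposition = FALSE, contact_id = 3)
  tab <- rbind(ok, no_thick, no_appos)
  with_thick <- score_contacts(tab, efferent_criteria(), g)
  expect_equal(sort(unique(with_thick$contact_id)), 1)
  without <- score_contacts(tab, efferent_criteria(
    require_thickening = FALSE), g)
  expect_equal(sort(unique(without$contact_id)), c(1, 2))
})

test_that("phantom efferent scoring recovers planted plaques exactly", {
  ph <- small_phantom()
  g <- ph$volume$geometry
  plq <- score_contacts(ph$annotations$efferent, efferent_criteria(), g)
  eff <- summarize_efferent(
    vapply(ph$truth$fibers, function(x) x$id, integer(1)), plq)
  for (tr in ph$truth$efferent) {
    row <- eff[eff$fiber_id == tr$fiber, ]
    expect_equal(row$plaque_count, tr$plaque_count)
    expect_equal(row$total_area_um2, sum(tr$plaque_areas_um2),
                 tolerance = 1e-4)
  }
  # decomposition: per-fiber totals equal the sum over their plaques
  for (f in unique(plq$fiber_id)) {
    expect_equal(eff$total_area_um2[eff$fiber_id == f],
                 sum(plq$surface_area_um2[plq$fiber_id == f]))
  }
})
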