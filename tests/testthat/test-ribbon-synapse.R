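test_that("a single-voxel ribbon has voxel volume and zero length", {
  arr <- array(0L, dim = c(8, 8, 6))
  arr[4, 4, 3] <- 3001L
  v <- make_volume(arr, c("3001" = "RIBBON"))
  r <- reconstruct_ribbons(v)
  expect_equal(nrow(r), 1)
  expect_equal(r$volume_nm3, 500)     # default 5 x 5 x 20 nm voxels
  expect_equal(r$length_nm, 0)
  expect_false(r$hollow_core)
})

test_that("a voxelized flattened cylinder recovers volume and length", {
  # axis along columns: length 400 nm, elliptical cross 100 x 75 nm
  # semi-axes, at the native 5/5/20 nm geometry
  arr <- array(0L, dim = c(60, 100, 16))
  g <- expand.grid(r = 1:60, c = 1:100, s = 1:16)
  u <- (g$c - 50) * 5
  dv <- (g$r - 30) * 5
  dw <- (g$s - 8) * 20
  inside <- abs(u) <= 200 & (dv / 100)^2 + (dw / 75)^2 <= 1
  arr[cbind(g$r, g$c, g$s)[inside, ]] <- 3001L
  v <- make_volume(arr, c("3001" = "RIBBON"))
  r <- reconstruct_ribbons(v)
  analytic <- 400 * pi * 100 * 75
  expect_lt(abs(r$volume_nm3 - analytic) / analytic, 0.10)
  expect_lt(abs(r$length_nm - 400) / 400, 0.10)
})

test_that("an enclosed cavity marks a ribbon hollow", {
  arr <- array(0L, dim = c(12, 12, 12))
  arr[3:10, 3:10, 3:10] <- 3001L
  arr[5:8, 5:8, 5:8] <- 0L                 # fully enclosed cavity
  v <- make_volume(arr, c("3001" = "RIBBON"))
  expect_true(reconstruct_ribbons(v)$hollow_core)
  arr[5:8, 5:8, 3:8] <- 0L                 # open to the outside: no hole
  v2 <- make_volume(arr, c("3001" = "RIBBON"))
  expect_false(reconstruct_ribbons(v2)$hollow_core)
})

test_that("connected components and hole filling match flood-fill oracles", {
  set.seed(13)
  for (rep in 1:6) {
    d <- sample(10:32, 3, replace = TRUE)
    arr <- array(0L, dim = d)
    for (b in 1:4) {
      ctr <- vapply(d, function(k) sample(seq_len(k), 1), integer(1))
      g <- expand.grid(r = seq_len(d[1]), c = seq_len(d[2]),
                       s = seq_len(d[3]))
      keep <- (g$r - ctr[1])^2 + (g$c - ctr[2])^2 + (g$s - ctr[3])^2 <=
        runif(1, 2, 18)
      arr[cbind(g$r, g$c, g$s)[keep, ]] <- 1L
    }
    for (conn in c(6L, 26L)) {
      cc <- cpp_cc3d(arr, d[1], d[2], d[3], 1L,
                     c(0L, d[1] - 1L, 0L, d[2] - 1L, 0L, d[3] - 1L),
                     conn)
      oc <- oracle_cc3d(arr, conn)
      expect_equal(cc$n, max(oc))
      # same partition: component sizes agree as multisets
      expect_equal(sort(tabulate(cc$comp[cc$comp > 0])),
                   sort(tabulate(oc[oc > 0])))
    }
    filled <- cpp_fill_holes3d(arr, d[1], d[2], d[3])
    expect_equal(as.integer(filled), as.integer(oracle_fill_holes(arr)))
  }
})

# constructed scene: an IHC slab with an apposed fiber and nearby ribbons
linking_scene <- function(two_ribbons = FALSE) {
  g <- voxel_geometry(dx = 40, dy = 40, dz = 20)
  arr <- array(0L, dim = c(40, 40, 60))
  arr[, , 41:55] <- 1L                         # IHC occupying the top
  gg <- expand.grid(r = 1:40, c = 1:40)
  disc <- (gg$r - 20)^2 + (gg$c - 20)^2 <= 36
  for (s in 5:40) arr[cbind(gg$r[disc], gg$c[disc], s)] <- 101L
  # ribbon(s) just inside the IHC, above the fiber tip
  arr[18:22, 18:22, 43:46] <- 3001L
  if (two_ribbons) {
    # second ribbon 100 nm away in-plane (2.5 voxels): separate instance,
    # same apposition
    arr[18:22, 26:30, 43:46] <- 3002L
  }
  cls <- c("1" = "IHC", "101" = "ANF", "3001" = "RIBBON",
           "3002" = "RIBBON")
  make_volume(arr, cls, geometry = g)
}

test_that("ribbons link to the apposed fiber and group into synapses", {
  v <- linking_scene()
  r <- reconstruct_ribbons(v)
  lk <- link_synapses(v, r)
  expect_equal(nrow(lk$synapses), 1)
  expect_equal(lk$synapses$fiber_id, 101)
  expect_equal(lk$synapses$ihc_id, 1)
  expect_equal(lk$synapses$n_ribbons, 1)
  expect_true(is.na(lk$synapses$psd_present))  # no annotations given

  v2 <- linking_scene(two_ribbons = TRUE)
  r2 <- reconstruct_ribbons(v2)
  expect_equal(nrow(r2), 2)
  lk2 <- link_synapses(v2, r2)
  expect_equal(nrow(lk2$synapses), 1)
  expect_equal(lk2$synapses$n_ribbons, 2)
  # volume additivity
  expect_equal(lk2$synapses$total_volume_nm3, sum(r2$volume_nm3))
})

test_that("splitting a ribbon into touching labels leaves totals intact", {
  v <- linking_scene()
  arr <- v$labels
  arr[18:22, 18:19, 43:46] <- 3002L   # split the label; parts still touch
  v2 <- make_volume(arr, c("1" = "IHC", "101" = "ANF",
                           "3001" = "RIBBON", "3002" = "RIBBON"),
                    geometry = v$geometry)
  r1 <- reconstruct_ribbons(v)
  r2 <- reconstruct_ribbons(v2)
  expect_equal(nrow(r2), 1)           # touching labels = one instance
  expect_equal(sum(r2$volume_nm3), sum(r1$volume_nm3))
  lk1 <- link_synapses(v, r1)
  lk2 <- link_synapses(v2, r2)
  expect_equal(lk2$synapses$total_volume_nm3,
               lk1$synapses$total_volume_nm3)
})

test_that("retracted-fiber distance matches the constructed gap", {
  g <- voxel_geometry(dx = 40, dy = 40, dz = 20)
  arr <- array(0L, dim = c(30, 30, 120))
  arr[, , 101:110] <- 1L                       # IHC slab
  gg <- expand.grid(r = 1:30, c = 1:30)
  disc <- (gg$r - 15)^2 + (gg$c - 15)^2 <= 25
  for (s in 5:60) arr[cbind(gg$r[disc], gg$c[disc], s)] <- 101L
  v <- make_volume(arr, c("1" = "IHC", "101" = "ANF"), geometry = g)
  cl <- classify_fibers(v, data.frame(fiber_id = integer(),
                                      psd_present = logical()))
  expect_equal(cl$status, "nonsynaptic_retracted")
  gap_analytic <- (100 - 59) * 20              # 41 slices of 20 nm
  diag_nm <- sqrt(40^2 + 40^2 + 20^2)
  expect_lt(abs(cl$distance_to_nearest_ihc_nm - gap_analytic), diag_nm)
})

test_that("phantom classification and multiplicity recover exactly", {
  ph <- small_phantom()
  rec <- recover_phantom(ph, small_params(ph))
  expect_true(rec$status_match)
  expect_equal(rec$multiplicity_measured, rec$multiplicity_planted)
  # classification partition identity
  cl <- rec$classification
  expect_equal(sum(cl$status == "synaptic") +
                 sum(cl$status == "nonsynaptic_contact") +
                 sum(cl$status == "nonsynaptic_retracted"), nrow(cl))
})

test_that("orphan detection flags only unapposed ribbons", {
  ph <- small_phantom()
  r <- reconstruct_ribbons(ph$volume)
  orphans <- detect_orphans(ph$volume, r)
  orphan_labels <- r$label_id[r$ribbon_id %in% orphans]
  expect_equal(sort(orphan_labels), sort(ph$truth$orphan_ribbon_ids))
  # with an infinite radius every ribbon finds some fiber
  expect_length(detect_orphans(ph$volume, r, orphan_radius = Inf), 0)
  # all-apposed scene has no orphans
  v <- linking_scene()
  expect_length(detect_orphans(v, reconstruct_ribbons(v)), 0)
})

test_that("section frames recover a planar membrane normal within 5
          degrees", {
  # IHC as a tilted half-space with known inward normal; ribbon below it
  g <- voxel_geometry(dx = 40, dy = 40, dz = 20)
  arr <- array(0L, dim = c(60, 60, 80))
  gg <- expand.grid(r = 1:60, c = 1:60, s = 1:80)
  n_true <- anfmorph:::unitize(c(0.15, -0.1, -1))  # (x, y, z), outward
  zplane <- 50 * 20 + (gg$c - 30) * 40 * 0.15 - (gg$r - 30) * 40 * 0.1
  ihc <- gg$s * 20 > zplane
  arr[cbind(gg$r, gg$c, gg$s)[ihc, ]] <- 1L
  # bar-shaped ribbon just below the membrane, long axis along x
  rib <- abs(gg$c - 30) <= 5 & abs(gg$r - 30) <= 2 &
    gg$s * 20 > zplane - 220 & gg$s * 20 < zplane - 80
  arr[cbind(gg$r, gg$c, gg$s)[rib & !ihc, ]] <- 3001L
  v <- make_volume(arr, c("1" = "IHC", "3001" = "RIBBON"), geometry = g)
  r <- reconstruct_ribbons(v)
  fr <- build_section_frame(v, r, r$ribbon_id[1])
  ang <- acos(min(1, abs(sum(fr$membrane_normal * n_true)))) * 180 / pi
  expect_lt(ang, 5)
  # axis projected into the membrane plane, frame orthonormal
  expect_lt(abs(sum(fr$membrane_normal * fr$ribbon_axis)), 1e-6)
  expect_lt(abs(sum(fr$membrane_normal * fr$third_axis)), 1e-6)
  expect_equal(sqrt(sum(fr$ribbon_axis^2)), 1, tolerance = 1e-6)
  # the long axis is close to x
  expect_gt(abs(fr$ribbon_axis[1]), 0.95)
})

test_that("section frames on the curved phantom membrane stay close to
          the planted normals", {
  ph <- small_phantom()
  r <- reconstruct_ribbons(ph$volume)
  truth_norm <- lapply(ph$truth$ribbons, function(x) x$normal)
  names(truth_norm) <- vapply(ph$truth$ribbons, function(x) x$id,
                              integer(1))
  checked <- 0
  for (i in seq_len(nrow(r))) {
    tn <- truth_norm[[as.character(r$label_id[i])]]
    if (is.null(tn)) next
    fr <- build_section_frame(ph$volume, r, r$ribbon_id[i])
    ang <- acos(min(1, abs(sum(fr$membrane_normal * unlist(tn))))) *
      180 / pi
    # the 500-nm patch on a 3-um hemisphere subtends ~10 degrees, so the
    # fitted normal can deviate from the planted one by a few degrees
    expect_lt(ang, 10)
    expect_lt(abs(sum(fr$membrane_normal * fr$ribbon_axis)), 1e-6)
    checked <- checked + 1
    if (checked >= 4) break
  }
  expect_gte(checked, 2)
})

test_that("axis-aligned re-sectioning reproduces the native slice", {
  ph <- small_phantom()
  g <- ph$volume$geometry
  origin <- c(128 * g$dx, 128 * g$dy, 200 * g$dz)   # (x, y, z) nm
  fr <- structure(list(origin = origin,
                       membrane_normal = c(0, 0, 1),
                       ribbon_axis = c(1, 0, 0),
                       third_axis = c(0, 1, 0),
                       degenerate = FALSE),
                  class = "section_frame")
  img <- resection(ph$volume, fr, "membrane_parallel", extent_nm = 800,
                   step_nm = g$dx)
  n <- nrow(img)
  half <- (n - 1) / 2
  for (i in c(1, ceiling(n / 2), n)) {
    for (j in c(1, ceiling(n / 2), n)) {
      col <- 128 + (i - 1 - half)
      row <- 128 + (j - 1 - half)
      expect_equal(img[i, j], ph$volume$labels[row + 1, col + 1, 201])
    }
  }
  # flipping the in-plane axes mirrors the image
  fr2 <- fr
  fr2$ribbon_axis <- -fr$ribbon_axis
  fr2$third_axis <- -fr$third_axis
  img2 <- resection(ph$volume, fr2, "membrane_parallel", extent_nm = 800,
                    step_nm = g$dx)
  expect_equal(img2, img[n:1, n:1], ignore_attr = TRUE)
})

test_that("re-section images round-trip through TIFF", {
  img <- matrix(c(0L, 1L, 3001L, 0L), 2, 2)
  path <- file.path(tempdir(), "resection.tif")
  save_resection(img, path)
  back <- tiff::readTIFF(path, as.is = TRUE)
  expect_equal(matrix(as.integer(back), 2, 2), img)
  unlink(path)
})
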