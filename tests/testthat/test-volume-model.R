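test_that("voxel geometry validates and reports the voxel volume", {
  g <- voxel_geometry()
  expect_equal(voxel_volume(g), 500)   # 5 x 5 x 20 nm
  expect_error(voxel_geometry(dx = 0), "dx > 0")
  g2 <- voxel_geometry(dx = 40, dy = 40, dz = 20)
  expect_equal(voxel_volume(g2), 32000)
})

test_that("label volume construction enforces the label table", {
  arr <- array(0L, dim = c(6, 6, 4))
  arr[3, 3, 2] <- 7L
  # label present in lattice but absent from the table, named in the error
  expect_error(
    label_volume(arr, voxel_geometry(), label_table(1L, "ANF")),
    "7")
  # MITO whose parent is not an ANF label
  arr[4, 4, 2] <- 9L
  expect_error(
    label_volume(arr, voxel_geometry(),
                 label_table(c(7L, 9L), c("ANF", "MITO"), c(NA, 55L))),
    "MITO.*9")
  # missing parents warn and can be inferred from adjacency
  expect_warning(
    v_na <- label_volume(arr, voxel_geometry(),
                         label_table(c(7L, 9L), c("ANF", "MITO"))),
    "assign_mito_parents")
  v <- label_volume(arr, voxel_geometry(),
                    label_table(c(7L, 9L), c("ANF", "MITO"),
                                c(NA, 7L)))
  expect_s3_class(v, "label_volume")
  # non-3D and non-integer input rejected
  expect_error(label_volume(matrix(0L, 3, 3), voxel_geometry(),
                            label_table()), "3D")
  arrd <- array(0.5, dim = c(3, 3, 3))
  expect_error(label_volume(arrd, voxel_geometry(), label_table()),
               "integer")
  # empty volume with empty table is valid
  v0 <- label_volume(array(0L, dim = c(10, 10, 10)), voxel_geometry(),
                     label_table())
  expect_equal(nrow(v0$summary), 0)
})

test_that("slice profiles measure single-voxel and bar profiles", {
  arr <- array(0L, dim = c(5, 5, 3))
  arr[3, 3, 2] <- 1L
  v <- make_volume(arr, c("1" = "ANF"))
  p <- slice_profiles(v, 1L)
  expect_equal(nrow(p), 1)
  expect_equal(p$area_nm2, 25)            # one 5x5 nm pixel
  expect_equal(p$perimeter_nm, 20)        # crack contour of one voxel
  expect_equal(p$slice_index, 1)          # 0-based
  expect_equal(p$circularity, 1)          # Crofton index capped at 1

  arr <- array(0L, dim = c(5, 14, 3))
  arr[3, 3:12, 2] <- 1L
  v <- make_volume(arr, c("1" = "ANF"))
  p <- slice_profiles(v, 1L)
  expect_equal(p$area_nm2, 250)
  expect_equal(p$perimeter_nm, 110)
  # Crofton perimeter of the 1x10 bar is 19.7466 px (matches the
  # reference estimator in scikit-image): 4*pi*10 / 19.7466^2
  expect_equal(p$circularity, 4 * pi * 10 / 19.74659^2,
               tolerance = 1e-4)
})

test_that("a digitized disc has circularity near 1", {
  g <- expand.grid(r = -40:40, c = -40:40)
  disc <- matrix(as.integer(g$r^2 + g$c^2 <= 30^2), 81, 81)
  arr <- array(0L, dim = c(81, 81, 1))
  arr[, , 1] <- disc
  v <- make_volume(arr, c("1" = "ANF"))
  p <- slice_profiles(v, 1L)
  expect_gt(p$circularity, 0.95)
  expect_lt(p$circularity, 1.05)
})

test_that("per-slice areas conserve the voxel-count volume exactly", {
  set.seed(5)
  arr <- array(0L, dim = c(30, 30, 12))
  for (b in 1:5) {
    ctr <- sample(8:22, 3)
    g <- expand.grid(r = 1:30, c = 1:30, s = 1:12)
    keep <- (g$r - ctr[1])^2 + (g$c - ctr[2])^2 +
      4 * (g$s - ctr[3] %% 12)^2 <= 25
    arr[cbind(g$r, g$c, g$s)[keep, ]] <- 1L
  }
  v <- make_volume(arr, c("1" = "ANF"))
  p <- slice_profiles(v, 1L)
  gg <- v$geometry
  expect_equal(sum(p$area_nm2) * gg$dz, sum(arr == 1) * voxel_volume(gg))
  # profile completeness: per-slice areas equal per-slice voxel counts
  per_slice <- vapply(seq_len(dim(arr)[3]),
                      function(s) sum(arr[, , s] == 1L), integer(1))
  got <- tapply(p$area_nm2 / (gg$dx * gg$dy), p$slice_index, sum)
  expect_equal(as.numeric(got), as.numeric(per_slice[per_slice > 0]))
})

test_that("physical distances scale each axis by its pitch", {
  g <- voxel_geometry()
  expect_equal(physical_distance(c(1, 2, 3), c(1, 2, 3), g), 0)
  expect_equal(physical_distance(c(0, 0, 0), c(0, 0, 1), g), 20)
  # 1 slice, 3 rows, 4 cols at (5, 5, 20) nm
  expect_equal(physical_distance(c(0, 0, 0), c(3, 4, 1), g),
               sqrt(20^2 + 15^2 + 20^2))
})

test_that("label volumes round-trip through NRRD and TIFF bit-exactly", {
  set.seed(9)
  arr <- array(sample(c(0L, 0L, 1L, 2L, 300L), 20 * 18 * 7,
                      replace = TRUE), dim = c(20, 18, 7))
  tab <- label_table(c(1L, 2L, 300L), c("IHC", "ANF", "RIBBON"))
  v <- label_volume(arr, voxel_geometry(dx = 40, dy = 40, dz = 20), tab)
  for (ext in c("nrrd", "tif")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    save_label_volume(v, path, extra = list(note = "fixture"))
    v2 <- load_label_volume(path)
    expect_identical(v2$labels, v$labels)
    expect_equal(v2$geometry$dx, 40)
    expect_equal(sort(v2$table$label), sort(v$table$label))
    unlink(c(path, anfmorph:::sidecar_path(path)))
  }
  expect_error(load_label_volume(file.path(tempdir(), "absent.nrrd")),
               "not found")
})

test_that("a phantom volume survives a write/read round trip", {
  ph <- small_phantom()
  dir <- file.path(tempdir(), "phantom_rt")
  write_phantom(ph, dir, format = "nrrd")
  v2 <- load_label_volume(file.path(dir, "labels.nrrd"))
  expect_identical(v2$labels, ph$volume$labels)
  expect_equal(nrow(v2$table), nrow(ph$volume$table))
  eff <- read_efferent_contacts(file.path(dir, "efferent_contacts.csv"))
  expect_equal(nrow(eff), nrow(ph$annotations$efferent))
  unlink(dir, recursive = TRUE)
})

test_that("missing mitochondrion parents are inferred by adjacency", {
  arr <- array(0L, dim = c(16, 16, 8))
  arr[3:10, 3:10, 2:7] <- 101L
  arr[5:7, 5:7, 3:5] <- 9001L          # carved out of fiber 101
  arr[12:14, 12:14, 3:5] <- 102L       # a second, non-adjacent fiber
  suppressWarnings(
    v <- label_volume(arr, voxel_geometry(dx = 40, dy = 40, dz = 20),
                      label_table(c(101L, 102L, 9001L),
                                  c("ANF", "ANF", "MITO"))))
  v2 <- assign_mito_parents(v)
  row <- v2$table[v2$table$label == 9001, ]
  expect_equal(row$parent, 101L)
  expect_true(row$parent_inferred)
})
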