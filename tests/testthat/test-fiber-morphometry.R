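# fixture: a straight vertical tube (radius in voxels) with optional
# mitochondrion labels carved inside it
tube_volume <- function(radius_px = 6, n_slices = 60, dim_xy = 24,
                        geometry = voxel_geometry(dx = 40, dy = 40,
                                                  dz = 20)) {
  arr <- array(0L, dim = c(dim_xy, dim_xy, n_slices))
  ctr <- dim_xy / 2
  g <- expand.grid(r = 1:dim_xy, c = 1:dim_xy)
  disc <- (g$r - ctr)^2 + (g$c - ctr)^2 <= radius_px^2
  for (s in seq_len(n_slices)) {
    arr[cbind(g$r[disc], g$c[disc], s)] <- 101L
  }
  list(arr = arr, geometry = geometry, ctr = ctr)
}

test_that("a fiber without mitochondria yields all-zero mito profiles", {
  tv <- tube_volume()
  v <- make_volume(tv$arr, c("101" = "ANF"), geometry = tv$geometry)
  s <- build_fiber_series(v, 101L)
  expect_equal(nrow(s$slices), 60)
  expect_true(all(s$slices$mito_total_area_nm2 == 0))
  expect_true(all(s$slices$mito_profile_count == 0))
  expect_equal(s$terminus_slice, 59)
  expect_error(build_fiber_series(v, 999L), "not an ANF")
})

test_that("an ellipsoidal mitochondrion recovers its analytic volume", {
  tv <- tube_volume(radius_px = 8, dim_xy = 32, n_slices = 80)
  arr <- tv$arr
  # axis-aligned ellipsoid, radii (120, 120, 300) nm at (40,40,20) pitch
  g <- expand.grid(r = 1:32, c = 1:32, s = 1:80)
  inside <- ((g$r - 16) * 40 / 120)^2 + ((g$c - 16) * 40 / 120)^2 +
    ((g$s - 40) * 20 / 300)^2 <= 1
  arr[cbind(g$r, g$c, g$s)[inside & arr[cbind(g$r, g$c, g$s)] == 101L, ]] <-
    5001L
  v <- make_volume(arr, c("101" = "ANF", "5001" = "MITO"),
                   parents = c("101" = NA, "5001" = 101),
                   geometry = tv$geometry)
  s <- build_fiber_series(v, 101L)
  vol_meas <- sum(s$slices$mito_total_area_nm2) * tv$geometry$dz
  vol_analytic <- 4 / 3 * pi * 120 * 120 * 300
  expect_lt(abs(vol_meas - vol_analytic) / vol_analytic, 0.10)
  # the carved organelle still counts toward the fiber's outer profile
  a0 <- pi * 8^2 * 40 * 40
  expect_gt(min(s$slices$fiber_area_nm2), 0.9 * a0)
})

test_that("terminal partition splits at 200 slices and flags short fibers", {
  s <- fake_series(rep(10, 300))
  p <- partition_terminal(s)
  expect_equal(p$terminal_range, c(100, 299))
  expect_equal(p$preterminal_range, c(0, 99))
  expect_false(p$truncated)
  s2 <- fake_series(rep(10, 120))
  p2 <- partition_terminal(s2)
  expect_true(p2$truncated)
  expect_equal(p2$terminal_range, c(0, 119))
  expect_null(p2$preterminal_range)
})

test_that("peak window ties break toward the terminus", {
  s <- fake_series(rep(7, 400))
  p <- partition_terminal(s)
  expect_equal(p$mito_peak_window[2], s$terminus_slice)
})

test_that("window search matches brute-force enumeration", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(120:400, 1)
    areas <- runif(n, 0, 1e5)
    if (i %% 2 == 0) {
      # add a triangular bump at a random terminal position
      c0 <- sample(max(1, n - 180):(n - 30), 1)
      w <- 0:24
      bump <- c(rev(w), 25, w) / 25 * 3e5
      lo <- max(1, c0 - 25); hi <- min(n, c0 + 25)
      areas[lo:hi] <- areas[lo:hi] + bump[(lo - c0 + 26):(hi - c0 + 26)]
    }
    s <- fake_series(areas)
    p <- partition_terminal(s)
    term_rows <- (max(1, n - 200 + 1)):n
    w <- min(50, length(term_rows))
    start_o <- oracle_peak_window(areas, term_rows, w)
    expect_equal(p$mito_peak_window[1], start_o - 1)  # 0-based
  }
})

test_that("peak-aligned profiles are translation invariant and peak at 0", {
  areas <- c(rep(5, 150), seq(5, 3e5, length.out = 26),
             seq(3e5, 5, length.out = 26), rep(5, 98))
  s1 <- fake_series(areas, start_slice = 0)
  s2 <- fake_series(areas, start_slice = 10)
  a1 <- peak_aligned_profile(s1, partition_terminal(s1))
  a2 <- peak_aligned_profile(s2, partition_terminal(s2))
  expect_equal(a1$slice_rel, a2$slice_rel)
  expect_equal(a1$mito_total_area_nm2, a2$mito_total_area_nm2)
  expect_equal(a1$slice_rel[which.max(a1$mito_total_area_nm2)], 0,
               tolerance = 2)
})

test_that("circularity rejection filters only oblique pre-terminal slices", {
  # tube with an elongated (bar-shaped) stretch in the pre-terminal region
  arr <- array(0L, dim = c(30, 30, 100))
  g <- expand.grid(r = 1:30, c = 1:30)
  disc <- (g$r - 15)^2 + (g$c - 15)^2 <= 36
  for (s in 1:100) arr[cbind(g$r[disc], g$c[disc], s)] <- 101L
  for (s in 21:30) {
    arr[, , s] <- 0L
    arr[14:16, 4:27, s] <- 101L    # 3 x 24 bar: strongly elongated
  }
  v <- make_volume(arr, c("101" = "ANF"),
                   geometry = voxel_geometry(dx = 40, dy = 40, dz = 20))
  s <- build_fiber_series(v, 101L)
  p <- partition_terminal(s, terminal_slices = 50)
  f <- filter_preterminal_circularity(s, p, 0.8)
  rej <- f$slices$slice_index[f$slices$rejected]
  expect_equal(rej, 20:29)
  # filtering only removes: non-rejected rows keep their values
  expect_equal(f$slices$fiber_area_nm2[!f$slices$rejected],
               s$slices$fiber_area_nm2[!f$slices$rejected])
  # degenerate threshold keeps everything
  f0 <- filter_preterminal_circularity(s, p, 0)
  expect_false(any(f0$slices$rejected))
  # all-circular series: nothing rejected at the working threshold
  s_ok <- fake_series(rep(10, 300))
  expect_false(any(filter_preterminal_circularity(
    s_ok, partition_terminal(s_ok), 0.8)$slices$rejected))
})

test_that("profile statistics count planted profiles exactly at stride 1", {
  ph <- small_phantom()
  fid <- ph$truth$fibers[[1]]$id
  s <- build_fiber_series(ph$volume, fid)
  st <- mito_profile_stats(list(s), stride = 1)
  planted <- ph$truth$fibers[[1]]$mito_slice_count
  expect_equal(st$per_fiber$n_profiles, sum(planted))
  measured <- s$slices$mito_profile_count
  expect_equal(measured, planted[s$slices$slice_index + 1])
})

test_that("a single one-voxel profile per slice gives count 1, area dx*dy", {
  arr <- array(0L, dim = c(10, 10, 20))
  arr[3:8, 3:8, ] <- 101L
  for (s in 1:20) arr[5, 5, s] <- 5001L
  v <- make_volume(arr, c("101" = "ANF", "5001" = "MITO"),
                   parents = c("101" = NA, "5001" = 101),
                   geometry = voxel_geometry(dx = 40, dy = 40, dz = 20))
  st <- mito_profile_stats(list(build_fiber_series(v, 101L)), stride = 1)
  expect_equal(st$mean_profiles_per_slice, 1)
  expect_equal(st$mean_profile_area_nm2, 1600)
})
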