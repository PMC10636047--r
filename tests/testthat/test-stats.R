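test_that("side assignment follows the dividing plane conventions", {
  pl <- dividing_plane(c(0, 100, 0), c(0, 1, 0))
  expect_equal(assign_side(c(5, 200, 3), pl), "modiolar")
  expect_equal(assign_side(c(5, 50, 3), pl), "pillar")
  expect_message(on_plane <- assign_side(c(5, 100, 3), pl), "convention")
  expect_equal(on_plane, "modiolar")
  # flipping the normal swaps every assignment
  set.seed(2)
  pts <- cbind(runif(20, 0, 10), runif(20, 0, 200), runif(20, 0, 10))
  a <- assign_side(pts, pl)
  b <- assign_side(pts, dividing_plane(c(0, 100, 0), c(0, -1, 0)))
  expect_true(all(a != b))
})

test_that("per-IHC side assignment agrees with the global plane when the
          planes coincide and differs on borderline fibers when tilted", {
  pl <- dividing_plane(c(0, 100, 0), c(0, 1, 0))
  pts <- cbind(x = c(1, 2, 3, 4), y = c(90, 98, 102, 110), z = 0)
  ihc <- c(1, 1, 2, 2)
  same <- assign_side_per_ihc(pts, ihc, list("1" = pl, "2" = pl))
  expect_equal(same, assign_side(pts, pl))
  # a tilted plane for IHC 2 flips its borderline fiber
  tilted <- dividing_plane(c(0, 104, 0), c(0, 1, 0))
  mixed <- assign_side_per_ihc(pts, ihc, list("1" = pl, "2" = tilted))
  expect_equal(mixed[3], "pillar")      # was modiolar globally
  expect_equal(mixed[4], "modiolar")
  expect_warning(assign_side_per_ihc(pts, c(1, 1, 2, 3),
                                     list("1" = pl, "2" = pl)),
                 "without an associated IHC")
})

test_that("two-group comparisons equal exact Mann-Whitney enumeration", {
  set.seed(8)
  for (i in 1:12) {
    n1 <- sample(3:5, 1); n2 <- sample(4:8, 1)
    x <- runif(n1); y <- runif(n2) + runif(1, -0.5, 0.5)
    res <- compare_groups(list(a = x, b = y))
    expect_equal(res$test, "mann_whitney")
    expect_equal(res$p_value, oracle_mw_exact(x, y), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis is null for identical groups and Dunn separates
          a shifted group", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res <- compare_groups(same)
  expect_equal(unname(res$statistic), 0)
  set.seed(4)
  g <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15) + 10)
  res2 <- compare_groups(g)
  pw <- res2$pairwise
  hit_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(pw$p_adj[hit_c] < 0.05))
  expect_gt(pw$p_adj[!hit_c], 0.05)
  expect_true(all(pw$p_adj >= 0 & pw$p_adj <= 1))
  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "'a'")
})

test_that("type-I error of the two-group test is calibrated at 0.05", {
  set.seed(77)
  reject <- logical(2000)
  for (i in seq_along(reject)) {
    reject[i] <- compare_groups(list(a = rnorm(10),
                                     b = rnorm(10)))$p_value < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("percent change and fractions follow half-up rounding", {
  expect_identical(percent_change(2.48, 3.75), 51L)
  expect_identical(percent_change(0.496, 0.666), 34L)
  expect_identical(percent_change(5, 5), 0L)
  expect_identical(percent_change(4, 2), -50L)
  expect_error(percent_change(0, 1), "positive")
  expect_identical(fraction_report(31, 59), 53L)
  expect_identical(fraction_report(0, 10), 0L)
  expect_identical(fraction_report(2, 71), 3L)
  expect_error(fraction_report(5, 0), "positive")
  expect_error(fraction_report(7, 5), "numerator")
})

test_that("stack reports assert their count identities", {
  fib <- data.frame(
    status = c(rep("synaptic", 24), rep("nonsynaptic_contact", 3),
               rep("nonsynaptic_retracted", 2)),
    distance_to_nearest_ihc_nm = c(rep(0, 27), 2000, 2200))
  syn <- data.frame(synapse_id = 1:24, fiber_id = 1:24, ihc_id = 1,
                    n_ribbons = c(rep(1, 20), rep(2, 3), 3),
                    total_volume_nm3 = 1, total_length_nm = 1,
                    psd_present = TRUE)
  rep <- stack_report(fib, syn, span_um = 18)
  expect_equal(rep$counts$fibers, 29)
  expect_equal(rep$counts$multiplicity$single, 20)
  expect_equal(rep$synapses_per_20um, 24 * 20 / 18)
  expect_equal(rep$percentages$nonsynaptic, fraction_report(5, 29))
  expect_equal(rep$mean_retraction_distance_um, 2.1)
})

test_that("group statistics skip degenerate group sets with a notice", {
  tabs <- list(control = data.frame(x = rnorm(10, 5)),
               day1 = data.frame(x = rep(NA_real_, 10)))
  out <- group_statistics(tabs, "x")
  expect_match(out$note, "skipped")
  tabs$day1$x <- rnorm(10, 7)
  out2 <- group_statistics(tabs, "x")
  expect_s3_class(out2$stat, "stat_result")
  expect_true(is.integer(out2$percent_change))
})
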