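# Per-fiber longitudinal profiling: mitochondrial area per slice,
# terminal/pre-terminal partition, mito-peak alignment, circularity-based
# rejection of obliquely cut pre-terminal profiles, and mitochondrial
# profile counting.

#' Build the longitudinal profile series of one fiber
#'
#' Aggregates the per-slice outer profile of an ANF (its own label plus all
#' mitochondrion labels whose parent is the fiber, with 2D holes filled so
#' carved-out organelles count toward the fiber cross-section) and the
#' per-slice profiles of those mitochondria. The terminus is the fiber's
#' maximal occupied slice (the convention is that increasing slice index
#' approaches the IHC apex).
#'
#' @param volume A [label_volume()].
#' @param fiber_id An ANF label id.
#' @param fiber_profile Compute the fiber's own outer-contour area and
#'   circularity per slice (default TRUE). With FALSE only the
#'   mitochondrial profiles are measured (fiber_area and circularity are
#'   NA), which is considerably faster when only mitochondrial content is
#'   needed.
#' @return A `fiber_series`: list with `fiber_id`, `slices` (data.frame
#'   with slice_index, fiber_area_nm2, fiber_circularity,
#'   mito_total_area_nm2, mito_profile_count, rejected), `profile_areas`
#'   (list of per-slice mitochondrial profile areas, nm^2) and
#'   `terminus_slice`.
#' @export
build_fiber_series <- function(volume, fiber_id, fiber_profile = TRUE) {
  stopifnot(inherits(volume, "label_volume"))
  tab <- volume$table
  if (!fiber_id %in% tab$label[tab$class == "ANF"]) {
    stop("label ", fiber_id, " is not an ANF label")
  }
  if (!fiber_id %in% volume$summary$label) {
    stop("fiber ", fiber_id, " has zero voxels")
  }
  g <- volume$geometry
  d <- dim(volume$labels)
  mito_ids <- tab$label[tab$class == "MITO" & !is.na(tab$parent) &
                          tab$parent == fiber_id]
  mito_ids <- mito_ids[mito_ids %in% volume$summary$label]
  bb <- label_bbox(volume, c(fiber_id, mito_ids))

  if (fiber_profile) {
    fib <- cpp_mask_slice_stats(volume$labels, d[1], d[2], d[3],
                                as.integer(c(fiber_id, mito_ids)),
                                union_mode = TRUE, fill_holes = TRUE,
                                bbox = bb)
    if (nrow(fib) == 0) stop("fiber ", fiber_id, " has zero voxels")
    # per-slice outer profile: area sums; circularity of the largest part
    spl <- split(fib, fib$slice)
    slice_idx <- as.integer(names(spl))
    area_px <- vapply(spl, function(x) sum(x$area_px), numeric(1))
    circ <- vapply(spl, function(x) {
      i <- which.max(x$area_px)
      min(1, 4 * pi * x$area_px[i] / max(x$crofton_px[i], 1e-12)^2)
    }, numeric(1))
  } else {
    sm <- volume$summary[volume$summary$label == fiber_id, ]
    slice_idx <- sm$smin:sm$smax
    area_px <- rep(NA_real_, length(slice_idx))
    circ <- rep(NA_real_, length(slice_idx))
  }

  gapped <- any(diff(sort(slice_idx)) > 1L)
  if (gapped) {
    warning("fiber ", fiber_id, " is not contiguous across slices")
  }

  mito_areas <- rep(list(numeric(0)), length(slice_idx))
  names(mito_areas) <- as.character(slice_idx)
  if (length(mito_ids) > 0) {
    mt <- cpp_mask_slice_stats(volume$labels, d[1], d[2], d[3],
                               as.integer(mito_ids), union_mode = FALSE,
                               fill_holes = FALSE, bbox = bb)
    if (nrow(mt) > 0) {
      for (sl in split(mt, mt$slice)) {
        key <- as.character(sl$slice[1])
        if (!is.null(mito_areas[[key]])) {
          mito_areas[[key]] <- sl$area_px * g$dx * g$dy
        }
      }
    }
  }
  ord <- order(slice_idx)
  slices <- data.frame(
    slice_index = slice_idx[ord],
    fiber_area_nm2 = area_px[ord] * g$dx * g$dy,
    fiber_circularity = circ[ord],
    mito_total_area_nm2 = vapply(mito_areas[ord], sum, numeric(1)),
    mito_profile_count = vapply(mito_areas[ord], length, integer(1)),
    rejected = FALSE
  )
  structure(
    list(fiber_id = fiber_id, slices = slices,
         profile_areas = mito_areas[ord],
         terminus_slice = max(slice_idx)),
    class = "fiber_series"
  )
}

#' @export
print.fiber_series <- function(x, ...) {
  cat(sprintf(
    "<fiber_series> fiber %d: %d slices (%d..%d), %d mito-profile rows\n",
    x$fiber_id, nrow(x$slices), min(x$slices$slice_index),
    x$terminus_slice, sum(x$slices$mito_profile_count)))
  invisible(x)
}

#' Partition a fiber into terminal and pre-terminal regions
#'
#' The terminal region is the distalmost `terminal_slices` acquisition
#' slices ending at the terminus (4 um at 20-nm sections for the default
#' 200); the rest is pre-terminal. Within the terminal region, the
#' mito-peak window is the contiguous `peak_window`-slice interval with the
#' highest mean mitochondrial cross-sectional area, ties broken toward the
#' terminus; its middle slice is the mito-peak center. Fibers spanning
#' fewer than `terminal_slices` slices are entirely terminal and flagged
#' truncated.
#'
#' @param series A [build_fiber_series()] result.
#' @param terminal_slices Terminal-region length in slices (default 200).
#' @param peak_window Mito-peak window length in slices (default 50).
#' @return A `terminal_partition`: list with `terminal_range`,
#'   `preterminal_range` (NULL when truncated), `mito_peak_window`,
#'   `mito_peak_center`, `truncated`.
#' @export
partition_terminal <- function(series, terminal_slices = 200,
                               peak_window = 50) {
  stopifnot(inherits(series, "fiber_series"), terminal_slices >= 1,
            peak_window >= 1)
  sl <- series$slices
  n <- nrow(sl)
  if (n == 0) stop("empty fiber series")
  k <- min(terminal_slices, n)
  term_rows <- (n - k + 1):n
  truncated <- n < terminal_slices
  terminal_range <- c(sl$slice_index[term_rows[1]], sl$slice_index[n])
  preterminal_range <- if (truncated) NULL else
    c(sl$slice_index[1], sl$slice_index[n - k])

  w <- min(peak_window, k)
  a <- sl$mito_total_area_nm2[term_rows]
  cs <- cumsum(c(0, a))
  wins <- seq_len(k - w + 1)
  means <- (cs[wins + w] - cs[wins]) / w
  best <- wins[max(which(means == max(means)))]   # ties toward terminus
  start_row <- term_rows[best]
  window <- c(sl$slice_index[start_row],
              sl$slice_index[start_row + w - 1])
  center <- sl$slice_index[start_row + floor(w / 2)]
  structure(
    list(terminal_range = terminal_range,
         preterminal_range = preterminal_range,
         mito_peak_window = window, mito_peak_center = center,
         peak_window_slices = w, truncated = truncated),
    class = "terminal_partition"
  )
}

#' Re-index a fiber's mitochondrial profile to its mito-peak
#'
#' Order-preserving re-index with no resampling: slice 0 of the output is
#' the mito-peak center, negative indices are habenular of it.
#'
#' @param series A [build_fiber_series()] result.
#' @param partition The [partition_terminal()] of the same series.
#' @return data.frame(slice_rel, mito_total_area_nm2, fiber_area_nm2).
#' @export
peak_aligned_profile <- function(series, partition) {
  stopifnot(inherits(series, "fiber_series"),
            inherits(partition, "terminal_partition"))
  sl <- series$slices
  data.frame(
    slice_rel = sl$slice_index - partition$mito_peak_center,
    mito_total_area_nm2 = sl$mito_total_area_nm2,
    fiber_area_nm2 = sl$fiber_area_nm2
  )
}

#' Reject obliquely cut pre-terminal profiles by circularity
#'
#' Pre-terminal slices whose fiber circularity falls below the threshold
#' (profiles "stretched" where the fiber runs parallel to the section
#' plane) are flagged rejected and excluded from downstream area
#' statistics. Terminal slices are never filtered.
#'
#' @param series A [build_fiber_series()] result.
#' @param partition The matching [partition_terminal()].
#' @param threshold Circularity threshold (default 0.8).
#' @return The series with its `rejected` column updated.
#' @export
filter_preterminal_circularity <- function(series, partition,
                                           threshold = 0.8) {
  stopifnot(inherits(series, "fiber_series"),
            inherits(partition, "terminal_partition"))
  sl <- series$slices
  pre <- sl$slice_index < partition$terminal_range[1]
  sl$rejected <- pre & !is.na(sl$fiber_circularity) &
    sl$fiber_circularity < threshold
  series$slices <- sl
  series
}

#' Mitochondrial profile statistics across a cohort of fibers
#'
#' Samples every `stride`-th occupied (non-rejected) slice of each fiber
#' and returns the cohort mean number of mitochondrial profiles per
#' section and the mean area of a single profile, with standard errors
#' over fibers.
#'
#' @param series_list List of [build_fiber_series()] results (optionally
#'   circularity-filtered).
#' @param stride Sampling stride in slices (default 10, i.e. every 10th
#'   section).
#' @return list with `mean_profiles_per_slice`, `se_profiles_per_slice`,
#'   `mean_profile_area_nm2`, `se_profile_area_nm2`, `n_fibers`,
#'   `n_slices_sampled`, `n_profiles` and the per-fiber table `per_fiber`.
#' @export
mito_profile_stats <- function(series_list, stride = 10) {
  stopifnot(stride >= 1)
  per <- lapply(series_list, function(s) {
    keep <- !s$slices$rejected
    rows <- which(keep)[seq(1, sum(keep), by = stride)]
    counts <- s$slices$mito_profile_count[rows]
    areas <- unlist(s$profile_areas[rows], use.names = FALSE)
    data.frame(
      fiber_id = s$fiber_id,
      n_slices = length(rows),
      mean_count = mean(counts),
      mean_area_nm2 = if (length(areas)) mean(areas) else NA_real_,
      n_profiles = length(areas)
    )
  })
  per <- do.call(rbind, per)
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  }
  list(
    mean_profiles_per_slice = mean(per$mean_count),
    se_profiles_per_slice = se(per$mean_count),
    mean_profile_area_nm2 = mean(per$mean_area_nm2, na.rm = TRUE),
    se_profile_area_nm2 = se(per$mean_area_nm2),
    n_fibers = nrow(per),
    n_slices_sampled = sum(per$n_slices),
    n_profiles = sum(per$n_profiles),
    per_fiber = per
  )
}

#' Regional mitochondrial summary of one fiber
#'
#' Mean (and summed) mitochondrial cross-sectional area in the mito-peak
#' window, the terminal region and the pre-terminal region, honouring the
#' circularity rejection flags in the pre-terminal region.
#'
#' @param series A (possibly filtered) [build_fiber_series()].
#' @param partition The matching [partition_terminal()].
#' @return One-row data.frame.
#' @export
fiber_region_summary <- function(series, partition) {
  sl <- series$slices
  term <- sl$slice_index >= partition$terminal_range[1]
  peak <- sl$slice_index >= partition$mito_peak_window[1] &
    sl$slice_index <= partition$mito_peak_window[2]
  pre <- !term & !sl$rejected
  m <- function(idx) if (any(idx)) mean(sl$mito_total_area_nm2[idx]) else
    NA_real_
  s <- function(idx) if (any(idx)) sum(sl$mito_total_area_nm2[idx]) else
    NA_real_
  data.frame(
    fiber_id = series$fiber_id,
    terminus_slice = series$terminus_slice,
    mito_peak_center = partition$mito_peak_center,
    truncated = partition$truncated,
    peak_mean_area_nm2 = m(peak), peak_sum_area_nm2 = s(peak),
    terminal_mean_area_nm2 = m(term), terminal_sum_area_nm2 = s(term),
    preterminal_mean_area_nm2 = m(pre), preterminal_sum_area_nm2 = s(pre),
    n_rejected_slices = sum(sl$rejected)
  )
}

#' Plot-ready peak-aligned profile table for a cohort
#'
#' Long-format table of per-slice mitochondrial areas re-indexed to each
#' fiber's mito-peak (slice 0 = peak center), mirroring per-fiber
#' longitudinal profile plots.
#'
#' @param series_list Named list of [build_fiber_series()] results.
#' @param partitions Matching list of [partition_terminal()] results.
#' @return data.frame(fiber_id, slice_rel, mito_total_area_nm2,
#'   fiber_area_nm2).
#' @export
aligned_profile_table <- function(series_list, partitions) {
  out <- lapply(seq_along(series_list), function(i) {
    ap <- peak_aligned_profile(series_list[[i]], partitions[[i]])
    cbind(fiber_id = series_list[[i]]$fiber_id, ap)
  })
  do.call(rbind, out)
}
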