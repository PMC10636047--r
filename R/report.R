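# Stack-level reporting: counts, identities, percentage summaries and
# group statistics assembled from the per-fiber table.

#' Assemble the stack-level report
#'
#' Emits per-stack counts (fibers, synaptic, non-synaptic contact and
#' retracted, ribbon-multiplicity histogram, orphans), the percentage
#' summaries, mean mitochondrial and efferent metrics (side-stratified
#' when sides are available) and the synapse count normalized to a 20-um
#' cochlear span. The count identities (synaptic + non-synaptic = total;
#' contact + retracted = non-synaptic; multiplicity histogram sums to the
#' synapse count) are asserted on every report.
#'
#' @param fibers Per-fiber table (one row per fiber) with at least
#'   `status`, and optionally `side` and the mitochondrial/efferent metric
#'   columns produced by [analyze_stack()].
#' @param synapses Synapse table from [link_synapses()].
#' @param span_um Cochlear span of the stack in um.
#' @param orphan_ids Orphan ribbon ids ([detect_orphans()]).
#' @param group Condition tag ("control", "day1", "week1" or NA).
#' @param stack_id Stack identifier.
#' @return A `stack_report` (nested list, JSON-serializable).
#' @export
stack_report <- function(fibers, synapses, span_um, orphan_ids = integer(),
                         group = NA_character_, stack_id = "stack") {
  n_f <- nrow(fibers)
  n_syn <- sum(fibers$status == "synaptic")
  n_con <- sum(fibers$status == "nonsynaptic_contact")
  n_ret <- sum(fibers$status == "nonsynaptic_retracted")
  n_non <- n_con + n_ret
  stopifnot(n_syn + n_non == n_f)
  mult <- integer(3)
  if (nrow(synapses) > 0) {
    tb <- table(factor(pmin(synapses$n_ribbons, 3), levels = 1:3))
    mult <- as.integer(tb)
  }
  stopifnot(sum(mult) == nrow(synapses))

  pct <- list(
    nonsynaptic = if (n_f > 0) fraction_report(n_non, n_f) else NA,
    contact_among_nonsynaptic = if (n_non > 0)
      fraction_report(n_con, n_non) else NA,
    multi_ribbon = if (nrow(synapses) > 0)
      fraction_report(sum(synapses$n_ribbons > 1), nrow(synapses)) else NA
  )
  mean_or_na <- function(x) {
    x <- x[is.finite(x)]
    if (length(x)) mean(x) else NA_real_
  }
  retr_d <- fibers$distance_to_nearest_ihc_nm[
    fibers$status == "nonsynaptic_retracted"]
  side_block <- NULL
  if ("side" %in% names(fibers) && any(!is.na(fibers$side))) {
    side_block <- lapply(split(fibers, fibers$side), function(fs) {
      list(
        n_fibers = nrow(fs),
        n_synaptic = sum(fs$status == "synaptic"),
        mean_peak_area_nm2 = mean_or_na(fs$peak_mean_area_nm2),
        mean_preterminal_area_nm2 =
          mean_or_na(fs$preterminal_mean_area_nm2),
        mean_efferent_total_um2 = mean_or_na(fs$efferent_total_area_um2),
        mean_total_ribbon_volume_nm3 =
          mean_or_na(fs$total_ribbon_volume_nm3)
      )
    })
  }
  rep <- list(
    stack_id = stack_id, group = group, span_um = span_um,
    counts = list(
      fibers = n_f, synaptic = n_syn, nonsynaptic = n_non,
      nonsynaptic_contact = n_con, nonsynaptic_retracted = n_ret,
      synapses = nrow(synapses),
      multiplicity = list(single = mult[1], double = mult[2],
                          triple = mult[3]),
      orphan_ribbons = length(orphan_ids)
    ),
    percentages = pct,
    synapses_per_20um = if (span_um > 0)
      nrow(synapses) * 20 / span_um else NA,
    fibers_per_20um = if (span_um > 0) n_f * 20 / span_um else NA,
    mean_retraction_distance_um = mean_or_na(retr_d) / 1000,
    mitochondria = list(
      mean_peak_area_nm2 = mean_or_na(fibers$peak_mean_area_nm2),
      mean_terminal_area_nm2 = mean_or_na(fibers$terminal_mean_area_nm2),
      mean_preterminal_area_nm2 =
        mean_or_na(fibers$preterminal_mean_area_nm2),
      mean_profiles_per_slice =
        mean_or_na(fibers$mito_profiles_per_slice),
      mean_profile_area_nm2 =
        mean_or_na(fibers$mito_mean_profile_area_nm2)
    ),
    efferent = list(
      mean_plaques_per_fiber = mean_or_na(fibers$efferent_plaque_count),
      mean_plaque_area_um2 = if ("efferent_total_area_um2" %in%
                                   names(fibers) &&
                                 sum(fibers$efferent_plaque_count) > 0)
        sum(fibers$efferent_total_area_um2) /
          sum(fibers$efferent_plaque_count) else NA,
      mean_total_area_um2 = mean_or_na(fibers$efferent_total_area_um2)
    ),
    by_side = side_block
  )
  structure(rep, class = "stack_report")
}

#' @export
print.stack_report <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("<stack_report> %s (%s): %d fibers, %d synapses\n",
              x$stack_id, x$group, ct$fibers, ct$synapses))
  cat(sprintf("  synaptic %d | contact %d | retracted %d (non-syn %s%%)\n",
              ct$synaptic, ct$nonsynaptic_contact,
              ct$nonsynaptic_retracted, x$percentages$nonsynaptic))
  cat(sprintf("  multiplicity 1/2/3: %d/%d/%d, orphans %d\n",
              ct$multiplicity$single, ct$multiplicity$double,
              ct$multiplicity$triple, ct$orphan_ribbons))
  invisible(x)
}

#' Cross-stack group statistics
#'
#' Compares a per-fiber metric across condition groups (Kruskal-Wallis +
#' Dunn, or Mann-Whitney for two groups) and reports the percent change of
#' each exposed group against the reference.
#'
#' @param fiber_tables Named list (by group) of per-fiber tables from
#'   [analyze_stack()].
#' @param metric Column to compare.
#' @param reference Reference group name (default "control").
#' @return list with the [compare_groups()] result and integer percent
#'   changes; groups whose column is all-NA are dropped with a notice.
#' @export
group_statistics <- function(fiber_tables, metric,
                             reference = "control") {
  vals <- lapply(fiber_tables, function(tb) {
    v <- tb[[metric]]
    v[is.finite(v)]
  })
  vals <- vals[vapply(vals, length, integer(1)) >= 2]
  if (length(vals) < 2) {
    return(list(stat = NULL, percent_change = NULL,
                note = "fewer than two groups with data; comparison skipped"))
  }
  stat <- compare_groups(vals)
  pc <- NULL
  if (reference %in% names(vals)) {
    ref <- mean(vals[[reference]])
    others <- setdiff(names(vals), reference)
    if (is.finite(ref) && ref > 0) {
      pc <- vapply(others, function(gp) percent_change(ref,
                                                       mean(vals[[gp]])),
                   integer(1))
    }
  }
  list(stat = stat, percent_change = pc, metric = metric)
}
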