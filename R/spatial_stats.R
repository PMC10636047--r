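# Modiolar/pillar spatial classification and nonparametric group
# statistics (Kruskal-Wallis with Dunn's multiple comparisons for more
# than two groups, Mann-Whitney for two), plus the percentage conventions
# used in stack reports.

#' Modiolar/pillar dividing plane
#'
#' @param point A point on the plane, physical nm `(x, y, z)`.
#' @param normal Plane normal, oriented toward the modiolar side
#'   (normalized internally).
#' @return A `dividing_plane` object.
#' @export
dividing_plane <- function(point, normal) {
  structure(list(point = as.numeric(point),
                 normal = unitize(as.numeric(normal), "plane normal")),
            class = "dividing_plane")
}

#' Assign the modiolar/pillar side of a location
#'
#' Modiolar iff the signed distance to the plane is >= 0; a location
#' exactly on the plane is modiolar by convention (logged). For a fiber,
#' the location should be its synaptic centroid, or its closest IHC
#' approach when non-synaptic.
#'
#' @param location Physical coordinate `(x, y, z)` in nm, or a matrix with
#'   one row per location.
#' @param plane A [dividing_plane()].
#' @return Character vector, "modiolar" or "pillar".
#' @export
assign_side <- function(location, plane) {
  stopifnot(inherits(plane, "dividing_plane"))
  loc <- rbind(location)
  sd <- sweep(loc, 2, plane$point) %*% plane$normal
  if (any(abs(sd) < 1e-9)) {
    message(sum(abs(sd) < 1e-9),
            " location(s) exactly on the dividing plane; assigned",
            " modiolar by convention")
  }
  unname(ifelse(sd >= 0, "modiolar", "pillar")[, 1])
}

#' Per-IHC modiolar/pillar assignment
#'
#' As [assign_side()], but each location is judged against the dividing
#' plane of its own IHC (IHC synaptic poles are often staggered, so the
#' single-plane and per-IHC definitions can disagree on borderline
#' fibers).
#'
#' @param location Matrix of physical coordinates (one row each).
#' @param ihc_id IHC id per location.
#' @param ihc_planes Named list of [dividing_plane()] objects, one per
#'   IHC id.
#' @return Character vector with NA (and a warning) for locations whose
#'   IHC has no plane.
#' @export
assign_side_per_ihc <- function(location, ihc_id, ihc_planes) {
  loc <- rbind(location)
  stopifnot(nrow(loc) == length(ihc_id))
  out <- rep(NA_character_, nrow(loc))
  for (i in seq_len(nrow(loc))) {
    key <- as.character(ihc_id[i])
    if (is.na(ihc_id[i]) || is.null(ihc_planes[[key]])) next
    out[i] <- assign_side(loc[i, , drop = FALSE], ihc_planes[[key]])
  }
  if (anyNA(out)) {
    warning(sum(is.na(out)), " location(s) without an associated IHC",
            " plane; excluded from side-stratified statistics")
  }
  out
}

# Dunn's multiple-comparisons test on mid-ranks with tie correction,
# Bonferroni-adjusted over the pairwise comparisons.
dunn_test <- function(values, groups) {
  g <- factor(groups)
  r <- rank(values)
  N <- length(values)
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  k <- length(lv)
  m <- k * (k - 1) / 2
  out <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    z <- (rbar[i] - rbar[j]) / se
    out[[length(out) + 1]] <- data.frame(
      group1 = lv[i], group2 = lv[j], z = as.numeric(z),
      p_unadj = 2 * pnorm(-abs(as.numeric(z))),
      p_adj = min(1, 2 * pnorm(-abs(as.numeric(z))) * m)
    )
  }
  do.call(rbind, out)
}

#' Nonparametric group comparison
#'
#' Two groups: two-sided Mann-Whitney (Wilcoxon rank-sum; exact for small
#' tie-free samples, normal approximation with continuity and tie
#' correction otherwise). More than two: Kruskal-Wallis followed by
#' Dunn's multiple-comparisons test (Bonferroni-adjusted pairwise
#' p-values). The 0.05 significance threshold is reported, never
#' enforced.
#'
#' @param values_by_group Named list of numeric vectors.
#' @param mode "auto" (default; picks by group count), "kw_dunn" or
#'   "mann_whitney".
#' @return A `stat_result`: list with `test`, `statistic`, `p_value`,
#'   `pairwise` (Dunn table or NULL), `n`, `means`, `alpha`.
#' @export
compare_groups <- function(values_by_group,
                           mode = c("auto", "kw_dunn", "mann_whitney")) {
  mode <- match.arg(mode)
  k <- length(values_by_group)
  if (k < 2) stop("need at least 2 groups")
  if (is.null(names(values_by_group))) {
    names(values_by_group) <- paste0("group", seq_len(k))
  }
  ns <- vapply(values_by_group, length, integer(1))
  if (any(ns < 2)) {
    stop("group '", names(values_by_group)[which(ns < 2)[1]],
         "' has fewer than 2 values")
  }
  if (mode == "auto") mode <- if (k == 2) "mann_whitney" else "kw_dunn"
  if (mode == "mann_whitney") {
    if (k != 2) stop("mann_whitney mode requires exactly 2 groups")
    ht <- suppressWarnings(
      wilcox.test(values_by_group[[1]], values_by_group[[2]],
                  alternative = "two.sided", correct = TRUE))
    res <- list(test = "mann_whitney", statistic = unname(ht$statistic),
                p_value = ht$p.value, pairwise = NULL)
  } else {
    values <- unlist(values_by_group, use.names = FALSE)
    groups <- rep(names(values_by_group), ns)
    ht <- kruskal.test(values, factor(groups))
    res <- list(test = "kruskal_wallis_dunn",
                statistic = unname(ht$statistic), p_value = ht$p.value,
                pairwise = dunn_test(values, groups))
  }
  res$n <- ns
  res$means <- vapply(values_by_group, mean, numeric(1))
  res$alpha <- 0.05
  structure(res, class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g\n", x$test,
              x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Percent change between two means
#'
#' `100 * (exposed - reference) / reference`, half-up rounded to the
#' nearest integer with the sign preserved.
#'
#' @param reference_mean,exposed_mean Means (reference must be > 0).
#' @return Integer percent.
#' @export
percent_change <- function(reference_mean, exposed_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0) {
    stop("reference mean must be positive")
  }
  as.integer(round_half_up(100 * (exposed_mean - reference_mean) /
                             reference_mean))
}

#' Percentage of a count fraction
#'
#' `100 * numerator / denominator`, half-up rounded to the nearest
#' integer.
#'
#' @param numerator,denominator Counts, `0 <= numerator <= denominator`,
#'   denominator > 0.
#' @return Integer percent.
#' @export
fraction_report <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator < 0 || numerator > denominator) {
    stop("numerator must lie in [0, denominator]")
  }
  as.integer(round_half_up(100 * numerator / denominator))
}
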