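# Efferent (lateral olivocochlear) synapse scoring.
#
# A contact between an efferent terminal and an ANF is synaptic only when
# four criteria hold: (1) direct membrane apposition, (2) a cluster of at
# least five vesicles within two vesicle-diameters of the efferent
# membrane, (3) membrane thickening / intermembranous darkening at the
# apposition, and (4) criteria 1-3 sustained over at least five
# consecutive slices.  Apposition and thickening are grayscale judgements
# and therefore arrive as annotation flags; vesicles arrive as point
# coordinates and the membrane as a per-slice trace polyline.  Plaque
# surface area is estimated as the serial-trace length times the slice
# thickness (a ruled surface between sections).

#' Efferent synapse criteria
#'
#' @param min_vesicles Minimum vesicles near the membrane (criterion 2;
#'   default 5).
#' @param vesicle_proximity Distance limit in vesicle diameters (default
#'   2).
#' @param require_apposition,require_thickening Toggle criteria 1 and 3.
#' @param min_consecutive_slices Minimum qualifying run length (criterion
#'   4; default 5).
#' @param vesicle_diameter_nm Vesicle diameter (default 35 nm; the
#'   proximity limit is `vesicle_proximity * vesicle_diameter_nm`).
#' @return An `efferent_criteria` object.
#' @export
efferent_criteria <- function(min_vesicles = 5, vesicle_proximity = 2,
                              require_apposition = TRUE,
                              require_thickening = TRUE,
                              min_consecutive_slices = 5,
                              vesicle_diameter_nm = 35) {
  stopifnot(min_vesicles >= 1, vesicle_proximity > 0,
            min_consecutive_slices >= 1, vesicle_diameter_nm > 0)
  structure(
    list(min_vesicles = as.integer(min_vesicles),
         vesicle_proximity = vesicle_proximity,
         require_apposition = isTRUE(require_apposition),
         require_thickening = isTRUE(require_thickening),
         min_consecutive_slices = as.integer(min_consecutive_slices),
         vesicle_diameter_nm = vesicle_diameter_nm),
    class = "efferent_criteria"
  )
}

# "r,c;r,c;..." -> matrix of (row, col) in voxel units (possibly
# fractional: annotation vertices need not sit on voxel centers)
parse_points <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(numeric(0), 0, 2))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.numeric))
  colnames(m) <- c("row", "col")
  m
}

# polyline length in nm given (row, col) vertices in voxel units
polyline_length_nm <- function(poly, geometry) {
  if (nrow(poly) < 2) return(0)
  dr <- diff(poly[, 1]) * geometry$dy
  dc <- diff(poly[, 2]) * geometry$dx
  sum(sqrt(dr^2 + dc^2))
}

# minimum distance (nm) from each point to a polyline
points_to_polyline_nm <- function(pts, poly, geometry) {
  if (nrow(pts) == 0) return(numeric(0))
  P <- cbind(pts[, 2] * geometry$dx, pts[, 1] * geometry$dy)
  V <- cbind(poly[, 2] * geometry$dx, poly[, 1] * geometry$dy)
  d <- rep(Inf, nrow(P))
  if (nrow(V) == 1) {
    return(sqrt((P[, 1] - V[1, 1])^2 + (P[, 2] - V[1, 2])^2))
  }
  for (k in seq_len(nrow(V) - 1)) {
    a <- V[k, ]; b <- V[k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(P)) else
      pmin(1, pmax(0, ((P[, 1] - a[1]) * ab[1] +
                         (P[, 2] - a[2]) * ab[2]) / len2))
    dx <- P[, 1] - (a[1] + t * ab[1])
    dy <- P[, 2] - (a[2] + t * ab[2])
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  d
}

#' Plaque surface area from serial membrane traces
#'
#' Area = sum over slices of (in-plane trace length x slice thickness),
#' i.e. a ruled surface between consecutive sections, converted to um^2.
#'
#' @param traces List of polyline matrices (columns row, col in voxel
#'   units, possibly fractional), one per slice.
#' @param geometry A [voxel_geometry()].
#' @return Area in um^2 (0 with a warning for empty input).
#' @export
plaque_area <- function(traces, geometry) {
  if (length(traces) == 0) {
    warning("no traces supplied; plaque area is 0")
    return(0)
  }
  lens <- vapply(traces, polyline_length_nm, numeric(1),
                 geometry = geometry)
  sum(lens * geometry$dz) / 1e6
}

#' Read an efferent contact annotation table
#'
#' One row per (contact_id, slice_index) with logical `apposition` and
#' `thickening` flags, a semicolon-separated `vesicle_points` field and a
#' semicolon-separated `trace` polyline ("row,col;row,col;..." in voxel
#' units).
#'
#' @param path CSV path.
#' @return The validated data.frame.
#' @export
read_efferent_contacts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("contact_id", "fiber_id", "slice_index", "apposition",
            "thickening", "vesicle_points", "trace")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("efferent contact table lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  df$apposition <- as.logical(df$apposition)
  df$thickening <- as.logical(df$thickening)
  df
}

#' Score one efferent contact against the synapse criteria
#'
#' A slice qualifies when (criterion 1) apposition is annotated, (2) at
#' least `min_vesicles` vesicle centers lie within
#' `vesicle_proximity * vesicle_diameter_nm` of the membrane trace and
#' (3) thickening is annotated; maximal runs of at least
#' `min_consecutive_slices` qualifying slices become plaques (criterion
#' 4). Overlapping runs are merged: a slice belongs to at most one plaque
#' of a contact.
#'
#' @param contact Data.frame rows of one contact (see
#'   [read_efferent_contacts()]).
#' @param criteria An [efferent_criteria()].
#' @param geometry A [voxel_geometry()].
#' @return data.frame of plaques: contact_id, fiber_id, efferent_id,
#'   slice_start, slice_end, n_slices, surface_area_um2.
#' @export
score_contact <- function(contact, criteria, geometry) {
  stopifnot(inherits(criteria, "efferent_criteria"))
  contact <- contact[order(contact$slice_index), , drop = FALSE]
  limit <- criteria$vesicle_proximity * criteria$vesicle_diameter_nm
  n <- nrow(contact)
  ok <- rep(TRUE, n)
  if (criteria$require_apposition) {
    ok <- ok & !is.na(contact$apposition) & contact$apposition
  }
  if (criteria$require_thickening) {
    ok <- ok & !is.na(contact$thickening) & contact$thickening
  }
  traces <- lapply(contact$trace, parse_points)
  ok <- ok & vapply(traces, nrow, integer(1)) > 0
  for (i in which(ok)) {
    ves <- parse_points(contact$vesicle_points[i])
    ok[i] <- sum(points_to_polyline_nm(ves, traces[[i]], geometry) <=
                   limit) >= criteria$min_vesicles
  }
  runs <- consecutive_runs(contact$slice_index[ok])
  runs <- runs[runs$length >= criteria$min_consecutive_slices, ,
               drop = FALSE]
  if (nrow(runs) == 0) {
    return(data.frame(contact_id = integer(), fiber_id = integer(),
                      efferent_id = integer(), slice_start = integer(),
                      slice_end = integer(), n_slices = integer(),
                      surface_area_um2 = numeric()))
  }
  do.call(rbind, lapply(seq_len(nrow(runs)), function(k) {
    sel <- contact$slice_index >= runs$start[k] &
      contact$slice_index <= runs$end[k] & ok
    data.frame(
      contact_id = contact$contact_id[1],
      fiber_id = contact$fiber_id[1],
      efferent_id = contact$efferent_id[1] %||% NA_integer_,
      slice_start = runs$start[k], slice_end = runs$end[k],
      n_slices = runs$length[k],
      surface_area_um2 = plaque_area(traces[sel], geometry)
    )
  }))
}

#' Score all efferent contacts of a stack
#'
#' @param contacts Annotation table (see [read_efferent_contacts()]).
#' @param criteria An [efferent_criteria()].
#' @param geometry A [voxel_geometry()].
#' @return data.frame of plaques with a `plaque_id` column.
#' @export
score_contacts <- function(contacts, criteria, geometry) {
  out <- do.call(rbind, lapply(split(contacts, contacts$contact_id),
                               score_contact, criteria = criteria,
                               geometry = geometry))
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(contact_id = integer(), fiber_id = integer(),
                      efferent_id = integer(), slice_start = integer(),
                      slice_end = integer(), n_slices = integer(),
                      surface_area_um2 = numeric())
  }
  rownames(out) <- NULL
  out$plaque_id <- seq_len(nrow(out))
  out
}

#' Per-fiber efferent innervation summary
#'
#' @param fiber_ids All fiber ids of the stack (fibers without plaques are
#'   reported with zeros).
#' @param plaques Plaque table from [score_contacts()].
#' @return data.frame: fiber_id, plaque_count, total_area_um2,
#'   mean_plaque_area_um2 (NA when the fiber has no plaques).
#' @export
summarize_efferent <- function(fiber_ids, plaques) {
  bad <- setdiff(plaques$fiber_id, fiber_ids)
  if (length(bad) > 0) {
    stop("plaques refer to unknown fiber(s): ", paste(bad, collapse = ", "))
  }
  do.call(rbind, lapply(fiber_ids, function(f) {
    p <- plaques[plaques$fiber_id == f, , drop = FALSE]
    data.frame(
      fiber_id = f,
      plaque_count = nrow(p),
      total_area_um2 = sum(p$surface_area_um2),
      mean_plaque_area_um2 = if (nrow(p) > 0)
        mean(p$surface_area_um2) else NA_real_
    )
  }))
}
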