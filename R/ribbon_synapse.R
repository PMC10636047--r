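# Afferent synapse analysis: presynaptic ribbon reconstruction (volume,
# principal-axis length, multiplicity, hollow cores), ribbon-centric
# virtual re-sectioning, fiber synaptic classification, contact detection,
# distance-to-IHC and orphan-ribbon detection.

#' Reconstruct presynaptic ribbons
#'
#' One record per 3D connected component (26-connectivity) of the
#' RIBBON-class mask. Volume is the voxel count times the voxel volume;
#' length is the extent of the voxel centers along the first principal
#' axis of their physical coordinates; a ribbon is hollow when it encloses
#' a background cavity (3D hole under 6-connected background flood).
#'
#' @param volume A [label_volume()].
#' @return data.frame with ribbon_id, label_id (majority label),
#'   n_voxels, volume_nm3, length_nm, hollow_core, centroid_row/col/slice
#'   (0-based voxel units). The voxel coordinate matrices are attached as
#'   attribute `"coords"` (list indexed by ribbon_id).
#' @export
reconstruct_ribbons <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  g <- volume$geometry
  d <- dim(volume$labels)
  rib_ids <- labels_of_class(volume, "RIBBON")
  empty <- data.frame(ribbon_id = integer(), label_id = integer(),
                      n_voxels = integer(), volume_nm3 = numeric(),
                      length_nm = numeric(), hollow_core = logical(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      centroid_slice = numeric())
  if (length(rib_ids) == 0) {
    attr(empty, "coords") <- list()
    return(empty)
  }
  # group labels whose padded bounding boxes intersect, so touching labels
  # merge into one instance without scanning the whole lattice at once
  sm <- volume$summary[volume$summary$label %in% rib_ids, , drop = FALSE]
  nlab <- nrow(sm)
  grp <- seq_len(nlab)
  if (nlab > 1) {
    for (i in 1:(nlab - 1)) for (j in (i + 1):nlab) {
      if (sm$rmin[j] <= sm$rmax[i] + 1 && sm$rmax[j] >= sm$rmin[i] - 1 &&
          sm$cmin[j] <= sm$cmax[i] + 1 && sm$cmax[j] >= sm$cmin[i] - 1 &&
          sm$smin[j] <= sm$smax[i] + 1 && sm$smax[j] >= sm$smin[i] - 1) {
        grp[grp == grp[j]] <- grp[i]
      }
    }
  }
  out <- list(); coords_list <- list()
  rid <- 0
  for (gk in unique(grp)) {
    rows <- sm[grp == gk, , drop = FALSE]
    bb <- as.integer(c(min(rows$rmin), max(rows$rmax), min(rows$cmin),
                       max(rows$cmax), min(rows$smin), max(rows$smax)))
    cc <- cpp_cc3d(volume$labels, d[1], d[2], d[3],
                   as.integer(rows$label), bb, 26L)
    comp <- cc$comp
    W <- dim(comp)[1]; H <- dim(comp)[2]; D <- dim(comp)[3]
    for (k in seq_len(cc$n)) {
      idx <- which(comp == k)
      co <- arrayInd(idx, dim(comp)) - 1L
      co[, 1] <- co[, 1] + bb[1]
      co[, 2] <- co[, 2] + bb[3]
      co[, 3] <- co[, 3] + bb[5]
      labs <- volume$labels[cbind(co[, 1] + 1L, co[, 2] + 1L,
                                  co[, 3] + 1L)]
      phys <- vox_to_nm(co, g)
      len <- 0
      if (nrow(co) > 1) {
        ctr <- sweep(phys, 2, colMeans(phys))
        pc1 <- svd(ctr, nu = 0, nv = 1)$v[, 1]
        proj <- ctr %*% pc1
        len <- max(proj) - min(proj)
      }
      # hollow core: fill enclosed 3D background within a padded crop
      rng <- apply(co, 2, range)
      Wm <- rng[2, 1] - rng[1, 1] + 3
      Hm <- rng[2, 2] - rng[1, 2] + 3
      Dm <- rng[2, 3] - rng[1, 3] + 3
      mask <- array(0L, dim = c(Wm, Hm, Dm))
      mask[cbind(co[, 1] - rng[1, 1] + 2L, co[, 2] - rng[1, 2] + 2L,
                 co[, 3] - rng[1, 3] + 2L)] <- 1L
      filled <- cpp_fill_holes3d(mask, Wm, Hm, Dm)
      rid <- rid + 1
      out[[rid]] <- data.frame(
        ribbon_id = rid,
        label_id = as.integer(names(which.max(table(labs)))),
        n_voxels = nrow(co),
        volume_nm3 = nrow(co) * voxel_volume(g),
        length_nm = len,
        hollow_core = sum(filled) > sum(mask),
        centroid_row = mean(co[, 1]),
        centroid_col = mean(co[, 2]),
        centroid_slice = mean(co[, 3])
      )
      coords_list[[rid]] <- co
    }
  }
  res <- do.call(rbind, out)
  attr(res, "coords") <- coords_list
  res
}

# ANF voxels face-adjacent to an IHC (the apposition zone) within a
# physical-radius crop of a voxel coordinate, with the minimum distance
# per fiber label.  Linking against apposed voxels (rather than any fiber
# voxel) implements pairing at the shared fiber-IHC apposition and makes
# ribbon assignment robust to tightly packed neighbouring terminals.
apposed_fibers_near <- function(volume, center_vox, radius_nm) {
  g <- volume$geometry
  d <- dim(volume$labels)
  rr <- ceiling(radius_nm / g$dy) + 1L
  rc <- ceiling(radius_nm / g$dx) + 1L
  rs <- ceiling(radius_nm / g$dz) + 1L
  r0 <- max(0, floor(center_vox[1] - rr))
  r1 <- min(d[1] - 1, ceiling(center_vox[1] + rr))
  c0 <- max(0, floor(center_vox[2] - rc))
  c1 <- min(d[2] - 1, ceiling(center_vox[2] + rc))
  s0 <- max(0, floor(center_vox[3] - rs))
  s1 <- min(d[3] - 1, ceiling(center_vox[3] + rs))
  sub <- volume$labels[(r0:r1) + 1, (c0:c1) + 1, (s0:s1) + 1,
                       drop = FALSE]
  anf_ids <- volume$table$label[volume$table$class == "ANF"]
  ihc_ids <- volume$table$label[volume$table$class == "IHC"]
  anf <- array(sub %in% anf_ids, dim = dim(sub))
  ihc <- array(sub %in% ihc_ids, dim = dim(sub))
  if (!any(anf) || !any(ihc)) {
    return(data.frame(label = integer(), dist_nm = numeric()))
  }
  dd <- dim(sub)
  apposed <- array(FALSE, dim = dd)
  sh <- function(a, ax, by) {
    out <- array(FALSE, dim = dd)
    idx_src <- lapply(dd, seq_len)
    idx_dst <- idx_src
    if (by > 0) {
      idx_dst[[ax]] <- (1 + by):dd[ax]; idx_src[[ax]] <- 1:(dd[ax] - by)
    } else {
      idx_dst[[ax]] <- 1:(dd[ax] + by); idx_src[[ax]] <- (1 - by):dd[ax]
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    apposed <- apposed | (anf & sh(ihc, ax, by))
  }
  hit <- which(apposed)
  if (length(hit) == 0) {
    return(data.frame(label = integer(), dist_nm = numeric()))
  }
  co <- arrayInd(hit, dd) - 1L
  dist <- sqrt(((co[, 1] + r0 - center_vox[1]) * g$dy)^2 +
               ((co[, 2] + c0 - center_vox[2]) * g$dx)^2 +
               ((co[, 3] + s0 - center_vox[3]) * g$dz)^2)
  lab <- sub[hit]
  keep <- dist <= radius_nm
  df <- data.frame(label = lab[keep], dist_nm = dist[keep])
  df <- df[order(df$dist_nm), , drop = FALSE]
  df[!duplicated(df$label), , drop = FALSE]
}

# labels present within a physical-radius crop around a voxel coordinate,
# with the minimum anisotropic center-to-center distance per label
labels_near <- function(volume, center_vox, radius_nm, classes) {
  g <- volume$geometry
  d <- dim(volume$labels)
  rr <- ceiling(radius_nm / g$dy); rc <- ceiling(radius_nm / g$dx)
  rs <- ceiling(radius_nm / g$dz)
  r0 <- max(0, floor(center_vox[1] - rr)); r1 <- min(d[1] - 1,
                                                    ceiling(center_vox[1] + rr))
  c0 <- max(0, floor(center_vox[2] - rc)); c1 <- min(d[2] - 1,
                                                    ceiling(center_vox[2] + rc))
  s0 <- max(0, floor(center_vox[3] - rs)); s1 <- min(d[3] - 1,
                                                    ceiling(center_vox[3] + rs))
  ids <- volume$table$label[volume$table$class %in% classes]
  sub <- volume$labels[(r0:r1) + 1, (c0:c1) + 1, (s0:s1) + 1, drop = FALSE]
  hit <- which(array(sub %in% ids, dim = dim(sub)))
  if (length(hit) == 0) {
    return(data.frame(label = integer(), dist_nm = numeric(),
                      row = numeric(), col = numeric(), slice = numeric()))
  }
  co <- arrayInd(hit, dim(sub)) - 1L
  co[, 1] <- co[, 1] + r0; co[, 2] <- co[, 2] + c0; co[, 3] <- co[, 3] + s0
  dist <- sqrt(((co[, 1] - center_vox[1]) * g$dy)^2 +
               ((co[, 2] - center_vox[2]) * g$dx)^2 +
               ((co[, 3] - center_vox[3]) * g$dz)^2)
  lab <- sub[hit]
  keep <- dist <= radius_nm
  if (!any(keep)) {
    return(data.frame(label = integer(), dist_nm = numeric(),
                      row = numeric(), col = numeric(), slice = numeric()))
  }
  df <- data.frame(label = lab[keep], dist_nm = dist[keep],
                   row = co[keep, 1], col = co[keep, 2],
                   slice = co[keep, 3])
  df <- df[order(df$dist_nm), ]
  df[!duplicated(df$label), , drop = FALSE]
}

#' Group ribbons into afferent synapses
#'
#' Each ribbon is paired to the nearest apposed fiber within
#' `pairing_radius` of its centroid (deterministic tie-break toward the
#' lower fiber id, logged) and to the nearest IHC; ribbons sharing a
#' fiber-IHC apposition form one synapse. Ribbons with no fiber in range
#' are left unpaired (see [detect_orphans()]). When PSD annotations are
#' provided, each synapse records whether a post-synaptic density was
#' annotated for its fiber; otherwise ribbon apposition alone suffices and
#' `psd_present` is NA.
#'
#' @param volume A [label_volume()].
#' @param ribbons Result of [reconstruct_ribbons()].
#' @param psd Optional PSD annotation data.frame with columns fiber_id,
#'   ihc_id, psd_present.
#' @param pairing_radius Pairing radius in nm (default 200).
#' @return list with `synapses` (data.frame: synapse_id, fiber_id, ihc_id,
#'   n_ribbons, total_volume_nm3, total_length_nm, psd_present),
#'   `ribbon_synapse` (ribbon_id -> synapse_id map) and `unpaired`
#'   (ribbon ids with no fiber in range).
#' @export
link_synapses <- function(volume, ribbons, psd = NULL,
                          pairing_radius = 200) {
  stopifnot(pairing_radius > 0)
  n <- nrow(ribbons)
  fiber_of <- rep(NA_integer_, n)
  ihc_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ctr <- c(ribbons$centroid_row[i], ribbons$centroid_col[i],
             ribbons$centroid_slice[i])
    near_f <- if (any(volume$table$class == "IHC")) {
      apposed_fibers_near(volume, ctr, pairing_radius)
    } else {
      # no IHC in the volume (reduced fixtures): pair to any fiber
      labels_near(volume, ctr, pairing_radius, "ANF")
    }
    if (nrow(near_f) > 0) {
      best <- min(near_f$dist_nm)
      cand <- near_f$label[near_f$dist_nm <= best + 1e-9]
      if (length(cand) > 1) {
        message("ribbon ", ribbons$ribbon_id[i],
                " equidistant to fibers ",
                paste(sort(cand), collapse = ", "),
                "; tie broken toward the lower id")
      }
      fiber_of[i] <- min(cand)
    }
    near_i <- labels_near(volume, ctr, pairing_radius + 400, "IHC")
    if (nrow(near_i) > 0) ihc_of[i] <- near_i$label[1]
  }
  paired <- which(!is.na(fiber_of))
  key <- paste(fiber_of[paired], ihc_of[paired])
  syn_id <- match(key, unique(key))
  synapses <- do.call(rbind, lapply(seq_along(unique(key)), function(k) {
    sel <- paired[syn_id == k]
    nrib <- length(sel)
    if (nrib > 3) {
      warning("synapse with ", nrib,
              " ribbons (more than the observed maximum of 3)")
    }
    fid <- fiber_of[sel[1]]
    iid <- ihc_of[sel[1]]
    psd_flag <- if (is.null(psd)) NA else
      any(psd$fiber_id == fid & (psd$psd_present %||% TRUE))
    data.frame(
      synapse_id = k, fiber_id = fid, ihc_id = iid, n_ribbons = nrib,
      total_volume_nm3 = sum(ribbons$volume_nm3[sel]),
      total_length_nm = sum(ribbons$length_nm[sel]),
      psd_present = psd_flag
    )
  }))
  if (is.null(synapses)) {
    synapses <- data.frame(synapse_id = integer(), fiber_id = integer(),
                           ihc_id = integer(), n_ribbons = integer(),
                           total_volume_nm3 = numeric(),
                           total_length_nm = numeric(),
                           psd_present = logical())
  }
  rs <- data.frame(ribbon_id = ribbons$ribbon_id[paired],
                   synapse_id = syn_id,
                   fiber_id = fiber_of[paired])
  list(synapses = synapses, ribbon_synapse = rs,
       unpaired = ribbons$ribbon_id[is.na(fiber_of)])
}

# per-(fiber, ihc) apposition runs from the face-adjacency table
apposition_runs <- function(volume) {
  d <- dim(volume$labels)
  tab <- volume$table
  maxlab <- max(tab$label)
  code <- integer(maxlab + 1)
  code[tab$label[tab$class == "ANF"] + 1L] <- 1L
  code[tab$label[tab$class == "IHC"] + 1L] <- 2L
  adj <- cpp_pair_adjacency(volume$labels, d[1], d[2], d[3], code, 1L, 2L)
  adj
}

#' Classify fibers as synaptic, contact or retracted
#'
#' A fiber is synaptic when it owns at least one synapse (with an
#' annotated PSD when PSD annotations were provided to
#' [link_synapses()]); otherwise it is a non-synaptic contact when its
#' membrane is face-apposed to an IHC over at least `contact_min_run`
#' consecutive slices, and non-synaptic retracted otherwise. The distance
#' to the nearest IHC is the minimum surface-to-surface distance from the
#' fiber's terminal segment (distalmost `terminal_um` micrometres of
#' slices) and is 0 for contact fibers by definition.
#'
#' @param volume A [label_volume()].
#' @param synapses The `synapses` data.frame from [link_synapses()].
#' @param contact_min_run Minimum apposed consecutive-slice run (default
#'   5, mirroring the efferent persistence criterion).
#' @param terminal_um Terminal-segment length used for the distance
#'   (default 4 um).
#' @return data.frame: fiber_id, status, distance_to_nearest_ihc_nm,
#'   nearest_ihc, contact_run, near_row/col/slice (fiber-side closest
#'   approach, 0-based).
#' @export
classify_fibers <- function(volume, synapses, contact_min_run = 5,
                            terminal_um = 4) {
  stopifnot(inherits(volume, "label_volume"))
  g <- volume$geometry
  d <- dim(volume$labels)
  fibers <- labels_of_class(volume, "ANF")
  adj <- apposition_runs(volume)
  syn_fibers <- unique(synapses$fiber_id[is.na(synapses$psd_present) |
                                           synapses$psd_present])
  ihcs <- labels_of_class(volume, "IHC")
  ihc_surf <- lapply(ihcs, function(i) {
    cpp_surface_coords(volume$labels, d[1], d[2], d[3], as.integer(i),
                       label_bbox(volume, i))
  })
  names(ihc_surf) <- as.character(ihcs)

  out <- lapply(fibers, function(f) {
    a <- adj[adj$a_label == f, , drop = FALSE]
    best_run <- 0L; run_ihc <- NA_integer_
    run_lo <- NA_integer_; run_hi <- NA_integer_
    for (i in unique(a$b_label)) {
      runs <- consecutive_runs(a$slice[a$b_label == i])
      if (nrow(runs) > 0 && max(runs$length) > best_run) {
        best_run <- max(runs$length)
        run_ihc <- i
        r <- runs[which.max(runs$length), ]
        run_lo <- r$start; run_hi <- r$end
      }
    }
    status <- if (f %in% syn_fibers) "synaptic"
      else if (best_run >= contact_min_run) "nonsynaptic_contact"
      else "nonsynaptic_retracted"

    # surface-to-surface distance is only informative for non-synaptic
    # fibers; for contact fibers restrict to the apposed run (distance ~0,
    # the closest-approach point locates the contact patch)
    dist_nm <- 0; ni_lab <- run_ihc
    near <- c(NA_real_, NA_real_, NA_real_)
    if (status != "synaptic") {
      smax <- volume$summary$smax[volume$summary$label == f]
      smin_t <- max(0, smax - round(terminal_um * 1000 / g$dz) + 1)
      bb <- label_bbox(volume, f)
      bb[5] <- max(bb[5], smin_t)
      if (status == "nonsynaptic_contact") {
        bb[5] <- max(bb[5], run_lo - 2L)
        bb[6] <- min(bb[6], run_hi + 2L)
      }
      fsurf <- cpp_surface_coords(volume$labels, d[1], d[2], d[3],
                                  as.integer(f), bb)
      fsurf <- fsurf[order(-fsurf[, 3]), , drop = FALSE]  # tip first
      dists <- lapply(ihcs, function(i) {
        if (nrow(ihc_surf[[as.character(i)]]) == 0 || nrow(fsurf) == 0)
          return(list(dist = Inf))
        cpp_min_dist(fsurf, ihc_surf[[as.character(i)]], pitch_vec(g))
      })
      dmin <- vapply(dists, function(x) x$dist, numeric(1))
      ni <- which.min(dmin)
      if (is.finite(dmin[ni])) {
        near <- as.numeric(fsurf[dists[[ni]]$i, ])
        ni_lab <- ihcs[ni]
        dist_nm <- if (status == "nonsynaptic_retracted") dmin[ni] else 0
      } else {
        dist_nm <- if (status == "nonsynaptic_retracted") Inf else 0
      }
    }
    data.frame(
      fiber_id = f, status = status,
      distance_to_nearest_ihc_nm = dist_nm,
      nearest_ihc = ni_lab %||% NA_integer_,
      contact_run = best_run,
      near_row = near[1], near_col = near[2], near_slice = near[3]
    )
  })
  do.call(rbind, out)
}

#' Detect orphan ribbons
#'
#' Ribbons at the IHC membrane with no fiber surface within
#' `orphan_radius` of their centroid.
#'
#' @param volume A [label_volume()].
#' @param ribbons Result of [reconstruct_ribbons()].
#' @param orphan_radius Radius in nm (default 500); `Inf` searches the
#'   whole lattice.
#' @return Integer vector of orphan ribbon_ids.
#' @export
detect_orphans <- function(volume, ribbons, orphan_radius = 500) {
  d <- dim(volume$labels)
  anf <- labels_of_class(volume, "ANF")
  if (length(anf) == 0) return(ribbons$ribbon_id)
  r_eff <- if (is.infinite(orphan_radius)) {
    g <- volume$geometry
    sqrt((d[1] * g$dy)^2 + (d[2] * g$dx)^2 + (d[3] * g$dz)^2)
  } else orphan_radius
  orphan <- vapply(seq_len(nrow(ribbons)), function(i) {
    ctr <- c(ribbons$centroid_row[i], ribbons$centroid_col[i],
             ribbons$centroid_slice[i])
    nrow(labels_near(volume, ctr, r_eff, "ANF")) == 0
  }, logical(1))
  ribbons$ribbon_id[orphan]
}

#' Build a ribbon-centric section frame
#'
#' The membrane normal is the normal of a least-squares plane fitted to
#' the IHC surface voxels within `patch_radius` of the ribbon centroid,
#' oriented away from the IHC interior; the ribbon axis is the first
#' principal axis of the ribbon projected onto the membrane plane. A
#' near-spherical ribbon (no dominant axis) falls back to its second
#' principal axis and is flagged.
#'
#' @param volume A [label_volume()].
#' @param ribbons Result of [reconstruct_ribbons()].
#' @param ribbon_id Which ribbon.
#' @param patch_radius Membrane patch radius in nm (default 500).
#' @return A `section_frame`: list with `origin` (physical nm),
#'   `membrane_normal`, `ribbon_axis`, `third_axis`, `degenerate`.
#' @export
build_section_frame <- function(volume, ribbons, ribbon_id,
                                patch_radius = 500) {
  g <- volume$geometry
  d <- dim(volume$labels)
  i <- match(ribbon_id, ribbons$ribbon_id)
  if (is.na(i)) stop("unknown ribbon_id: ", ribbon_id)
  ctr <- c(ribbons$centroid_row[i], ribbons$centroid_col[i],
           ribbons$centroid_slice[i])
  near_i <- labels_near(volume, ctr, patch_radius + 1500, "IHC")
  if (nrow(near_i) == 0) {
    stop("no IHC membrane patch within range of ribbon ", ribbon_id)
  }
  ihc <- near_i$label[1]
  surf <- cpp_surface_coords(volume$labels, d[1], d[2], d[3],
                             as.integer(ihc), label_bbox(volume, ihc))
  phys <- vox_to_nm(surf, g)
  ctr_phys <- vox_to_nm(matrix(ctr, 1), g)[1, ]
  dd <- sqrt(rowSums(sweep(phys, 2, ctr_phys)^2))
  patch <- phys[dd <= patch_radius, , drop = FALSE]
  if (nrow(patch) < 3) {
    patch <- phys[order(dd)[seq_len(min(30, nrow(phys)))], , drop = FALSE]
  }
  pc <- sweep(patch, 2, colMeans(patch))
  normal <- svd(pc, nu = 0, nv = 3)$v[, 3]
  smm <- volume$summary[volume$summary$label == ihc, ]
  ihc_ctr <- vox_to_nm(matrix(c(smm$rmean, smm$cmean, smm$smean), 1),
                       g)[1, ]
  if (sum(normal * (colMeans(patch) - ihc_ctr)) < 0) normal <- -normal

  co <- attr(ribbons, "coords")[[i]]
  rphys <- vox_to_nm(co, g)
  rc <- sweep(rphys, 2, colMeans(rphys))
  sv <- svd(rc, nu = 0, nv = min(3, ncol(rc)))
  degenerate <- FALSE
  axis_raw <- sv$v[, 1]
  if (length(sv$d) >= 2 && sv$d[2] > 0 && sv$d[1] / sv$d[2] < 1.05) {
    degenerate <- TRUE
    axis_raw <- sv$v[, 2]
  }
  axis_proj <- axis_raw - sum(axis_raw * normal) * normal
  if (sqrt(sum(axis_proj^2)) < 1e-6) {
    axis_proj <- c(normal[2], -normal[1], 0)
    degenerate <- TRUE
  }
  axis <- unitize(axis_proj, "ribbon axis")
  third <- unitize(pracma_cross(normal, axis))
  structure(
    list(origin = ctr_phys, membrane_normal = normal, ribbon_axis = axis,
         third_axis = third, degenerate = degenerate),
    class = "section_frame"
  )
}

#' Virtually re-section the volume in a ribbon-centric plane
#'
#' Nearest-neighbour resampling of the label lattice on a plane through
#' the frame origin: `cross` is spanned by (membrane normal, third axis),
#' `longitudinal` by (membrane normal, ribbon axis), `membrane_parallel`
#' by (ribbon axis, third axis) through the middle of the ribbon.
#'
#' @param volume A [label_volume()].
#' @param frame A [build_section_frame()] result.
#' @param plane "cross", "longitudinal" or "membrane_parallel".
#' @param extent_nm Side length of the sampled square (nm).
#' @param step_nm Sampling step (default: the in-plane pitch).
#' @return Integer matrix of labels with attributes `step_nm`, `axes` and
#'   `padded` (TRUE when part of the plane fell outside the lattice).
#' @export
resection <- function(volume, frame,
                      plane = c("cross", "longitudinal",
                                "membrane_parallel"),
                      extent_nm = 1500, step_nm = NULL) {
  plane <- match.arg(plane)
  g <- volume$geometry
  d <- dim(volume$labels)
  step <- step_nm %||% min(g$dx, g$dy)
  ax <- switch(plane,
    cross = list(frame$membrane_normal, frame$third_axis),
    longitudinal = list(frame$membrane_normal, frame$ribbon_axis),
    membrane_parallel = list(frame$ribbon_axis, frame$third_axis))
  u <- seq(-extent_nm / 2, extent_nm / 2, by = step)
  gr <- expand.grid(a = u, b = u)
  pts <- cbind(frame$origin[1] + gr$a * ax[[1]][1] + gr$b * ax[[2]][1],
               frame$origin[2] + gr$a * ax[[1]][2] + gr$b * ax[[2]][2],
               frame$origin[3] + gr$a * ax[[1]][3] + gr$b * ax[[2]][3])
  vox <- cbind(round(pts[, 2] / g$dy), round(pts[, 1] / g$dx),
               round(pts[, 3] / g$dz))
  inside <- vox[, 1] >= 0 & vox[, 1] < d[1] & vox[, 2] >= 0 &
    vox[, 2] < d[2] & vox[, 3] >= 0 & vox[, 3] < d[3]
  vals <- integer(nrow(vox))
  vals[inside] <- volume$labels[vox[inside, , drop = FALSE] + 1L]
  img <- matrix(vals, nrow = length(u))
  attr(img, "step_nm") <- step
  attr(img, "axes") <- ax
  attr(img, "padded") <- any(!inside)
  if (any(!inside)) {
    message("re-section extent exceeds the lattice; padded with background")
  }
  img
}

#' Write a re-section image as TIFF
#'
#' @param img Label matrix from [resection()].
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
save_resection <- function(img, path) {
  if (max(img) > 65535) stop("label ids exceed 16-bit TIFF range")
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "LZW")
  invisible(path)
}
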