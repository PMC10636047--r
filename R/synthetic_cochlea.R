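# Synthetic cochlear phantom generator.
#
# Renders label volumes with the statistical structure of a 20-um FIB-SEM
# stack of the IHC/ANF synaptic region: IHC basal poles as hemispheres at
# the top of the stack, ANFs as curved tubes rising from the habenular face,
# synaptic terminals with 1-3 planted presynaptic ribbons (flattened
# cylinders, optionally hollow), non-synaptic contact and retracted fibers,
# terminal-clustered mitochondria with group- and side-dependent content,
# and efferent contacts with per-slice annotation tables of exactly known
# plaque area.  Classification counts, ribbon multiplicities and plaque
# counts are planted deterministically (largest-remainder apportionment of
# the group fractions), so downstream recovery can be tested for equality.

PHANTOM_LABELS <- list(ihc = 1L, fiber = 101L, ribbon = 3001L,
                       mito = 10001L, efferent = 40001L)

#' Phantom configuration
#'
#' All geometric parameters are physical (nm or um); the lattice defaults to
#' 512 x 512 x 400 voxels at (40, 40, 20) nm — the in-plane pitch is
#' coarsened relative to the 5-nm acquisitions it emulates so that full
#' pipelines run in seconds, while the slice thickness (20 nm) and the
#' ~20-um cochlear span match the real stacks.  Group presets
#' ([group_preset()]) fill in the condition-dependent parameters.
#'
#' @param n_fibers Number of ANFs in the stack.
#' @param group One of "control", "day1", "week1".
#' @param n_ihc Number of inner hair cells (default 2).
#' @param frac_nonsynaptic Fraction of fibers without a synapse.
#' @param frac_contact_among_nonsynaptic Fraction of the non-synaptic fibers
#'   still in intimate IHC contact.
#' @param retraction_distance_mean_um,retraction_distance_sd_um Location and
#'   spread of the retracted-fiber gap distribution; gaps are planted at
#'   deterministic normal quantiles so the planted mean is exact.
#' @param ribbon_multiplicity_probs Probabilities of 1/2/3 ribbons per
#'   synapse (must sum to 1); planted as exact largest-remainder counts.
#' @param ribbon_length_range_nm Range of planted ribbon long-axis lengths.
#' @param ribbon_width_nm,ribbon_thickness_nm Full width/thickness of the
#'   flattened-cylinder ribbons.
#' @param ribbon_hollow_prob Fraction of ribbons with an electron-lucent
#'   core (planted deterministically; a core is only recorded as hollow if
#'   the carved cavity is verifiably enclosed at the phantom resolution).
#' @param mito_density_terminal,mito_density_preterminal Mean total
#'   mitochondrial cross-sectional area per slice (nm^2), named per side
#'   `c(modiolar=, pillar=)`.
#' @param mito_profile_area_nm2 Mean area of a single mitochondrial profile
#'   (nm^2); with densities, determines planted per-slice profile counts.
#' @param efferent_plaque_count_mean Mean efferent plaques per fiber, per
#'   side `c(modiolar=, pillar=)`.
#' @param efferent_plaque_area_mean_um2 Mean plaque surface area (um^2), per
#'   side.
#' @param vesicle_diameter_nm Synaptic vesicle diameter used when planting
#'   vesicle clouds (the efferent criteria are expressed in
#'   vesicle-diameter units, so this cancels in scoring).
#' @param noise Label-boundary jitter applied to fiber radii (voxels).
#' @param orphan_ribbons Number of orphan ribbons to plant at the IHC
#'   membrane with no nearby fiber.
#' @param dims Lattice dimensions c(rows, cols, slices).
#' @param geometry A [voxel_geometry()] for the lattice.
#' @param ihc_radius_um IHC basal-pole radius.
#' @param fiber_radius_nm ANF shaft radius (terminal swelling is ~15%
#'   wider).
#' @param terminal_slices Terminal-region length in slices (defines where
#'   the terminal mitochondrial density applies).
#' @param seed Default RNG seed used by [generate_phantom()].
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(n_fibers = 41,
                           group = c("control", "day1", "week1"),
                           n_ihc = 2,
                           frac_nonsynaptic = 4 / 75,
                           frac_contact_among_nonsynaptic = 0.5,
                           retraction_distance_mean_um = 2.1,
                           retraction_distance_sd_um = 0.45,
                           ribbon_multiplicity_probs = c(69, 2, 0) / 71,
                           ribbon_length_range_nm = c(300, 500),
                           ribbon_width_nm = 220,
                           ribbon_thickness_nm = 160,
                           ribbon_hollow_prob = 0.3,
                           mito_density_terminal =
                             c(modiolar = 0.85, pillar = 1.15) * 81409,
                           mito_density_preterminal =
                             c(modiolar = 0.85, pillar = 1.15) * 54862,
                           mito_profile_area_nm2 = 35395,
                           efferent_plaque_count_mean =
                             c(modiolar = 3.78, pillar = 3.78),
                           efferent_plaque_area_mean_um2 =
                             c(modiolar = 0.9, pillar = 1.1) * 0.496,
                           vesicle_diameter_nm = 35,
                           noise = 0.5,
                           orphan_ribbons = 0,
                           dims = c(512L, 512L, 400L),
                           geometry = voxel_geometry(dx = 40, dy = 40,
                                                     dz = 20),
                           ihc_radius_um = 3.5,
                           fiber_radius_nm = 400,
                           terminal_slices = 200,
                           seed = 1L) {
  group <- match.arg(group)
  cfg <- list(
    n_fibers = as.integer(n_fibers), group = group,
    n_ihc = as.integer(n_ihc),
    frac_nonsynaptic = frac_nonsynaptic,
    frac_contact_among_nonsynaptic = frac_contact_among_nonsynaptic,
    retraction_distance_mean_um = retraction_distance_mean_um,
    retraction_distance_sd_um = retraction_distance_sd_um,
    ribbon_multiplicity_probs = ribbon_multiplicity_probs,
    ribbon_length_range_nm = ribbon_length_range_nm,
    ribbon_width_nm = ribbon_width_nm,
    ribbon_thickness_nm = ribbon_thickness_nm,
    ribbon_hollow_prob = ribbon_hollow_prob,
    mito_density_terminal = mito_density_terminal,
    mito_density_preterminal = mito_density_preterminal,
    mito_profile_area_nm2 = mito_profile_area_nm2,
    efferent_plaque_count_mean = efferent_plaque_count_mean,
    efferent_plaque_area_mean_um2 = efferent_plaque_area_mean_um2,
    vesicle_diameter_nm = vesicle_diameter_nm,
    noise = noise,
    orphan_ribbons = as.integer(orphan_ribbons),
    dims = as.integer(dims), geometry = geometry,
    ihc_radius_um = ihc_radius_um,
    fiber_radius_nm = fiber_radius_nm,
    terminal_slices = as.integer(terminal_slices),
    seed = as.integer(seed)
  )
  cfg$span_um <- dims[2] * geometry$dx / 1000
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  fr <- c(cfg$frac_nonsynaptic, cfg$frac_contact_among_nonsynaptic,
          cfg$ribbon_hollow_prob)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  p <- cfg$ribbon_multiplicity_probs
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("ribbon_multiplicity_probs must be 3 non-negative values summing",
         " to 1")
  }
  if (cfg$n_fibers < 1) stop("n_fibers must be >= 1")
  if (cfg$n_ihc < 1) stop("n_ihc must be >= 1")
  pos <- c(cfg$retraction_distance_mean_um, cfg$ribbon_length_range_nm,
           cfg$ribbon_width_nm, cfg$ribbon_thickness_nm,
           cfg$vesicle_diameter_nm, cfg$ihc_radius_um, cfg$fiber_radius_nm,
           cfg$span_um)
  if (any(pos <= 0)) stop("span and all lengths must be positive")
  invisible(cfg)
}

#' Group presets matching the study conditions
#'
#' Returns a [phantom_config()] whose planted fractions, multiplicities and
#' effect sizes match the printed per-stack statistics of the three
#' conditions: control (75 fibers over two stacks of 33 and 41, 71
#' synaptic, 69/2/0 single/double/triple ribbons), 1 day after exposure
#' (59 fibers, 37 non-synaptic of which 21 in contact, 15/5/2 ribbon
#' multiplicity, one orphan ribbon, +51.2% mitochondrial profile count and
#' +15% profile area, efferent plaques 0.666 um^2 x 3.98 per fiber) and 1
#' week after exposure (59 fibers, 31 non-synaptic of which 15 in contact,
#' 19/8/1 multiplicity, mitochondrial and efferent content back at control
#' values).
#'
#' @param group "control", "day1" or "week1".
#' @param n_fibers Fiber count override (control stacks had 33 and 41
#'   fibers; default 41).
#' @param ... Further overrides passed to [phantom_config()].
#' @return A `phantom_config`.
#' @export
group_preset <- function(group = c("control", "day1", "week1"),
                         n_fibers = NULL, ...) {
  group <- match.arg(group)
  mito_count_factor <- switch(group, control = 1, day1 = 1.512, week1 = 1)
  mito_area_factor <- switch(group, control = 1, day1 = 1.15, week1 = 1)
  base_t <- c(modiolar = 0.85, pillar = 1.15) * 81409
  base_p <- c(modiolar = 0.85, pillar = 1.15) * 54862
  args <- switch(group,
    control = list(
      n_fibers = 41,
      frac_nonsynaptic = 4 / 75,
      frac_contact_among_nonsynaptic = 2 / 4,
      ribbon_multiplicity_probs = c(69, 2, 0) / 71,
      ribbon_length_range_nm = c(300, 500),
      orphan_ribbons = 0,
      efferent_plaque_count_mean = c(modiolar = 3.78, pillar = 3.78),
      efferent_plaque_area_mean_um2 = c(modiolar = 0.9, pillar = 1.1) *
        0.496
    ),
    day1 = list(
      n_fibers = 59,
      frac_nonsynaptic = 37 / 59,
      frac_contact_among_nonsynaptic = 21 / 37,
      ribbon_multiplicity_probs = c(15, 5, 2) / 22,
      ribbon_length_range_nm = c(150, 700),
      orphan_ribbons = 1,
      efferent_plaque_count_mean = c(modiolar = 3.98, pillar = 3.98),
      efferent_plaque_area_mean_um2 = c(modiolar = 0.9, pillar = 1.1) *
        0.666
    ),
    week1 = list(
      n_fibers = 59,
      frac_nonsynaptic = 31 / 59,
      frac_contact_among_nonsynaptic = 15 / 31,
      ribbon_multiplicity_probs = c(19, 8, 1) / 28,
      ribbon_length_range_nm = c(250, 550),
      orphan_ribbons = 0,
      efferent_plaque_count_mean = c(modiolar = 3.78, pillar = 3.78),
      efferent_plaque_area_mean_um2 = c(modiolar = 0.9, pillar = 1.1) *
        0.496
    )
  )
  args$group <- group
  args$mito_density_terminal <- base_t * mito_count_factor *
    mito_area_factor
  args$mito_density_preterminal <- base_p * mito_count_factor *
    mito_area_factor
  args$mito_profile_area_nm2 <- 35395 * mito_area_factor
  args$retraction_distance_mean_um <- 2.1
  if (!is.null(n_fibers)) args$n_fibers <- n_fibers
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_config, args)
}

# --- internal geometry helpers -------------------------------------------

rodrigues <- function(v, axis, angle) {
  k <- unitize(axis, "rotation axis")
  v * cos(angle) + pracma_cross(k, v) * sin(angle) +
    k * sum(k * v) * (1 - cos(angle))
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# radial distance of the tube center line end point such that the minimum
# distance from a horizontal disc of radius rf (center at radius rho, polar
# angle theta from the downward axis) to the sphere surface equals `gap`
# (negative gap = overlap into the sphere).
attach_rho <- function(R, rf, theta, gap) {
  target <- R + gap
  if (tan(theta) <= rf / target) {
    target / cos(theta)
  } else {
    rf * sin(theta) + sqrt(target^2 - rf^2 * cos(theta)^2)
  }
}

# direction (polar angle) of the contact patch for a disc-ended tube
contact_theta <- function(rho, theta, rf) {
  xy <- max(rho * sin(theta) - rf, 0)
  atan2(xy, rho * cos(theta))
}


# --- attach-site layout --------------------------------------------------

# Candidate attachment sites on the lower hemisphere of each IHC: a
# sunflower spiral over polar angles 10-55 degrees, greedily thinned to a
# minimum 3D separation larger than two swollen terminal radii (so
# neighbouring boutons never clip each other), with azimuths near the
# modiolar/pillar dividing plane excluded so every fiber has an
# unambiguous side. Returns a data.frame.
attach_site_candidates <- function(cfg, ihc_centers_nm, R) {
  rf <- cfg$fiber_radius_nm
  min_sep <- max(2.3 * rf, 900)
  th_lo <- 10 * pi / 180
  th_hi <- 60 * pi / 180
  rho <- R + rf
  n_dense <- max(60L, ceiling(
    3 * 2 * pi * rho^2 * (cos(th_lo) - cos(th_hi)) / min_sep^2))
  k <- seq_len(n_dense)
  ct <- cos(th_lo) + (k - 0.5) / n_dense * (cos(th_hi) - cos(th_lo))
  th <- acos(ct)
  ph <- (k * 2.399963) %% (2 * pi)
  keep <- abs(sin(ph)) >= 0.10
  th <- th[keep]; ph <- ph[keep]
  xyz <- rho * cbind(sin(th) * cos(ph), sin(th) * sin(ph), -cos(th))
  sel <- integer(0)
  for (j in seq_along(th)) {       # greedy thinning, pole-ward first
    if (length(sel) == 0 ||
        min(sqrt(colSums((t(xyz[sel, , drop = FALSE]) - xyz[j, ])^2))) >=
          min_sep) {
      sel <- c(sel, j)
    }
  }
  out <- list()
  for (i in seq_len(nrow(ihc_centers_nm))) {
    out[[i]] <- data.frame(ihc = i, theta = th[sel], phi = ph[sel])
  }
  sites <- do.call(rbind, out)
  sites$side <- ifelse(sin(sites$phi) > 0, "modiolar", "pillar")
  sites
}

# --- main generator ------------------------------------------------------

#' Generate a synthetic cochlear phantom
#'
#' Deterministic for a fixed seed: the same config and seed reproduce the
#' label lattice bit-exactly. Classification counts, ribbon multiplicities
#' and efferent plaque counts are planted exactly (largest remainder from
#' the configured fractions); different seeds move objects around but never
#' change the planted counts.
#'
#' @param config A [phantom_config()] or [group_preset()].
#' @param seed Integer seed (default `config$seed`).
#' @return A list with elements `volume` (a [label_volume()]),
#'   `annotations` (list of `efferent` and `psd` data.frames),
#'   `truth` (planted ground truth: per-fiber records, synapse records,
#'   efferent records, the dividing plane, seed) and `config`.
#' @export
generate_phantom <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  g <- config$geometry
  d <- config$dims
  nr <- d[1]; nc <- d[2]; ns <- d[3]
  dx <- g$dx; dy <- g$dy; dz <- g$dz
  extent_x <- nc * dx; extent_y <- nr * dy; extent_z <- ns * dz
  rf <- config$fiber_radius_nm
  R <- config$ihc_radius_um * 1000
  vol <- array(0L, dim = d)

  # ---- IHCs: basal hemispheres protruding from the stack top
  n_ihc <- config$n_ihc
  cz <- extent_z + R - 0.25 * extent_z          # lower cap inside the stack
  ihc_centers <- cbind(
    x = (seq_len(n_ihc) - 0.5) / n_ihc * extent_x,
    y = extent_y / 2,
    z = cz
  )
  for (i in seq_len(n_ihc)) {
    cpp_fill_ball(vol, nr, nc, ns,
                  c(ihc_centers[i, "y"] / dy, ihc_centers[i, "x"] / dx,
                    ihc_centers[i, "z"] / dz),
                  pitch_vec(g), R, PHANTOM_LABELS$ihc + i - 1L)
  }
  y_mid <- extent_y / 2
  plane <- list(point = c(x = 0, y = y_mid, z = 0),
                normal = c(x = 0, y = 1, z = 0))

  # ---- planted counts (largest remainder, exact)
  nf <- config$n_fibers
  n_nonsyn <- apportion(nf, c(1 - config$frac_nonsynaptic,
                              config$frac_nonsynaptic))[2]
  n_syn <- nf - n_nonsyn
  n_contact <- apportion(n_nonsyn,
                         c(config$frac_contact_among_nonsynaptic,
                           1 - config$frac_contact_among_nonsynaptic))[1]
  n_retr <- n_nonsyn - n_contact
  status <- c(rep("synaptic", n_syn), rep("nonsynaptic_contact", n_contact),
              rep("nonsynaptic_retracted", n_retr))
  # sides balanced within each classification group
  side <- c(rep(c("modiolar", "pillar"),
                length.out = n_syn),
            rep(c("modiolar", "pillar"), length.out = n_contact),
            rep(c("pillar", "modiolar"), length.out = n_retr))

  mult_counts <- apportion(n_syn, config$ribbon_multiplicity_probs)
  multiplicity <- rep.int(c(1L, 2L, 3L), mult_counts)
  if (length(multiplicity) > 1) {               # shuffle across fibers
    multiplicity <- multiplicity[sample.int(length(multiplicity))]
  }
  mult_of <- integer(nf)
  if (n_syn > 0) mult_of[seq_len(n_syn)] <- multiplicity

  # retraction gaps at deterministic normal quantiles (mean exact)
  gaps <- if (n_retr > 0) {
    q <- stats::qnorm((seq_len(n_retr) - 0.5) / n_retr)
    pmax(800, config$retraction_distance_mean_um * 1000 +
           config$retraction_distance_sd_um * 1000 * q)
  } else numeric(0)
  if (n_retr > 1) gaps <- gaps[sample.int(n_retr)]

  # ---- assign attach sites
  # Site spacing (>= ~900 nm) plus apposition-zone ribbon pairing keeps
  # neighbouring terminals from perturbing each other; retracted fibers
  # take the most pole-ward free sites so their near-vertical approach
  # puts the planted gap almost entirely along the radial direction.
  sites <- attach_site_candidates(config, ihc_centers, R)
  patch_xyz <- t(vapply(seq_len(nrow(sites)), function(i) {
    st <- sites[i, ]
    rho <- attach_rho(R, rf, st$theta, -80)
    th_s <- contact_theta(rho, st$theta, rf)
    ihc_centers[st$ihc, ] + (R - 150) *
      c(sin(th_s) * cos(st$phi), sin(th_s) * sin(st$phi), -cos(th_s))
  }, numeric(3)))
  ihc_of_fiber <- rep(seq_len(n_ihc), length.out = nf)
  fiber_site <- integer(nf)
  used <- logical(nrow(sites))
  claims <- numeric(nrow(sites))
  # orphan ribbons need ~1.3 um of clearance from every fiber surface;
  # reserve their pockets before the terminals pack the basal cap
  orphan_sites <- integer(0)
  if (config$orphan_ribbons > 0) {
    for (o in seq_len(config$orphan_ribbons)) {
      cand <- which(!used & sites$theta >= 25 * pi / 180 &
                      sites$theta <= 50 * pi / 180)
      if (length(cand) == 0) cand <- which(!used)
      if (length(cand) == 0) {
        stop("phantom geometry overflow: no room to reserve an orphan",
             " ribbon pocket")
      }
      pick <- cand[sample.int(length(cand), 1)]
      orphan_sites <- c(orphan_sites, pick)
      dd <- sqrt(colSums((t(patch_xyz) - patch_xyz[pick, ])^2))
      used[dd < 1300] <- TRUE
    }
  }
  claim_of <- function(m) if (m == 3) 1000 else if (m == 2) 860 else 0
  priority <- ifelse(mult_of == 3, 0L, ifelse(mult_of == 2, 1L,
                ifelse(status == "nonsynaptic_retracted", 2L, 3L)))
  for (f in order(priority, seq_len(nf))) {
    pool <- which(!used & sites$ihc == ihc_of_fiber[f] &
                    sites$side == side[f])
    if (length(pool) == 0) pool <- which(!used & sites$side == side[f])
    if (length(pool) == 0) {
      stop("phantom geometry overflow: no free attachment site for fiber ",
           f, " (side ", side[f], "); reduce n_fibers or enlarge lattice")
    }
    if (status[f] == "synaptic") {
      # keep ribbon-bearing terminals away from the pole, where contact
      # patches crowd together and ribbon pairing would become ambiguous
      high <- pool[sites$theta[pool] >= 20 * pi / 180]
      if (length(high) > 0) pool <- high
    }
    if (status[f] == "nonsynaptic_retracted") {
      pick <- pool[which.min(sites$theta[pool])]
    } else {
      # multi-ribbon synapses claim an isolation radius in contact-patch
      # space; other apposed terminals must stay outside existing claims
      need <- claim_of(mult_of[f])
      uidx <- which(used)
      margin <- vapply(pool, function(p) {
        if (length(uidx) == 0) return(Inf)
        dd <- sqrt(colSums((t(patch_xyz[uidx, , drop = FALSE]) -
                              patch_xyz[p, ])^2))
        min(dd - pmax(claims[uidx], need))
      }, numeric(1))
      feasible <- pool[margin >= 0]
      pick <- if (length(feasible) > 0) {
        feasible[sample.int(length(feasible), 1)]
      } else {
        warning("phantom: crowded attachment sites; fiber ", f,
                " placed with reduced isolation")
        pool[which.max(margin)]
      }
    }
    fiber_site[f] <- pick
    used[pick] <- TRUE
    claims[pick] <- claim_of(mult_of[f])
    ihc_of_fiber[f] <- sites$ihc[pick]
  }

  # shared lateral drift field: every fiber bends with the same smooth
  # in-plane displacement (vanishing near the IHCs), so curvature never
  # brings two tubes closer together than their attachment sites
  drift_amp <- runif(2, 120, 280) * sample(c(-1, 1), 2, replace = TRUE)
  drift_phase <- runif(2, 0, 2 * pi)
  z_ref <- 0.55 * min(extent_z, cz - R)
  drift_xy <- function(z) {
    fade <- pmax(0, 1 - z / z_ref)
    cbind(drift_amp[1] * sin(2 * pi * z / (2.2 * z_ref) +
                               drift_phase[1]) * fade,
          drift_amp[2] * sin(2 * pi * z / (2.6 * z_ref) +
                               drift_phase[2]) * fade)
  }

  # ---- render fibers
  lab <- PHANTOM_LABELS
  margin_px <- ceiling(1.4 * rf / dx) + 3
  fibers <- vector("list", nf)
  retr_i <- 0
  for (f in seq_len(nf)) {
    st <- sites[fiber_site[f], ]
    C <- ihc_centers[st$ihc, ]
    theta <- st$theta; phi <- st$phi
    retracted <- status[f] == "nonsynaptic_retracted"
    gap <- if (retracted) { retr_i <- retr_i + 1; gaps[retr_i] } else -80
    rho <- attach_rho(R, rf, theta, -80)
    dvec <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), -cos(theta))
    A <- C + rho * dvec
    if (retracted) {
      # retract vertically below the attachment point: the shaft keeps
      # the xy of its site (no lateral shift into neighbours) and stops
      # where the disc-to-sphere surface distance equals the planted gap
      a_xy <- rho * sin(theta)
      A[3] <- C[3] - sqrt((R + gap)^2 - max(a_xy - rf, 0)^2)
    }
    s_att <- floor(A[3] / dz)
    if (s_att < 60 || s_att > ns - 20) {
      stop("phantom geometry overflow: fiber ", f,
           " attachment slice ", s_att, " outside lattice")
    }
    # approach path: rises from the habenular face directly below the
    # attachment site, curved by the shared drift field plus a small
    # per-fiber wobble (texture only; too small to cause collisions)
    slices <- 0:s_att
    zs <- slices * dz
    dr <- drift_xy(zs)
    wob <- runif(2, -60, 60)
    px_path <- A[1] + dr[, 1] + wob[1] * pmax(0, 1 - zs / z_ref)
    py_path <- A[2] + dr[, 2] + wob[2] * pmax(0, 1 - zs / z_ref)
    px_path <- pmin(pmax(px_path, margin_px * dx),
                    extent_x - margin_px * dx)
    py_path <- pmin(pmax(py_path, margin_px * dy),
                    extent_y - margin_px * dy)
    # embed phase: contact and synaptic terminals keep rising past first
    # touch so the hemisphere progressively clips them, producing an
    # annular membrane apposition sustained over many slices without any
    # lateral sweep toward neighbouring terminals
    if (!retracted) {
      embed <- 12L
      add <- seq_len(min(embed, ns - 3 - s_att))
      slices <- c(slices, s_att + add)
      px_path <- c(px_path, rep(A[1], length(add)))
      py_path <- c(py_path, rep(A[2], length(add)))
    }
    n_sl <- length(slices)
    swell <- 1 + 0.15 * exp(-(slices[n_sl] - slices) / 25)
    rad_px <- rf / dx * swell + runif(n_sl, -config$noise, config$noise)
    rad_px <- pmax(rad_px, 2)
    fid <- lab$fiber + f - 1L
    cnt <- cpp_fill_discs(vol, nr, nc, ns, as.integer(slices),
                          py_path / dy, px_path / dx, rad_px, fid)
    if (any(attr(cnt, "overflow"))) {
      stop("phantom geometry overflow: fiber ", f,
           " exceeds lattice bounds in-plane")
    }
    # slices fully engulfed by the IHC place no voxels: trim them so the
    # terminus is the last occupied slice
    occ <- which(cnt > 0)
    if (length(occ) == 0) {
      stop("phantom geometry overflow: fiber ", f, " placed no voxels")
    }
    keep <- seq_len(max(occ))
    slices <- slices[keep]; px_path <- px_path[keep]
    py_path <- py_path[keep]; rad_px <- rad_px[keep]
    cnt <- cnt[keep]
    terminus <- slices[length(slices)]
    fibers[[f]] <- list(
      id = fid, status = status[f], side = side[f], ihc = st$ihc,
      theta = theta, phi = phi, rho = rho, gap = if (retracted) gap else 0,
      attach_slice = s_att, terminus = terminus,
      path = cbind(slice = slices, x = px_path, y = py_path,
                   rad_px = rad_px),
      area_vox = as.integer(cnt)
    )
  }

  # ---- mitochondria
  # Non-overlapping placement on six radial lanes per fiber (one axial,
  # five on a ring wide enough that same-slice profiles never touch),
  # interval-scheduled along z.  Three populations: a pre-terminal stream
  # at the pre-terminal density, a terminal stream topping the terminal
  # region up to its density, and a "bump" of 2-3 elongated cylindrical
  # mitochondria spanning exactly the 50 slices centred on the recorded
  # mito-peak.  The bump cylinders have constant cross-section, so the
  # planted peak has sharp edges and the best 50-slice window is pinned;
  # the extreme terminus stays devoid of mitochondria.
  A_p <- config$mito_profile_area_nm2
  r_ip <- sqrt(1.5 * A_p / pi)                 # in-plane radius, nm
  mito_id <- lab$mito
  mito_rows <- list()
  hs_st <- 14L                                 # stream mito half-length
  for (f in seq_len(nf)) {
    fb <- fibers[[f]]
    T_ <- fb$terminus
    span <- T_ + 1
    rate_t <- config$mito_density_terminal[[fb$side]] / A_p
    rate_p <- config$mito_density_preterminal[[fb$side]] / A_p
    t0 <- max(12L, T_ - config$terminal_slices + 1L)
    peak_center <- T_ - 45L
    bump_ok <- peak_center - 25 >= t0 + 2 && peak_center + 24 <= T_ - 14
    chains <- if (bump_ok)
      min(3L, max(2L, round(1.5 * (rate_t - rate_p)))) else 0L

    # candidate intervals: (start, end, kind) in slice units
    iv <- list()
    if (chains > 0) {
      for (ch in seq_len(chains)) {
        iv[[length(iv) + 1]] <- c(peak_center - 25L, peak_center + 24L, 1L)
      }
    }
    if (t0 - 1 >= 12 + hs_st) {
      n_pre <- max(0L, round(rate_p * (t0 - 12) / (2 * hs_st + 1)))
      if (n_pre > 0) {
        for (zc in round(seq(12 + hs_st, t0 - 1 - hs_st,
                             length.out = n_pre))) {
          iv[[length(iv) + 1]] <- c(zc - hs_st, zc + hs_st, 0L)
        }
      }
    }
    len_t <- (T_ - 16) - t0 + 1
    if (len_t > 2 * hs_st + 1) {
      occ_t <- rate_t * len_t - 50 * chains
      n_ter <- max(0L, round(occ_t / (2 * hs_st + 1)))
      if (n_ter > 0) {
        for (zc in round(seq(t0 + hs_st, T_ - 16 - hs_st,
                             length.out = n_ter))) {
          iv[[length(iv) + 1]] <- c(zc - hs_st, zc + hs_st, 0L)
        }
      }
    }

    # greedy interval scheduling onto 6 lanes (bump chains first, then by
    # start slice); an interval with no free lane is dropped (physical
    # packing cap of ~6 profiles per slice)
    ang0 <- runif(1, 0, 2 * pi)
    lane_xy <- rbind(c(0, 0),
                     240 * cbind(cos(ang0 + 2 * pi * (0:4) / 5),
                                 sin(ang0 + 2 * pi * (0:4) / 5)))
    lane_end <- rep(-10L, 6)
    sched <- list()
    if (length(iv) > 0) {
      ord <- order(-vapply(iv, `[`, numeric(1), 3),
                   vapply(iv, `[`, numeric(1), 1))
      for (m in ord) {
        a <- iv[[m]][1]; b <- iv[[m]][2]; kind <- iv[[m]][3]
        lanes_try <- if (kind == 1L) 2:6 else c(2:6, 1L)
        free <- lanes_try[lane_end[lanes_try] < a - 1L]
        if (length(free) == 0) next
        l <- free[1]
        lane_end[l] <- b
        sched[[length(sched) + 1]] <- c(a, b, kind, l)
      }
    }

    per_slice_area <- numeric(ns)
    per_slice_cnt <- integer(ns)
    mlist <- list()
    for (sc in sched) {
      a <- sc[1]; b <- sc[2]; kind <- sc[3]; l <- sc[4]
      zc <- (a + b) / 2
      if (a < 1 || b > T_ - 2) next
      row_i <- round(zc) + 1L            # path slices contiguous from 0
      if (row_i > nrow(fb$path)) next
      cxy <- c(fb$path[row_i, "x"], fb$path[row_i, "y"]) + lane_xy[l, ]
      if (kind == 1L) {
        res_m <- cpp_fill_ribbon(vol, nr, nc, ns,
                                 c(cxy[2] / dy, cxy[1] / dx, zc),
                                 pitch_vec(g), c(0, 0, 1), c(1, 0, 0),
                                 c(0, 1, 0),
                                 c((b - a + 0.9) / 2 * dz, r_ip, r_ip),
                                 mito_id, fb$id, 0)
        cnt <- res_m$per_slice
        placed <- res_m$placed
      } else {
        cnt <- cpp_fill_ellipsoid(vol, nr, nc, ns,
                                  c(cxy[2] / dy, cxy[1] / dx, zc),
                                  c(r_ip / dy, r_ip / dx, (b - a) / 2),
                                  mito_id, fb$id)
        placed <- sum(cnt)
      }
      if (placed == 0) next
      smin <- attr(cnt, "smin")
      sl <- smin + seq_along(cnt) - 1L
      nz <- cnt > 0
      per_slice_area[sl[nz] + 1L] <- per_slice_area[sl[nz] + 1L] +
        cnt[nz] * dx * dy
      per_slice_cnt[sl[nz] + 1L] <- per_slice_cnt[sl[nz] + 1L] + 1L
      mlist[[length(mlist) + 1]] <- data.frame(
        label = mito_id, parent = fb$id, n_voxels = placed)
      mito_id <- mito_id + 1L
    }
    fibers[[f]]$mito_peak_center <- if (chains > 0) peak_center else
      NA_integer_
    fibers[[f]]$mito_slice_area <- per_slice_area[seq_len(T_ + 1)]
    fibers[[f]]$mito_slice_count <- per_slice_cnt[seq_len(T_ + 1)]
    mito_rows[[f]] <- if (length(mlist)) do.call(rbind, mlist) else NULL
  }
  mito_tab <- do.call(rbind, mito_rows)

  # ---- ribbons + PSD annotations
  hw_v <- config$ribbon_width_nm / 2
  hw_w <- config$ribbon_thickness_nm / 2
  syn_fibers <- which(status == "synaptic")
  n_ribbons_total <- sum(multiplicity)
  len_all <- seq(config$ribbon_length_range_nm[1],
                 config$ribbon_length_range_nm[2],
                 length.out = max(n_ribbons_total, 2))
  len_all <- len_all[sample.int(length(len_all))][seq_len(n_ribbons_total)]
  hollow_flags <- rep(FALSE, n_ribbons_total)
  n_hollow <- round(config$ribbon_hollow_prob * n_ribbons_total)
  if (n_hollow > 0) {
    hollow_flags[round(seq(1, n_ribbons_total,
                           length.out = n_hollow))] <- TRUE
  }
  rib_id <- lab$ribbon
  ribbons <- list()
  synapses <- list()
  psd_rows <- list()
  ri <- 0
  for (k in seq_along(syn_fibers)) {
    f <- syn_fibers[k]
    fb <- fibers[[f]]
    C <- ihc_centers[fb$ihc, ]
    m <- multiplicity[k]
    # the apposed annulus sweeps from the first-touch direction outward
    # as the terminal embeds; centre the ribbons on the middle of that
    # patch so every member sits within the pairing radius of it
    th_in <- contact_theta(fb$rho, fb$theta, rf)
    th_out <- atan2(fb$rho * sin(fb$theta) + 0.8 * rf,
                    fb$rho * cos(fb$theta))
    th_c <- acos(min(1, max(cos(th_out), cos(th_in) - 120 / R)))
    d0 <- c(sin(th_c) * cos(fb$phi), sin(th_c) * sin(fb$phi), -cos(th_c))
    t1 <- unitize(c(-sin(fb$phi), cos(fb$phi), 0))        # azimuthal
    # side-by-side ribbons stacked azimuthally (constant polar angle, so
    # every member stays at the apposed terminal), 300 nm apart: the
    # 80-nm surface gap always leaves an empty voxel column (no
    # 26-connected merge) while every member stays within the pairing
    # radius of the apposition
    depth_r <- R - hw_w - 30
    offs <- (seq_len(m) - (m + 1) / 2) * 300 / depth_r
    # all members share the frame of the group center: parallel long axes
    # keep the inter-ribbon gap constant (converging meridians would let
    # neighbouring members touch near the pole and merge into one
    # instance)
    u0 <- unitize(pracma_cross(d0, t1))                   # meridional
    rids <- integer(m)
    rvols <- numeric(m); rlens <- numeric(m); rhol <- logical(m)
    rcent <- matrix(0, m, 3)
    for (j in seq_len(m)) {
      ri <- ri + 1
      L <- len_all[ri]
      dj <- unitize(d0 + offs[j] * t1)
      center <- C + depth_r * dj
      carve <- if (hollow_flags[ri]) 0.45 else 0
      res <- cpp_fill_ribbon(vol, nr, nc, ns,
                             c(center[2] / dy, center[1] / dx,
                               center[3] / dz),
                             pitch_vec(g), u0, t1, d0,
                             c(L / 2, hw_v, hw_w),
                             rib_id, lab$ihc + fb$ihc - 1L, carve)
      hollow_ok <- FALSE
      if (carve > 0 && res$carved > 0) {
        reach <- sqrt(sum((L / 2)^2 + hw_v^2 + hw_w^2))
        hollow_ok <- ribbon_cavity_enclosed(
          vol, rib_id, c(center[2] / dy, center[1] / dx, center[3] / dz),
          c(reach / dy, reach / dx, reach / dz), nr, nc, ns)
      }
      vol_an <- L * pi * hw_v * hw_w
      if (hollow_ok) vol_an <- vol_an * (1 - 0.45^3)
      ribbons[[length(ribbons) + 1]] <- list(
        id = rib_id, fiber = fb$id, ihc = fb$ihc,
        analytic_volume_nm3 = vol_an, planted_length_nm = L,
        hollow = hollow_ok, n_voxels = res$placed - res$carved,
        normal = dj, orphan = FALSE)
      rids[j] <- rib_id
      rvols[j] <- vol_an; rlens[j] <- L; rhol[j] <- hollow_ok
      rcent[j, ] <- center
      rib_id <- rib_id + 1L
    }
    psd_rows[[k]] <- data.frame(
      fiber_id = fb$id, ihc_id = fb$ihc,
      row = mean(rcent[, 2]) / dy, col = mean(rcent[, 1]) / dx,
      slice = mean(rcent[, 3]) / dz, psd_present = TRUE)
    synapses[[k]] <- list(
      fiber = fb$id, ihc = fb$ihc, ribbon_ids = rids,
      multiplicity = m, analytic_volumes = rvols, lengths = rlens,
      hollow = rhol)
  }

  # ---- orphan ribbons (no fiber nearby)
  orphan_ids <- integer(0)
  if (config$orphan_ribbons > 0) {
    free_sites <- unique(c(orphan_sites, which(!used)))
    for (o in seq_len(config$orphan_ribbons)) {
      placed_ok <- FALSE
      # most isolated free sites first; acceptance is decided on the
      # rendered voxels: no ANF voxel within 500 nm of the ribbon's
      # bounding sphere, and clearance from every planted ribbon
      uidx <- which(used)
      iso <- vapply(free_sites, function(cand) {
        if (length(uidx) == 0) return(Inf)
        dd <- sqrt(colSums((t(patch_xyz[uidx, , drop = FALSE]) -
                              patch_xyz[cand, ])^2))
        min(dd)
      }, numeric(1))
      anf_ids <- vapply(fibers, function(x) x$id, integer(1))
      rib_ids_so_far <- vapply(ribbons, function(x) x$id, integer(1))
      for (cand in free_sites[order(-iso)]) {
        st <- sites[cand, ]
        ctr_vox <- c(patch_xyz[cand, 2] / dy, patch_xyz[cand, 1] / dx,
                     patch_xyz[cand, 3] / dz)
        d_anf <- min_label_dist(vol, ctr_vox, 1300, anf_ids, g)
        if (d_anf < 500 + 320) next
        if (length(rib_ids_so_far) > 0 &&
            min_label_dist(vol, ctr_vox, 1300, rib_ids_so_far, g) < 700)
          next
        C <- ihc_centers[st$ihc, ]
        dj <- c(sin(st$theta) * cos(st$phi), sin(st$theta) * sin(st$phi),
                -cos(st$theta))
        t1 <- unitize(c(-sin(st$phi), cos(st$phi), 0))
        t2 <- pracma_cross(dj, t1)
        center <- C + (R - hw_w - 30) * dj
        res <- cpp_fill_ribbon(vol, nr, nc, ns,
                               c(center[2] / dy, center[1] / dx,
                                 center[3] / dz),
                               pitch_vec(g), t1, t2, dj,
                               c(180, hw_v, hw_w), rib_id,
                               lab$ihc + st$ihc - 1L, 0)
        if (res$placed == 0) next
        ribbons[[length(ribbons) + 1]] <- list(
          id = rib_id, fiber = NA_integer_, ihc = st$ihc,
          analytic_volume_nm3 = 360 * pi * hw_v * hw_w,
          planted_length_nm = 360, hollow = FALSE,
          n_voxels = res$placed, normal = dj, orphan = TRUE)
        orphan_ids <- c(orphan_ids, rib_id)
        used[cand] <- TRUE
        rib_id <- rib_id + 1L
        placed_ok <- TRUE
        break
      }
      if (!placed_ok) {
        stop("phantom geometry overflow: no isolated site for an orphan",
             " ribbon")
      }
    }
  }

  # ---- efferent contacts + annotations
  eff <- plant_efferents(vol, config, fibers, g)

  # ---- label table + volume object
  tab_rows <- list(
    data.frame(label = lab$ihc + seq_len(n_ihc) - 1L, class = "IHC",
               parent = NA_integer_),
    data.frame(label = vapply(fibers, function(x) x$id, integer(1)),
               class = "ANF", parent = NA_integer_)
  )
  if (length(ribbons) > 0) {
    tab_rows <- c(tab_rows, list(data.frame(
      label = vapply(ribbons, function(x) x$id, integer(1)),
      class = "RIBBON",
      parent = vapply(ribbons, function(x) x$fiber, integer(1)))))
  }
  if (!is.null(mito_tab) && nrow(mito_tab) > 0) {
    tab_rows <- c(tab_rows, list(data.frame(
      label = mito_tab$label, class = "MITO", parent = mito_tab$parent)))
  }
  if (length(eff$labels) > 0) {
    tab_rows <- c(tab_rows, list(data.frame(
      label = eff$labels, class = "EFFERENT", parent = NA_integer_)))
  }
  tab <- do.call(rbind, tab_rows)
  volume <- label_volume(vol, g, label_table(tab$label, tab$class,
                                             tab$parent))

  truth <- list(
    seed = seed, group = config$group,
    dividing_plane = plane,
    ihc_centers_nm = ihc_centers, ihc_radius_nm = R,
    fibers = lapply(fibers, function(fb) {
      fb[c("id", "status", "side", "ihc", "gap", "terminus",
           "mito_peak_center", "mito_slice_area", "mito_slice_count")]
    }),
    synapses = synapses,
    ribbons = ribbons,
    orphan_ribbon_ids = orphan_ids,
    efferent = eff$truth,
    counts = list(
      n_fibers = nf, synaptic = n_syn, nonsynaptic_contact = n_contact,
      nonsynaptic_retracted = n_retr,
      multiplicity = mult_counts
    )
  )
  list(volume = volume,
       annotations = list(efferent = eff$table, psd = do.call(rbind,
                                                              psd_rows)),
       truth = truth, config = config)
}

# min anisotropic distance (nm) from a voxel coordinate to any voxel whose
# label is in `ids`, searched within a crop of physical radius `radius_nm`
min_label_dist <- function(vol, center_vox, radius_nm, ids, g) {
  d <- dim(vol)
  rr <- ceiling(radius_nm / g$dy); rc <- ceiling(radius_nm / g$dx)
  rs <- ceiling(radius_nm / g$dz)
  r0 <- max(0, floor(center_vox[1] - rr))
  r1 <- min(d[1] - 1, ceiling(center_vox[1] + rr))
  c0 <- max(0, floor(center_vox[2] - rc))
  c1 <- min(d[2] - 1, ceiling(center_vox[2] + rc))
  s0 <- max(0, floor(center_vox[3] - rs))
  s1 <- min(d[3] - 1, ceiling(center_vox[3] + rs))
  sub <- vol[(r0:r1) + 1, (c0:c1) + 1, (s0:s1) + 1, drop = FALSE]
  hit <- which(array(sub %in% ids, dim = dim(sub)))
  if (length(hit) == 0) return(Inf)
  co <- arrayInd(hit, dim(sub)) - 1L
  min(sqrt(((co[, 1] + r0 - center_vox[1]) * g$dy)^2 +
           ((co[, 2] + c0 - center_vox[2]) * g$dx)^2 +
           ((co[, 3] + s0 - center_vox[3]) * g$dz)^2))
}

# arc distance between attach sites on the same sphere
site_arc_dist <- function(sites_df, st, R) {
  v1 <- cbind(sin(sites_df$theta) * cos(sites_df$phi),
              sin(sites_df$theta) * sin(sites_df$phi),
              -cos(sites_df$theta))
  v0 <- c(sin(st$theta) * cos(st$phi), sin(st$theta) * sin(st$phi),
          -cos(st$theta))
  R * acos(pmin(1, pmax(-1, v1 %*% v0)))
}

# verify that a carved ribbon cavity is a genuinely enclosed 3D hole,
# within a local crop around the known ribbon center
ribbon_cavity_enclosed <- function(vol, rib_id, center_vox, reach_vox,
                                   nr, nc, ns) {
  bb <- c(max(0, floor(center_vox[1] - reach_vox[1]) - 1),
          min(nr - 1, ceiling(center_vox[1] + reach_vox[1]) + 1),
          max(0, floor(center_vox[2] - reach_vox[2]) - 1),
          min(nc - 1, ceiling(center_vox[2] + reach_vox[2]) + 1),
          max(0, floor(center_vox[3] - reach_vox[3]) - 1),
          min(ns - 1, ceiling(center_vox[3] + reach_vox[3]) + 1))
  W <- bb[2] - bb[1] + 1; H <- bb[4] - bb[3] + 1; D <- bb[6] - bb[5] + 1
  sub <- vol[(bb[1]:bb[2]) + 1, (bb[3]:bb[4]) + 1, (bb[5]:bb[6]) + 1]
  mask <- array(as.integer(sub == rib_id), dim = c(W, H, D))
  filled <- cpp_fill_holes3d(mask, W, H, D)
  sum(filled) > sum(mask)
}

# ---- efferent planting --------------------------------------------------

plant_efferents <- function(vol, config, fibers, g) {
  d <- dim(vol)
  nr <- d[1]; nc <- d[2]; ns <- d[3]
  dx <- g$dx; dy <- g$dy; dz <- g$dz
  sides <- vapply(fibers, function(x) x$side, character(1))
  truth <- list(); labels <- integer(0)
  eff_id <- PHANTOM_LABELS$efferent
  contact_id <- 0L
  vd <- config$vesicle_diameter_nm
  # column accumulators (one row per annotated slice)
  A_cid <- integer(0); A_eid <- integer(0); A_fid <- integer(0)
  A_sl <- integer(0); A_ap <- logical(0); A_th <- logical(0)
  A_vp <- character(0); A_tr <- character(0)
  emit <- function(cid, eid, fid, sl, ap, th, vp, tr) {
    A_cid <<- c(A_cid, rep(cid, length(sl)))
    A_eid <<- c(A_eid, rep(eid, length(sl)))
    A_fid <<- c(A_fid, rep(fid, length(sl)))
    A_sl <<- c(A_sl, sl); A_ap <<- c(A_ap, rep(ap, length(sl)))
    A_th <<- c(A_th, rep(th, length(sl)))
    A_vp <<- c(A_vp, vp); A_tr <<- c(A_tr, tr)
  }
  slice_strings <- function(ctr_x, ctr_y, ang, ell, with_vesicles = TRUE,
                            n_ves = 6) {
    tang <- c(-sin(ang), cos(ang))
    ax <- ctr_x - tang[1] * ell / 2; ay <- ctr_y - tang[2] * ell / 2
    bx <- ctr_x + tang[1] * ell / 2; by <- ctr_y + tang[2] * ell / 2
    tr <- sprintf("%.4f,%.4f;%.4f,%.4f", ay / dy, ax / dx, by / dy,
                  bx / dx)
    vp <- character(length(ctr_x))
    if (with_vesicles) {
      nsl <- length(ctr_x)
      tpos <- seq(0.15, 0.85, length.out = n_ves)
      for (i in seq_len(nsl)) {
        off <- runif(n_ves, 0.8 * vd, 1.7 * vd)
        vx <- ax[i] + tpos * (bx[i] - ax[i]) + cos(ang) * off
        vy <- ay[i] + tpos * (by[i] - ay[i]) + sin(ang) * off
        vp[i] <- paste(sprintf("%.3f,%.3f", vy / dy, vx / dx),
                       collapse = ";")
      }
    }
    list(trace = tr, ves = vp)
  }
  for (sd in c("modiolar", "pillar")) {
    idx <- which(sides == sd)
    if (length(idx) == 0) next
    total <- round(config$efferent_plaque_count_mean[[sd]] * length(idx))
    per_fiber <- apportion(total, rep(1 / length(idx), length(idx)))
    mu <- config$efferent_plaque_area_mean_um2[[sd]] * 1e6   # nm^2
    n_pl <- sum(per_fiber)
    wts <- rep(c(0.7, 1.0, 1.3), length.out = n_pl)
    wts <- wts / mean(wts)                     # planted mean exactly mu
    areas <- mu * wts
    ai <- 0
    for (q in seq_along(idx)) {
      f <- idx[q]
      fb <- fibers[[f]]
      T_ <- fb$terminus
      ztop <- T_ - 40
      pl_truth <- list()
      for (k in seq_len(per_fiber[q])) {
        ai <- ai + 1
        A_nm2 <- areas[ai]
        n_s <- max(5L, min(60L, round(sqrt(A_nm2) / dz)))
        ell <- A_nm2 / (n_s * dz)              # per-slice trace length, nm
        z1 <- ztop - (n_s - 1)
        if (z1 < 15) {                          # stack further plaques up
          z1 <- 15; ztop <- z1 + n_s - 1
        }
        contact_id <- contact_id + 1L
        ang <- runif(1, 0, 2 * pi)
        sl <- z1:ztop
        p <- fb$path[sl + 1, , drop = FALSE]
        ctr_x <- p[, "x"] + (p[, "rad_px"] * dx + 1.2 * dx) * cos(ang)
        ctr_y <- p[, "y"] + (p[, "rad_px"] * dx + 1.2 * dx) * sin(ang)
        ss <- slice_strings(ctr_x, ctr_y, ang, ell)
        emit(contact_id, eff_id, fb$id, sl, TRUE, TRUE, ss$ves, ss$trace)
        # small vesicle-filled bouton in the lattice next to the trace
        mid_i <- ceiling(length(sl) / 2)
        ctr <- c(ctr_x[mid_i], ctr_y[mid_i]) +
          360 * c(cos(ang), sin(ang))
        cpp_fill_ellipsoid(vol, nr, nc, ns,
                           c(ctr[2] / dy, ctr[1] / dx, sl[mid_i]),
                           c(320 / dy, 320 / dx, 14), eff_id, 0L)
        labels <- c(labels, eff_id)
        pl_truth[[k]] <- list(contact_id = contact_id,
                              area_um2 = A_nm2 / 1e6, n_slices = n_s)
        eff_id <- eff_id + 1L
        ztop <- z1 - 7
      }
      # sub-threshold negative contact (4 qualifying slices) on every
      # fourth fiber: must never be recovered as a plaque
      if (q %% 4 == 1 && ztop - 3 >= 15) {
        contact_id <- contact_id + 1L
        sl <- (ztop - 3):ztop
        ang <- runif(1, 0, 2 * pi)
        p <- fb$path[sl + 1, , drop = FALSE]
        ctr_x <- p[, "x"] + (p[, "rad_px"] * dx + 1.2 * dx) * cos(ang)
        ctr_y <- p[, "y"] + (p[, "rad_px"] * dx + 1.2 * dx) * sin(ang)
        ss <- slice_strings(ctr_x, ctr_y, ang, 500)
        emit(contact_id, NA_integer_, fb$id, sl, TRUE, TRUE, ss$ves,
             ss$trace)
      }
      truth[[length(truth) + 1]] <- list(
        fiber = fb$id, side = sd,
        plaque_count = per_fiber[q],
        plaque_areas_um2 = vapply(pl_truth, function(x) x$area_um2,
                                  numeric(1)))
    }
  }
  tab <- data.frame(contact_id = A_cid, efferent_id = A_eid,
                    fiber_id = A_fid, slice_index = A_sl,
                    apposition = A_ap, thickening = A_th,
                    vesicle_points = A_vp, trace = A_tr)
  list(table = tab, truth = truth, labels = unique(labels))
}

#' Write a phantom to disk
#'
#' Writes the label volume (TIFF or NRRD + JSON sidecar including the
#' dividing plane), the efferent and PSD annotation CSVs, the ground truth
#' and the configuration as JSON.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @param format "tiff" or "nrrd".
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, format = c("nrrd", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "tiff") "tif" else "nrrd"
  save_label_volume(phantom$volume, file.path(dir, paste0("labels.", ext)),
                    extra = list(
                      dividing_plane = phantom$truth$dividing_plane))
  write.csv(phantom$annotations$efferent,
            file.path(dir, "efferent_contacts.csv"), row.names = FALSE)
  write.csv(phantom$annotations$psd,
            file.path(dir, "psd_annotations.csv"), row.names = FALSE)
  jsonlite::write_json(phantom$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  cfg <- phantom$config
  cfg$geometry <- list(dx = cfg$geometry$dx, dy = cfg$geometry$dy,
                       dz = cfg$geometry$dz)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Recover the planted ground truth of a phantom
#'
#' Runs the analysis stages needed to compare a phantom against its own
#' ground truth: ribbon reconstruction and synapse linking, fiber
#' classification, orphan detection, mito-peak localization and
#' mitochondrial profile statistics. Used by the package's recovery and
#' acceptance tests and by validation scripts.
#'
#' @param phantom Result of [generate_phantom()].
#' @param params [analysis_params()].
#' @return list with `status_match` (per-fiber classification equality),
#'   `status_measured`/`status_planted` (counts), `multiplicity_measured`/
#'   `multiplicity_planted`, `orphans_measured`/`orphans_planted`,
#'   `peak_abs_dev` (per-fiber |measured - planted| mito-peak center, NA
#'   where no peak was planted), `mito_stats`
#'   ([mito_profile_stats()] result), `mean_retraction_um` and the
#'   underlying `classification`, `links` and `ribbons`.
#' @export
recover_phantom <- function(phantom, params = analysis_params()) {
  volume <- phantom$volume
  truth <- phantom$truth
  ribbons <- reconstruct_ribbons(volume)
  links <- link_synapses(volume, ribbons, psd = phantom$annotations$psd,
                         pairing_radius = params$pairing_radius_nm)
  cls <- classify_fibers(volume, links$synapses, params$contact_min_run)
  orph <- detect_orphans(volume, ribbons, params$orphan_radius_nm)

  fibers <- labels_of_class(volume, "ANF")
  series <- lapply(fibers, function(f) {
    build_fiber_series(volume, f, fiber_profile = FALSE)
  })
  names(series) <- as.character(fibers)
  parts <- lapply(series, partition_terminal, params$terminal_slices,
                  params$peak_window)
  peaks <- vapply(parts, function(p) p$mito_peak_center, numeric(1))

  ids <- vapply(truth$fibers, function(x) x$id, integer(1))
  t_status <- vapply(truth$fibers, function(x) x$status, character(1))
  t_peak <- vapply(truth$fibers, function(x) {
    if (is.null(x$mito_peak_center) || is.na(x$mito_peak_center))
      NA_real_ else as.numeric(x$mito_peak_center)
  }, numeric(1))
  m_status <- cls$status[match(ids, cls$fiber_id)]
  m_peak <- peaks[as.character(ids)]

  mult_m <- if (nrow(links$synapses) > 0) {
    as.integer(table(factor(pmin(links$synapses$n_ribbons, 3),
                            levels = 1:3)))
  } else c(0L, 0L, 0L)
  retr <- cls$distance_to_nearest_ihc_nm[
    cls$status == "nonsynaptic_retracted"]
  list(
    status_match = all(m_status == t_status),
    status_measured = table(factor(m_status, levels = sort(unique(
      c(m_status, t_status))))),
    status_planted = table(factor(t_status, levels = sort(unique(
      c(m_status, t_status))))),
    multiplicity_measured = mult_m,
    multiplicity_planted = as.integer(truth$counts$multiplicity),
    orphans_measured = length(orph),
    orphans_planted = length(truth$orphan_ribbon_ids),
    peak_abs_dev = abs(m_peak - t_peak),
    mito_stats = mito_profile_stats(series),
    mean_retraction_um = if (length(retr)) mean(retr) / 1000 else NA,
    classification = cls, links = links, ribbons = ribbons,
    series = series
  )
}
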