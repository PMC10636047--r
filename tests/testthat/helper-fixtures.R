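# Shared fixtures: a memoized reduced-lattice phantom, constructed label
# volumes, a fabricated fiber series, and independent brute-force oracles
# (3D flood fill, window search, exact Mann-Whitney enumeration).

phantom_cache <- new.env(parent = emptyenv())

# reduced-lattice phantom (one IHC, 8 fibers) reused across test files
small_phantom <- function(seed = 11) {
  key <- paste0("small", seed)
  if (!exists(key, envir = phantom_cache)) {
    cfg <- phantom_config(
      n_fibers = 8, n_ihc = 1, dims = c(256L, 256L, 400L),
      frac_nonsynaptic = 0.25, frac_contact_among_nonsynaptic = 0.5,
      ribbon_multiplicity_probs = c(0.5, 0.25, 0.25),
      orphan_ribbons = 1, ihc_radius_um = 3)
    assign(key, suppressWarnings(generate_phantom(cfg, seed = seed)),
           envir = phantom_cache)
  }
  get(key, envir = phantom_cache)
}

small_params <- function(phantom) {
  pl <- phantom$truth$dividing_plane
  analysis_params(dividing_plane = dividing_plane(unlist(pl$point),
                                                  unlist(pl$normal)))
}

# build a label volume from an integer array and a named class map
make_volume <- function(arr, classes, parents = NULL,
                        geometry = voxel_geometry()) {
  ids <- sort(unique(arr[arr != 0]))
  cls <- unname(classes[as.character(ids)])
  par <- if (is.null(parents)) NA_integer_ else
    unname(parents[as.character(ids)])
  label_volume(arr, geometry, label_table(ids, cls, par))
}

# fabricate a fiber series from per-slice mitochondrial areas
fake_series <- function(mito_areas, start_slice = 0,
                        fiber_area = 1e5, circ = 1) {
  n <- length(mito_areas)
  idx <- start_slice + seq_len(n) - 1L
  structure(
    list(fiber_id = 1L,
         slices = data.frame(
           slice_index = idx,
           fiber_area_nm2 = rep(fiber_area, n),
           fiber_circularity = rep(circ, n),
           mito_total_area_nm2 = mito_areas,
           mito_profile_count = as.integer(mito_areas > 0),
           rejected = FALSE),
         profile_areas = lapply(mito_areas, function(a)
           if (a > 0) a else numeric(0)),
         terminus_slice = idx[n]),
    class = "fiber_series")
}

# --- independent oracles -------------------------------------------------

# brute-force 3D connected components by breadth-first flood fill
oracle_cc3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  comp <- array(0L, dim = d)
  nb <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, ds = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  if (connectivity == 6) nb <- nb[rowSums(abs(nb)) == 1, ]
  k <- 0L
  idx <- which(mask != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    if (comp[p[1], p[2], p[3]] != 0) next
    k <- k + 1L
    queue <- matrix(p, 1)
    comp[p[1], p[2], p[3]] <- k
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (j in seq_len(nrow(nb))) {
        q <- cur + nb[j, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] != 0 && comp[q[1], q[2], q[3]] == 0) {
          comp[q[1], q[2], q[3]] <- k
          queue <- rbind(queue, q)
        }
      }
    }
  }
  comp
}

# brute-force 3D hole filling: flood 6-connected background from borders
oracle_fill_holes <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, dim = d)
  border <- which(
    slice.index(mask, 1) %in% c(1, d[1]) |
      slice.index(mask, 2) %in% c(1, d[2]) |
      slice.index(mask, 3) %in% c(1, d[3]))
  queue <- border[mask[border] == 0]
  seen[queue] <- TRUE
  nb_off <- c(-1, 1, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
  ind <- arrayInd(seq_len(prod(d)), d)
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    ci <- ind[cur, ]
    for (k in 1:6) {
      ax <- c(1, 1, 2, 2, 3, 3)[k]
      q <- ci
      q[ax] <- q[ax] + ifelse(k %% 2 == 1, -1, 1)
      if (any(q < 1) || any(q > d)) next
      lin <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
      if (mask[lin] == 0 && !seen[lin]) {
        seen[lin] <- TRUE
        queue <- c(queue, lin)
      }
    }
  }
  out <- mask
  out[mask == 0 & !seen] <- 1L
  out
}

# brute-force best 50-slice window (mean mito area, ties toward terminus)
oracle_peak_window <- function(areas, terminal_rows, w) {
  k <- length(terminal_rows)
  w <- min(w, k)
  best <- -Inf
  best_start <- NA
  for (s in 1:(k - w + 1)) {
    m <- mean(areas[terminal_rows[s:(s + w - 1)]])
    if (m >= best) { best <- m; best_start <- s }
  }
  terminal_rows[best_start]
}

# exact two-sided Mann-Whitney p by enumeration over all rank assignments
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  # ranks are a permutation of 1..N (no ties assumed): enumerate every
  # size-n1 subset of ranks group 1 could receive
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}
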