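# End-to-end orchestration: phantom generation or volume loading, fiber
# morphometry, ribbon/synapse analysis, efferent scoring, spatial
# classification and the stack report, with reproducible seeds and a
# manifest in every output directory.

#' Default analysis parameters
#'
#' Every parameter defaults to its study value: terminal region 200
#' slices (4 um at 20-nm sections), 50-slice mito-peak window, 0.8
#' pre-terminal circularity threshold, profile counting every 10th slice,
#' 200-nm ribbon pairing radius, 500-nm orphan radius, 5-slice contact
#' persistence, and the four efferent criteria (5 vesicles within 2
#' vesicle-diameters, apposition + thickening, 5 consecutive slices).
#'
#' @param terminal_slices,peak_window,circularity_threshold,stride,
#'   pairing_radius_nm,orphan_radius_nm,contact_min_run Stage parameters.
#' @param criteria An [efferent_criteria()].
#' @param dividing_plane Optional [dividing_plane()] (phantoms carry
#'   theirs in the sidecar).
#' @return Named list of parameters.
#' @export
analysis_params <- function(terminal_slices = 200, peak_window = 50,
                            circularity_threshold = 0.8, stride = 10,
                            pairing_radius_nm = 200,
                            orphan_radius_nm = 500, contact_min_run = 5,
                            criteria = efferent_criteria(),
                            dividing_plane = NULL) {
  list(terminal_slices = terminal_slices, peak_window = peak_window,
       circularity_threshold = circularity_threshold, stride = stride,
       pairing_radius_nm = pairing_radius_nm,
       orphan_radius_nm = orphan_radius_nm,
       contact_min_run = contact_min_run, criteria = criteria,
       dividing_plane = dividing_plane)
}

#' Analyze one stack end to end
#'
#' Runs fiber morphometry (series, terminal partition, circularity
#' filter, profile statistics), ribbon reconstruction and synapse
#' linking, fiber classification, orphan detection, efferent scoring and
#' modiolar/pillar assignment, and assembles the per-fiber table and the
#' stack report.
#'
#' @param volume A [label_volume()].
#' @param annotations List with optional `efferent` and `psd` annotation
#'   data.frames (as produced by [generate_phantom()] or read from CSV).
#' @param params [analysis_params()].
#' @param group,stack_id Report metadata.
#' @return list: `fibers` (per-fiber table), `series` (fiber series,
#'   filtered), `partitions`, `ribbons`, `links`, `classification`,
#'   `orphans`, `plaques`, `efferent_summary`, `mito_stats`, `report`.
#' @export
analyze_stack <- function(volume, annotations = list(),
                          params = analysis_params(),
                          group = NA_character_, stack_id = "stack") {
  stopifnot(inherits(volume, "label_volume"))
  g <- volume$geometry
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  fibers <- labels_of_class(volume, "ANF")

  series <- stage("fiber_morphometry", {
    out <- list()
    for (f in fibers) {
      s <- build_fiber_series(volume, f)
      p <- partition_terminal(s, params$terminal_slices,
                              params$peak_window)
      s <- filter_preterminal_circularity(s, p,
                                          params$circularity_threshold)
      out[[as.character(f)]] <- list(series = s, partition = p)
    }
    out
  })

  ribbons <- stage("ribbon_reconstruction", reconstruct_ribbons(volume))
  links <- stage("synapse_linking",
                 link_synapses(volume, ribbons, psd = annotations$psd,
                               pairing_radius = params$pairing_radius_nm))
  classification <- stage("fiber_classification",
                          classify_fibers(volume, links$synapses,
                                          params$contact_min_run))
  orphans <- stage("orphan_detection",
                   detect_orphans(volume, ribbons,
                                  params$orphan_radius_nm))

  plaques <- stage("efferent_scoring", {
    if (!is.null(annotations$efferent) &&
        nrow(annotations$efferent) > 0) {
      score_contacts(annotations$efferent, params$criteria, g)
    } else {
      data.frame(contact_id = integer(), fiber_id = integer(),
                 efferent_id = integer(), slice_start = integer(),
                 slice_end = integer(), n_slices = integer(),
                 surface_area_um2 = numeric(), plaque_id = integer())
    }
  })
  eff_sum <- summarize_efferent(fibers, plaques)

  mito_stats <- stage("mito_profile_stats",
                      mito_profile_stats(lapply(series,
                                                function(x) x$series),
                                         params$stride))

  # per-fiber locations for side assignment: synapse centroid when
  # synaptic, closest IHC approach otherwise
  fiber_tab <- stage("group_table", {
    rows <- lapply(fibers, function(f) {
      se <- series[[as.character(f)]]
      cl <- classification[classification$fiber_id == f, ]
      reg <- fiber_region_summary(se$series, se$partition)
      syn <- links$synapses[links$synapses$fiber_id == f, , drop = FALSE]
      loc <- NULL
      if (nrow(syn) > 0) {
        rid <- links$ribbon_synapse$ribbon_id[
          links$ribbon_synapse$fiber_id == f]
        rr <- ribbons[ribbons$ribbon_id %in% rid, , drop = FALSE]
        loc <- vox_to_nm(cbind(mean(rr$centroid_row),
                               mean(rr$centroid_col),
                               mean(rr$centroid_slice)), g)[1, ]
      } else if (is.finite(cl$near_row)) {
        loc <- vox_to_nm(cbind(cl$near_row, cl$near_col, cl$near_slice),
                         g)[1, ]
      }
      pf <- mito_stats$per_fiber[mito_stats$per_fiber$fiber_id == f, ]
      ef <- eff_sum[eff_sum$fiber_id == f, ]
      data.frame(
        stack_id = stack_id, group = group, fiber_id = f,
        status = cl$status,
        distance_to_nearest_ihc_nm = cl$distance_to_nearest_ihc_nm,
        nearest_ihc = cl$nearest_ihc,
        side = NA_character_,
        loc_x = if (is.null(loc)) NA_real_ else loc[1],
        loc_y = if (is.null(loc)) NA_real_ else loc[2],
        loc_z = if (is.null(loc)) NA_real_ else loc[3],
        terminus_slice = reg$terminus_slice,
        mito_peak_center = reg$mito_peak_center,
        truncated = reg$truncated,
        peak_mean_area_nm2 = reg$peak_mean_area_nm2,
        terminal_mean_area_nm2 = reg$terminal_mean_area_nm2,
        preterminal_mean_area_nm2 = reg$preterminal_mean_area_nm2,
        peak_sum_area_nm2 = reg$peak_sum_area_nm2,
        terminal_sum_area_nm2 = reg$terminal_sum_area_nm2,
        preterminal_sum_area_nm2 = reg$preterminal_sum_area_nm2,
        mito_profiles_per_slice = pf$mean_count,
        mito_mean_profile_area_nm2 = pf$mean_area_nm2,
        n_synapses = nrow(syn),
        n_ribbons = if (nrow(syn)) sum(syn$n_ribbons) else 0L,
        total_ribbon_volume_nm3 = if (nrow(syn))
          sum(syn$total_volume_nm3) else NA_real_,
        total_ribbon_length_nm = if (nrow(syn))
          sum(syn$total_length_nm) else NA_real_,
        efferent_plaque_count = ef$plaque_count,
        efferent_total_area_um2 = ef$total_area_um2
      )
    })
    do.call(rbind, rows)
  })

  if (!is.null(params$dividing_plane)) {
    has_loc <- is.finite(fiber_tab$loc_x)
    fiber_tab$side[has_loc] <- assign_side(
      as.matrix(fiber_tab[has_loc, c("loc_x", "loc_y", "loc_z")]),
      params$dividing_plane)
  }

  span_um <- dim(volume$labels)[2] * g$dx / 1000
  report <- stack_report(fiber_tab, links$synapses, span_um, orphans,
                         group = group, stack_id = stack_id)
  list(fibers = fiber_tab,
       series = series,
       ribbons = ribbons, links = links,
       classification = classification, orphans = orphans,
       plaques = plaques, efferent_summary = eff_sum,
       mito_stats = mito_stats, report = report)
}

#' Run configuration
#'
#' Either a phantom preset (`preset` + `seed`) or an input directory
#' written by [write_phantom()] / [save_label_volume()], plus analysis
#' parameters and an output directory.
#'
#' @param preset "control", "day1" or "week1" (phantom input), or NULL.
#' @param input_dir Directory with `labels.nrrd`/`labels.tif`, sidecar and
#'   annotation CSVs (volume input), or NULL.
#' @param seed Integer seed controlling every source of randomness.
#' @param params [analysis_params()].
#' @param out_dir Output directory (NULL: nothing written).
#' @param n_fibers Optional fiber-count override for phantom presets.
#' @param phantom_overrides Named list of further [phantom_config()]
#'   overrides applied on top of the preset (e.g. a reduced lattice).
#' @return A `run_config` list.
#' @export
run_config <- function(preset = NULL, input_dir = NULL, seed = 1L,
                       params = analysis_params(), out_dir = NULL,
                       n_fibers = NULL, phantom_overrides = list()) {
  if (is.null(preset) == is.null(input_dir)) {
    stop("specify exactly one of preset or input_dir")
  }
  structure(list(preset = preset, input_dir = input_dir,
                 seed = as.integer(seed), params = params,
                 out_dir = out_dir, n_fibers = n_fibers,
                 phantom_overrides = phantom_overrides),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Generates (or loads) the stack, runs [analyze_stack()], and writes the
#' report JSON, the per-fiber, synapse, classification and plaque CSVs,
#' and a manifest (config hash, seed, package version). Identical config
#' and seed produce byte-identical report JSON.
#'
#' @param config A [run_config()].
#' @return The [analyze_stack()] result (invisibly returns paths in
#'   attribute `"paths"` when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$input_dir)) {
    dir <- config$input_dir
    vol_path <- c(file.path(dir, "labels.nrrd"),
                  file.path(dir, "labels.tif"),
                  file.path(dir, "labels.tiff"))
    vol_path <- vol_path[file.exists(vol_path)][1]
    if (is.na(vol_path)) {
      stop("no label volume (labels.nrrd / labels.tif) found in ", dir)
    }
    volume <- load_label_volume(vol_path)
    side <- jsonlite::read_json(sidecar_path(vol_path),
                                simplifyVector = TRUE)
    ann <- list()
    eff_path <- file.path(dir, "efferent_contacts.csv")
    psd_path <- file.path(dir, "psd_annotations.csv")
    if (file.exists(eff_path)) ann$efferent <-
        read_efferent_contacts(eff_path)
    if (file.exists(psd_path)) ann$psd <- read.csv(psd_path)
    params <- config$params
    if (is.null(params$dividing_plane) &&
        !is.null(side$dividing_plane)) {
      params$dividing_plane <- dividing_plane(
        unlist(side$dividing_plane$point),
        unlist(side$dividing_plane$normal))
    }
    group <- side$group %||% NA_character_
    stack_id <- basename(dir)
  } else {
    cfg <- do.call(group_preset,
                   c(list(group = config$preset,
                          n_fibers = config$n_fibers),
                     config$phantom_overrides))
    phantom <- generate_phantom(cfg, seed = config$seed)
    volume <- phantom$volume
    ann <- phantom$annotations
    params <- config$params
    if (is.null(params$dividing_plane)) {
      pl <- phantom$truth$dividing_plane
      params$dividing_plane <- dividing_plane(unlist(pl$point),
                                              unlist(pl$normal))
    }
    group <- config$preset
    stack_id <- paste0("phantom_", config$preset, "_seed",
                       config$seed)
  }

  res <- analyze_stack(volume, ann, params, group = group,
                       stack_id = stack_id)

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(res$report),
                         file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    write.csv(res$fibers, file.path(out, "fibers.csv"),
              row.names = FALSE)
    write.csv(res$links$synapses, file.path(out, "synapses.csv"),
              row.names = FALSE)
    write.csv(res$classification, file.path(out, "classification.csv"),
              row.names = FALSE)
    write.csv(res$plaques, file.path(out, "plaques.csv"),
              row.names = FALSE)
    cfg_json <- file.path(out, "run_config.json")
    cfg_ser <- list(preset = config$preset, input_dir = config$input_dir,
                    seed = config$seed,
                    params = params_for_manifest(config$params))
    jsonlite::write_json(cfg_ser, cfg_json, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    manifest <- list(
      config_md5 = unname(tools::md5sum(cfg_json)),
      seed = config$seed,
      package = "anfmorph",
      version = as.character(utils::packageVersion("anfmorph")),
      created = "run"
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    attr(res, "paths") <- list.files(out, full.names = TRUE)
  }
  res
}

params_for_manifest <- function(params) {
  p <- params
  p$criteria <- unclass(p$criteria)
  if (!is.null(p$dividing_plane)) p$dividing_plane <-
      unclass(p$dividing_plane)
  p
}
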