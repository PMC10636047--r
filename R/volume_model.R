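# Data model and I/O for anisotropic label volumes.
#
# A label volume is a 3D integer array indexed [row, col, slice] together
# with a VoxelGeometry and a label table mapping every non-zero label id to
# a structural class (IHC, ANF, MITO, RIBBON, EFFERENT, BACKGROUND) and,
# for mitochondria (and optionally ribbons), the parent ANF label.
# All voxel coordinates and slice indices in user-facing output are 0-based;
# distances are physical nanometres with anisotropic scaling.

LABEL_CLASSES <- c("IHC", "ANF", "MITO", "RIBBON", "EFFERENT", "BACKGROUND")

#' Voxel geometry of an anisotropic EM stack
#'
#' Records the in-plane pixel pitch and the slice (milling) thickness in
#' nanometres, plus the axis convention that increasing slice index runs
#' toward the IHC apex. Defaults match a FIB-SEM acquisition with 5 nm
#' in-plane resolution and 20 nm sections (voxel volume 500 nm^3).
#'
#' @param dx,dy In-plane pitch (nm) along columns (x) and rows (y).
#' @param dz Slice thickness (nm).
#' @param slice_toward_apex Logical flag: increasing slice index approaches
#'   the IHC apex (the convention assumed by the terminal-region analysis).
#' @return A `voxel_geometry` object.
#' @export
voxel_geometry <- function(dx = 5, dy = 5, dz = 20,
                           slice_toward_apex = TRUE) {
  stopifnot(dx > 0, dy > 0, dz > 0)
  structure(
    list(dx = dx, dy = dy, dz = dz,
         slice_toward_apex = isTRUE(slice_toward_apex)),
    class = "voxel_geometry"
  )
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf(
    "<voxel_geometry> dx=%g dy=%g dz=%g nm (voxel %g nm^3), slices %s apex\n",
    x$dx, x$dy, x$dz, voxel_volume(x),
    if (x$slice_toward_apex) "toward" else "away from"))
  invisible(x)
}

#' Voxel volume in nm^3
#' @param geometry A [voxel_geometry()].
#' @export
voxel_volume <- function(geometry) geometry$dx * geometry$dy * geometry$dz

# pitch vector in the (row, col, slice) order used by the C++ kernels
pitch_vec <- function(geometry) c(geometry$dy, geometry$dx, geometry$dz)

#' Build a label table
#'
#' @param label Integer label ids (non-zero).
#' @param class Class per label, one of IHC, ANF, MITO, RIBBON, EFFERENT,
#'   BACKGROUND.
#' @param parent Parent ANF label id for MITO (required) and RIBBON
#'   (optional annotation) labels; NA otherwise.
#' @return data.frame with columns label, class, parent.
#' @export
label_table <- function(label = integer(), class = character(),
                        parent = NA_integer_) {
  label <- as.integer(label)
  stopifnot(length(class) == length(label))
  if (length(parent) == 1) parent <- rep(as.integer(parent), length(label))
  bad <- setdiff(unique(class), LABEL_CLASSES)
  if (length(bad) > 0) {
    stop("unknown label class(es): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(label)) stop("duplicated label ids in label table")
  data.frame(label = label, class = class, parent = as.integer(parent))
}

#' Construct a validated label volume
#'
#' @param labels 3D integer array indexed `[row, col, slice]`.
#' @param geometry A [voxel_geometry()].
#' @param label_table data.frame as from [label_table()]; must cover every
#'   non-zero label present in the lattice.
#' @return A `label_volume` object (list with `labels`, `geometry`, `table`
#'   and a cached per-label `summary` of voxel counts, bounding boxes and
#'   centroids, all 0-based).
#' @export
label_volume <- function(labels, geometry, label_table) {
  if (length(dim(labels)) != 3) {
    stop("labels must be a 3D array (got ",
         length(dim(labels)) %||% 1, " dimensions)")
  }
  if (is.double(labels)) {
    if (any(labels != trunc(labels), na.rm = TRUE)) {
      stop("labels must contain integer voxel values")
    }
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) stop("labels must be an integer array")
  if (anyNA(labels)) stop("labels must not contain NA voxels")
  stopifnot(inherits(geometry, "voxel_geometry"))
  d <- dim(labels)
  summ <- cpp_label_summary(labels, d[1], d[2], d[3])
  missing_ids <- setdiff(summ$label, label_table$label)
  if (length(missing_ids) > 0) {
    stop("label(s) present in lattice but absent from label table: ",
         paste(sort(missing_ids), collapse = ", "))
  }
  mito <- label_table[label_table$class == "MITO", , drop = FALSE]
  if (nrow(mito) > 0) {
    anf_ids <- label_table$label[label_table$class == "ANF"]
    bad <- mito$label[!is.na(mito$parent) & !(mito$parent %in% anf_ids)]
    if (length(bad) > 0) {
      stop("MITO label(s) whose parent is not an ANF label: ",
           paste(sort(bad), collapse = ", "))
    }
    if (anyNA(mito$parent)) {
      warning(sum(is.na(mito$parent)), " MITO label(s) without a parent",
              " fiber; see assign_mito_parents()")
    }
  }
  structure(
    list(labels = labels, geometry = geometry, table = label_table,
         summary = summ),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cls <- table(x$table$class[match(x$summary$label, x$table$label)])
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d labels (%s)\n",
              d[1], d[2], d[3], nrow(x$summary),
              paste(sprintf("%s:%d", names(cls), as.integer(cls)),
                    collapse = ", ")))
  print(x$geometry)
  invisible(x)
}

# label ids of a given class
labels_of_class <- function(volume, class) {
  ids <- volume$table$label[volume$table$class == class]
  ids[ids %in% volume$summary$label]
}

# 0-based bbox c(rmin, rmax, cmin, cmax, smin, smax) of a set of label ids
label_bbox <- function(volume, ids) {
  s <- volume$summary[volume$summary$label %in% ids, , drop = FALSE]
  if (nrow(s) == 0) stop("label(s) have no voxels: ",
                         paste(ids, collapse = ", "))
  as.integer(c(min(s$rmin), max(s$rmax), min(s$cmin), max(s$cmax),
               min(s$smin), max(s$smax)))
}

#' Per-slice 2D profiles of one label
#'
#' One row per in-plane 8-connected component of the label per slice.
#' Area is component pixel count times dx*dy; `perimeter_nm` is the exact
#' voxel-edge (crack) contour length; `circularity` is the normalized
#' isoperimetric index 4*pi*A/P^2 computed with a Crofton (4-direction)
#' perimeter estimate so that smooth discs score close to 1 (capped at 1,
#' as tiny profiles otherwise exceed it through discretization).
#'
#' @param volume A [label_volume()].
#' @param label_id A label id present in the label table.
#' @param fill_holes Fill enclosed 2D background (e.g. carved-out organelle
#'   labels) before measuring, so the profile reflects the outer contour.
#' @return data.frame with columns label_id, slice_index (0-based),
#'   area_nm2, perimeter_nm, circularity, centroid_row, centroid_col
#'   (0-based voxel units), ordered by slice_index.
#' @export
slice_profiles <- function(volume, label_id, fill_holes = FALSE) {
  stopifnot(inherits(volume, "label_volume"))
  if (!label_id %in% volume$table$label) {
    stop("unknown label id: ", label_id)
  }
  g <- volume$geometry
  d <- dim(volume$labels)
  if (!label_id %in% volume$summary$label) {
    return(data.frame(label_id = integer(), slice_index = integer(),
                      area_nm2 = numeric(), perimeter_nm = numeric(),
                      circularity = numeric(), centroid_row = numeric(),
                      centroid_col = numeric()))
  }
  bb <- label_bbox(volume, label_id)
  st <- cpp_mask_slice_stats(volume$labels, d[1], d[2], d[3],
                             as.integer(label_id),
                             union_mode = fill_holes,
                             fill_holes = fill_holes, bbox = bb)
  profile_frame(st, g, label_id)
}

# shared conversion from cpp slice stats to the profile data.frame
profile_frame <- function(st, g, label_id) {
  circ <- if (abs(g$dx - g$dy) < 1e-9) {
    pmin(1, 4 * pi * st$area_px / pmax(st$crofton_px, 1e-12)^2)
  } else {
    warning("circularity undefined for anisotropic in-plane pitch; NA")
    rep(NA_real_, nrow(st))
  }
  out <- data.frame(
    label_id = rep(as.integer(label_id), nrow(st)),
    slice_index = st$slice,
    area_nm2 = st$area_px * g$dx * g$dy,
    perimeter_nm = st$edges_r * g$dx + st$edges_c * g$dy,
    circularity = circ,
    centroid_row = st$centroid_row,
    centroid_col = st$centroid_col
  )
  out[order(out$slice_index), , drop = FALSE]
}

#' Physical distance between two voxel coordinates
#'
#' Euclidean distance after scaling each axis by its pitch. Coordinates are
#' 0-based `(row, col, slice)` triples.
#'
#' @param a,b Numeric length-3 voxel coordinates (row, col, slice).
#' @param geometry A [voxel_geometry()].
#' @return Distance in nm.
#' @export
physical_distance <- function(a, b, geometry) {
  stopifnot(length(a) == 3, length(b) == 3)
  sqrt(((a[1] - b[1]) * geometry$dy)^2 +
       ((a[2] - b[2]) * geometry$dx)^2 +
       ((a[3] - b[3]) * geometry$dz)^2)
}

# voxel (row, col, slice) -> physical (x, y, z) nm; accepts a matrix
vox_to_nm <- function(coords, geometry) {
  coords <- rbind(coords)
  cbind(x = coords[, 2] * geometry$dx,
        y = coords[, 1] * geometry$dy,
        z = coords[, 3] * geometry$dz)
}

# ------------------------------------------------------------------- I/O

#' Save a label volume to disk
#'
#' Writes a multi-page TIFF (`.tif`/`.tiff`, 16-bit, one page per slice) or
#' an NRRD file (`.nrrd`, int32), plus a JSON sidecar
#' (`<basename>.json`) holding the voxel geometry, the label table and any
#' extra metadata (e.g. the modiolar/pillar dividing plane).
#'
#' @param volume A [label_volume()].
#' @param path Output path ending in `.tif`, `.tiff` or `.nrrd`.
#' @param extra Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
save_label_volume <- function(volume, path, extra = list()) {
  stopifnot(inherits(volume, "label_volume"))
  ext <- tolower(tools::file_ext(path))
  d <- dim(volume$labels)
  if (ext %in% c("tif", "tiff")) {
    if (max(volume$labels) > 65535) {
      stop("TIFF export limited to label ids <= 65535; use NRRD")
    }
    pages <- lapply(seq_len(d[3]), function(s) {
      volume$labels[, , s] / 65535
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "LZW")
  } else if (ext == "nrrd") {
    write_nrrd(volume$labels, path, pitch_vec(volume$geometry))
  } else {
    stop("unsupported extension '", ext, "' (use .tif, .tiff or .nrrd)")
  }
  side <- c(list(
    geometry = list(dx = volume$geometry$dx, dy = volume$geometry$dy,
                    dz = volume$geometry$dz,
                    slice_toward_apex = volume$geometry$slice_toward_apex),
    label_table = volume$table
  ), extra)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Load a label volume from disk
#'
#' Reads a multi-page TIFF or NRRD label stack. Geometry and label table
#' are taken from the JSON sidecar written by [save_label_volume()] unless
#' supplied explicitly. Voxel data must be integer-valued; every non-zero
#' label must be covered by the label table.
#'
#' @param path Path to a `.tif`/`.tiff`/`.nrrd` file.
#' @param geometry Optional [voxel_geometry()] overriding the sidecar.
#' @param label_table Optional label table overriding the sidecar.
#' @return A [label_volume()].
#' @export
load_label_volume <- function(path, geometry = NULL, label_table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  side <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  }
  if (is.null(geometry)) {
    if (is.null(side$geometry)) {
      stop("no geometry given and no sidecar found for ", path)
    }
    geometry <- voxel_geometry(side$geometry$dx, side$geometry$dy,
                               side$geometry$dz,
                               side$geometry$slice_toward_apex %||% TRUE)
  }
  if (is.null(label_table)) {
    if (is.null(side$label_table)) {
      stop("no label table given and no sidecar found for ", path)
    }
    lt <- side$label_table
    label_table <- label_table(lt$label, lt$class, lt$parent)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(dim(pages[[1]])) != 2) stop("non-3D input: ", path)
    arr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
    for (s in seq_along(pages)) {
      pg <- pages[[s]]
      if (any(pg != trunc(pg))) stop("non-integer voxel data in ", path)
      arr[, , s] <- as.integer(pg)
    }
  } else if (ext == "nrrd") {
    arr <- read_nrrd(path)
  } else {
    stop("unsupported extension '", ext, "'")
  }
  label_volume(arr, geometry, label_table)
}

# Minimal NRRD writer (raw gzip-encoded int32, attached header).
write_nrrd <- function(arr, path, pitch) {
  d <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# anfmorph label volume",
    "type: int32",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "encoding: gzip",
    "endian: little",
    sprintf("spacings: %g %g %g", pitch[1], pitch[2], pitch[3]),
    ""
  )
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con,
            eos = NULL)
  raw <- writeBin(as.integer(arr), raw(), size = 4L, endian = "little")
  writeBin(memCompress(raw, type = "gzip"), con)
  invisible(path)
}

read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  nl <- which(raw_all == as.raw(10))
  hdr_end <- NA
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("malformed NRRD header in ", path)
  hdr <- strsplit(rawToChar(raw_all[seq_len(hdr_end)]), "\n")[[1]]
  fields <- list()
  for (ln in hdr[-1]) {
    if (grepl("^#", ln) || !grepl(":", ln)) next
    kv <- strsplit(ln, ":\\s*")[[1]]
    fields[[tolower(kv[1])]] <- kv[2]
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3) stop("non-3D input: ", path)
  type <- fields$type
  enc <- fields$encoding %||% "raw"
  payload <- raw_all[(hdr_end + 1L):length(raw_all)]
  if (enc == "gzip") payload <- memDecompress(payload, type = "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  size <- switch(type, int32 = 4L, uint16 = 2L, int16 = 2L, uchar = 1L,
                 uint8 = 1L, stop("unsupported NRRD type: ", type))
  n <- prod(sizes)
  vals <- readBin(payload, "integer", n = n, size = size,
                  endian = fields$endian %||% "little",
                  signed = size > 2 || type %in% c("int16"))
  array(as.integer(vals), dim = sizes)
}

#' Export slice profiles for a set of labels as CSV
#'
#' @param volume A [label_volume()].
#' @param label_ids Labels to profile (default: all present).
#' @param path Output CSV path.
#' @return The combined profile data.frame, invisibly.
#' @export
export_slice_profiles <- function(volume, label_ids = NULL, path) {
  ids <- label_ids %||% volume$summary$label
  out <- do.call(rbind, lapply(ids, function(i) slice_profiles(volume, i)))
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Infer mitochondrion parent fibers by majority adjacency
#'
#' Fallback for label tables lacking parent ids: each MITO label is
#' assigned to the ANF label sharing the most voxel faces with it (an
#' organelle carved out of a fiber mask is enclosed by it, so face
#' adjacency plays the role of mask overlap). Assignments made this way
#' are flagged in the returned table's `parent_inferred` column.
#'
#' @param volume A [label_volume()] whose MITO rows may lack parents.
#' @return The volume with its label table's missing MITO parents filled
#'   in where an adjacent fiber exists.
#' @export
assign_mito_parents <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  tab <- volume$table
  need <- tab$class == "MITO" & is.na(tab$parent)
  tab$parent_inferred <- FALSE
  if (!any(need)) {
    volume$table <- tab
    return(volume)
  }
  d <- dim(volume$labels)
  maxlab <- max(tab$label)
  code <- integer(maxlab + 1)
  code[tab$label[tab$class == "MITO"] + 1L] <- 1L
  code[tab$label[tab$class == "ANF"] + 1L] <- 2L
  adj <- cpp_pair_adjacency(volume$labels, d[1], d[2], d[3], code, 1L, 2L)
  for (m in tab$label[need]) {
    a <- adj[adj$a_label == m, , drop = FALSE]
    if (nrow(a) == 0) next
    faces <- tapply(a$n_faces, a$b_label, sum)
    i <- which(tab$label == m)
    tab$parent[i] <- as.integer(names(which.max(faces)))
    tab$parent_inferred[i] <- TRUE
  }
  still <- tab$class == "MITO" & is.na(tab$parent)
  if (any(still)) {
    warning(sum(still), " MITO label(s) without any adjacent fiber;",
            " parent left NA")
  }
  volume$table <- tab
  volume
}
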