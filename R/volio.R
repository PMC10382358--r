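# Volume and mesh I/O. The in-memory voxel_volume is the canonical container;
# NIfTI is the reference on-disk format. A minimal DICOM slice reader/writer
# (explicit VR little endian, geometry tags only) is provided because MRI
# source data ship as DICOM stacks.

STAGE_LEVELS <- c("naive", "insertion", "v2", "v5", "v10", "post_removal")
SITE_LEVELS <- c("abdomen", "thigh", "arm")

#' Voxel volume with physical spacing
#'
#' A 3-D grayscale array with anisotropic spacing, physical origin and stage /
#' site labels. Array axes are `(depth within slice, lateral within slice,
#' slice)`; voxel `(i, j, k)` (1-based) has its center at
#' `origin_mm + (c(i, j, k) - 0.5) * spacing_mm`.
#'
#' @param intensities non-negative 3-D numeric array.
#' @param spacing_mm positive length-3 spacing `(row, col, slice)` in mm.
#' @param origin_mm physical coordinate of the stack corner (mm).
#' @param stage stage label, one of `r paste(STAGE_LEVELS, collapse=", ")` or `NA`.
#' @param site site label (`abdomen`, `thigh`, `arm`) or `NA`.
#' @return Object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing_mm, origin_mm = c(0, 0, 0),
                         stage = NA_character_, site = NA_character_) {
  if (length(dim(intensities)) != 3L || !length(intensities)) {
    stop("intensities must be a non-empty 3-D array")
  }
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("spacing_mm must be three strictly positive values")
  }
  if (!is.na(stage)) stage <- match.arg(stage, STAGE_LEVELS)
  if (!is.na(site)) site <- match.arg(site, SITE_LEVELS)
  structure(list(intensities = intensities, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm), stage = stage, site = site,
                 orientation = "axial"),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume %s/%s: %s voxels, spacing %s mm>\n",
              x$site, x$stage, paste(dim(x$intensities), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x")))
  invisible(x)
}

#' Voxel volume in mm^3
#' @param volume a [voxel_volume()] (or anything with `$spacing_mm`).
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_size_mm3 <- function(volume) prod(volume$spacing_mm)

# Physical coordinates of voxel centers along each axis.
#' @noRd
.axis_coords <- function(volume) {
  d <- dim(volume$intensities)
  lapply(1:3, function(a) {
    volume$origin_mm[a] + (seq_len(d[a]) - 0.5) * volume$spacing_mm[a]
  })
}

#' Ordered series of co-located scans for one injection site
#'
#' @param volumes named list of [voxel_volume()] objects keyed by stage; gaps
#'   in the canonical stage order are allowed.
#' @param site site label shared by all volumes.
#' @param transforms optional named list of [rigid_transform()]s mapping each
#'   stage's image frame into the series reference frame.
#' @param fiducials optional named list of fiducial sets per stage.
#' @return Object of class `scan_series`.
#' @export
scan_series <- function(volumes, site, transforms = NULL, fiducials = NULL) {
  stages <- names(volumes)
  if (is.null(stages) || !all(stages %in% STAGE_LEVELS)) {
    stop("volumes must be a named list keyed by stage")
  }
  ord <- order(match(stages, STAGE_LEVELS))
  volumes <- volumes[ord]
  for (v in volumes) {
    if (!identical(v$site, site)) stop("all volumes in a series must share the site")
  }
  structure(list(volumes = volumes, site = site,
                 transforms = transforms, fiducials = fiducials),
            class = "scan_series")
}

#' @export
print.scan_series <- function(x, ...) {
  cat(sprintf("<scan_series %s: stages %s>\n", x$site,
              paste(names(x$volumes), collapse = ", ")))
  invisible(x)
}

#' Write a volume as NIfTI
#'
#' @param volume a [voxel_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$intensities)
  RNifti::`pixdim<-`(img, volume$spacing_mm) -> img
  RNifti::writeNifti(img, path)
  meta <- list(origin_mm = volume$origin_mm, stage = volume$stage,
               site = volume$site)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume from disk
#'
#' Supports NIfTI files (with an optional JSON sidecar carrying origin and
#' stage/site labels, as written by [write_volume()]) and DICOM series
#' directories as written by [write_dicom_series()].
#'
#' @param path a `.nii`/`.nii.gz` file or a directory of DICOM slices.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(.read_dicom_series(path))
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  sp <- signif(RNifti::pixdim(img), 7)  # stored as float32 in the header
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) {
    stop("volume is missing voxel spacing metadata (pixdim)")
  }
  meta <- list(origin_mm = c(0, 0, 0), stage = NA_character_, site = NA_character_)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    m <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta[names(m)] <- m
  }
  voxel_volume(array(as.numeric(img), dim = dim(img)), sp[1:3],
               origin_mm = as.numeric(meta$origin_mm),
               stage = meta$stage, site = meta$site)
}

#' Write a phantom series to a directory
#'
#' One NIfTI file per stage (`<stage>.nii.gz`) plus a `truth.json` sidecar when
#' ground truth is supplied.
#'
#' @param series a [scan_series()].
#' @param dir output directory (created if needed).
#' @param truth optional phantom truth object to serialise alongside.
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (st in names(series$volumes)) {
    write_volume(series$volumes[[st]], file.path(dir, paste0(st, ".nii.gz")))
  }
  if (!is.null(truth)) write_truth(truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a phantom series directory
#' @param dir a directory written by [write_series()].
#' @return A [scan_series()].
#' @export
read_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (!length(files)) stop("no NIfTI stages found in ", dir)
  vols <- lapply(files, read_volume)
  stages <- vapply(vols, function(v) v$stage, character(1))
  if (any(is.na(stages))) {
    stages[is.na(stages)] <- sub("\\.nii(\\.gz)?$", "", basename(files[is.na(stages)]))
  }
  names(vols) <- stages
  scan_series(vols, site = vols[[1]]$site)
}

# ---- mesh I/O --------------------------------------------------------------

#' Write a triangle mesh
#'
#' ASCII STL, PLY or OBJ with vertex units in mm. Open sheets are permitted
#' (and flagged as non-watertight in the PLY comment header).
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format `"stl"`, `"ply"` or `"obj"`; default guessed from `path`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply", "obj")) stop("unsupported mesh format: ", format)
  }
  if (nrow(mesh$faces) == 0L) stop("degenerate mesh: no triangles")
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "stl") {
    writeLines("solid depotmri", con)
    a <- v[f[, 1L], , drop = FALSE]; b <- v[f[, 2L], , drop = FALSE]
    c3 <- v[f[, 3L], , drop = FALSE]
    e1 <- b - a; e2 <- c3 - a
    n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    nn <- sqrt(rowSums(n^2)); nn[nn == 0] <- 1
    n <- n / nn
    txt <- sprintf(paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
                          "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
                          "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
                   n[, 1], n[, 2], n[, 3], a[, 1], a[, 2], a[, 3],
                   b[, 1], b[, 2], b[, 3], c3[, 1], c3[, 2], c3[, 3])
    writeLines(txt, con)
    writeLines("endsolid depotmri", con)
  } else if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("comment units mm; watertight %s",
                         if (isTRUE(mesh$closed)) "true" else "false"),
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else {
    writeLines("# depotmri mesh, units mm", con)
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Read a triangle mesh written by [write_mesh()]
#' @param path an ASCII STL, PLY or OBJ file.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "stl") {
    vl <- grep("^\\s*vertex ", lines, value = TRUE)
    m <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(x) as.numeric(x[2:4])))
    key <- paste(m[, 1], m[, 2], m[, 3])
    uk <- !duplicated(key)
    vid <- match(key, key[uk])
    faces <- matrix(vid, ncol = 3L, byrow = TRUE)
    surface_mesh(m[uk, , drop = FALSE], faces, closed = TRUE)
  } else if (ext == "ply") {
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
    closed <- any(grepl("watertight true", lines))
    h <- which(lines == "end_header")
    v <- do.call(rbind, lapply(strsplit(lines[h + seq_len(nv)], "\\s+"), as.numeric))
    f <- do.call(rbind, lapply(strsplit(lines[h + nv + seq_len(nf)], "\\s+"),
                               function(x) as.integer(x[2:4]) + 1L))
    surface_mesh(v, f, closed = closed)
  } else if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) as.integer(x[2:4])))
    surface_mesh(v, f)
  } else stop("unsupported mesh format: ", ext)
}

# ---- truth sidecar ---------------------------------------------------------

#' Serialise phantom ground truth to JSON
#' @param truth a `phantom_truth` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  enc <- unclass(truth)
  enc$stages <- lapply(enc$stages, function(s) {
    s$transform <- if (is.null(s$transform)) NULL else unclass(s$transform)
    s$depot_mask <- if (is.null(s$depot_mask)) NULL else
      list(dim = dim(s$depot_mask), idx = which(s$depot_mask))
    s$void_mask <- if (is.null(s$void_mask)) NULL else
      list(dim = dim(s$void_mask), idx = which(s$void_mask))
    s
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a phantom ground-truth sidecar
#' @param path a JSON file written by [write_truth()].
#' @return A `phantom_truth`-like list.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$stages <- lapply(tr$stages, function(s) {
    for (fld in c("depot_mask", "void_mask")) {
      if (!is.null(s[[fld]]) && !is.null(s[[fld]]$dim)) {
        m <- array(FALSE, unlist(s[[fld]]$dim))
        idx <- unlist(s[[fld]]$idx)
        if (length(idx)) m[idx] <- TRUE
        s[[fld]] <- m
      }
    }
    for (fld in c("id_sc_depth", "sc_im_depth", "thickness_map"))
      if (!is.null(s[[fld]])) s[[fld]] <- as.matrix(s[[fld]])
    s
  })
  class(tr) <- "phantom_truth"
  tr
}

# ---- minimal DICOM ---------------------------------------------------------
# Explicit VR little endian, one file per slice, 16-bit grayscale. Only the
# geometry and pixel tags the pipeline needs; not a conformant implementation.

.dcm_elem <- function(group, elem, vr, value) {
  hdr <- writeBin(c(group, elem), raw(), size = 2, endian = "little")
  if (vr %in% c("OB", "OW")) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value), raw(), size = 4, endian = "little"), value)
  } else {
    val <- charToRaw(as.character(value))
    if (length(val) %% 2L) val <- c(val, charToRaw(" "))
    c(hdr, charToRaw(vr),
      writeBin(length(val), raw(), size = 2, endian = "little"), val)
  }
}

#' Export a volume as a minimal DICOM series
#'
#' Writes one explicit-VR little-endian file per slice with PixelSpacing,
#' SliceThickness, SpacingBetweenSlices, ImagePositionPatient and 16-bit pixel
#' data. Intended for interchange tests, not PACS use.
#'
#' @param volume a [voxel_volume()].
#' @param dir output directory.
#' @param slice_thickness_mm acquired slice thickness (defaults to pitch - 1).
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(volume, dir,
                               slice_thickness_mm = max(volume$spacing_mm[3] - 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arr <- volume$intensities
  d <- dim(arr)
  scl <- max(arr)
  pix <- if (scl > 0) round(arr / scl * 4095) else arr
  for (k in seq_len(d[3])) {
    sl <- pix[, , k]
    px <- writeBin(as.integer(t(sl)), raw(), size = 2, endian = "little")
    # Rows/Columns use the binary US VR with 2-byte values
    us <- function(group, elem, val) {
      c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
        charToRaw("US"), writeBin(2L, raw(), size = 2, endian = "little"),
        writeBin(as.integer(val), raw(), size = 2, endian = "little"))
    }
    body <- c(
      .dcm_elem(0x0008L, 0x0060L, "CS", "MR"),
      .dcm_elem(0x0018L, 0x0050L, "DS", sprintf("%g", slice_thickness_mm)),
      .dcm_elem(0x0018L, 0x0088L, "DS", sprintf("%g", volume$spacing_mm[3])),
      .dcm_elem(0x0020L, 0x0013L, "IS", sprintf("%d", k)),
      .dcm_elem(0x0020L, 0x0032L, "DS",
                sprintf("%g\\%g\\%g", volume$origin_mm[1], volume$origin_mm[2],
                        volume$origin_mm[3] + (k - 0.5) * volume$spacing_mm[3])),
      us(0x0028L, 0x0010L, d[1]), us(0x0028L, 0x0011L, d[2]),
      .dcm_elem(0x0028L, 0x0030L, "DS",
                sprintf("%g\\%g", volume$spacing_mm[1], volume$spacing_mm[2])),
      .dcm_elem(0x0028L, 0x1053L, "DS", sprintf("%.9g", if (scl > 0) scl / 4095 else 1)),
      .dcm_elem(0x7FE0L, 0x0010L, "OW", px))
    con <- file(file.path(dir, sprintf("slice_%03d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM")), con)
    writeBin(body, con)
    close(con)
  }
  meta <- list(stage = volume$stage, site = volume$site,
               origin_mm = volume$origin_mm)
  jsonlite::write_json(meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @noRd
.read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM file: ", path)
  }
  i <- 133L
  out <- list()
  n <- length(raw)
  while (i + 8L <= n + 1L) {
    group <- readBin(raw[i:(i + 1L)], "integer", size = 2, endian = "little", signed = FALSE)
    elem <- readBin(raw[(i + 2L):(i + 3L)], "integer", size = 2, endian = "little", signed = FALSE)
    vr <- rawToChar(raw[(i + 4L):(i + 5L)])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- readBin(raw[(i + 8L):(i + 11L)], "integer", size = 4, endian = "little")
      off <- 12L
    } else {
      len <- readBin(raw[(i + 6L):(i + 7L)], "integer", size = 2, endian = "little", signed = FALSE)
      off <- 8L
    }
    val <- raw[(i + off):(i + off + len - 1L)]
    tag <- sprintf("%04X,%04X", group, elem)
    out[[tag]] <- if (vr == "US") {
      readBin(val, "integer", size = 2, endian = "little", signed = FALSE)
    } else if (vr %in% c("OW", "OB")) val else trimws(rawToChar(val))
    i <- i + off + len
  }
  out
}

#' @noRd
.read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (!length(files)) stop("no DICOM slices found in ", dir)
  slices <- lapply(files, .read_dicom_slice)
  ps <- slices[[1]][["0028,0030"]]
  if (is.null(ps)) stop("DICOM series is missing the PixelSpacing (0028,0030) tag")
  sp12 <- as.numeric(strsplit(ps, "\\\\")[[1]])
  sbs <- slices[[1]][["0018,0088"]]
  if (is.null(sbs)) stop("DICOM series is missing the SpacingBetweenSlices (0018,0088) tag")
  sp3 <- as.numeric(sbs)
  rows <- slices[[1]][["0028,0010"]]; cols <- slices[[1]][["0028,0011"]]
  scl <- as.numeric(slices[[1]][["0028,1053"]] %||% "1")
  zpos <- vapply(slices, function(s) {
    as.numeric(strsplit(s[["0020,0032"]], "\\\\")[[1]][3])
  }, numeric(1))
  if (length(zpos) > 2L) {
    dz <- diff(sort(zpos))
    if (max(abs(dz - sp3)) > 1e-3) stop("inconsistent slice spacing within DICOM series")
  }
  ord <- order(zpos)
  arr <- array(0, c(rows, cols, length(slices)))
  for (k in seq_along(ord)) {
    px <- readBin(slices[[ord[k]]][["7FE0,0010"]], "integer", n = rows * cols,
                  size = 2, endian = "little", signed = FALSE)
    arr[, , k] <- t(matrix(px, nrow = cols)) * scl
  }
  meta <- list(stage = NA_character_, site = NA_character_, origin_mm = c(0, 0, 0))
  side <- file.path(dir, "series.json")
  if (file.exists(side)) {
    m <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta[names(m)] <- m
  }
  voxel_volume(arr, c(sp12, sp3), origin_mm = as.numeric(meta$origin_mm),
               stage = meta$stage, site = meta$site)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
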