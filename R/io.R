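# Volumes are stored with spacing in mm (= um/1000). The NIfTI/NRRD spatial
# transform records the centre of the first voxel, i.e. origin + voxel/2.

.vol_payload <- function(x) {
  if (inherits(x, "brain_mask")) {
    list(grid = x$grid, value = array(as.integer(x$inside), dim = x$grid$shape),
         integer = TRUE)
  } else if (inherits(x, "coverage_mask")) {
    list(grid = x$grid, value = array(as.integer(x$covered), dim = x$grid$shape),
         integer = TRUE)
  } else if (inherits(x, "density_field")) {
    list(grid = x$grid, value = x$value, integer = FALSE)
  } else if (inherits(x, "expression_map")) {
    v <- x$value
    v[is.na(v)] <- -1   # outside-coverage sentinel for export
    list(grid = x$grid, value = v, integer = FALSE)
  } else if (inherits(x, "fraction_template")) {
    v <- x$fraction
    v[is.na(v)] <- -1L  # -1 marks voxels outside mask or series span
    list(grid = x$grid, value = v, integer = TRUE)
  } else {
    stop("don't know how to export this object as a volume", call. = FALSE)
  }
}

#' Write a volume to NIfTI-1 or NRRD
#'
#' Masks and fraction templates are written as integer label volumes
#' (templates use -1 for voxels outside the mask or series span); density
#' fields and expression maps as floating point (map voxels outside coverage
#' are exported as -1). Spacing is recorded in mm (um/1000); the spatial
#' offset records the centre of the first voxel. The format is chosen by
#' extension: `.nii`/`.nii.gz` (NIfTI-1 via RNifti) or `.nrrd` (NRRD0004,
#' raw little-endian encoding).
#'
#' @param x A `brain_mask`, `coverage_mask`, `density_field`,
#'   `expression_map`, `fraction_template`, or a bare array (then `grid`
#'   must be given).
#' @param path Output file path.
#' @param grid Required when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (is.array(x)) {
    stopifnot(inherits(grid, "voxel_grid"))
    payload <- list(grid = grid, value = x, integer = is.integer(x) || is.logical(x))
    if (is.logical(x)) payload$value <- array(as.integer(x), dim = dim(x))
  } else {
    payload <- .vol_payload(x)
  }
  g <- payload$grid
  sp_mm <- g$voxel_size / 1000
  off_mm <- g$origin / 1000 + sp_mm / 2
  ext <- tolower(sub("^.*?((\\.nii(\\.gz)?)|(\\.nrrd))$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(payload$value)
    RNifti::pixdim(img) <- rep(sp_mm, 3)
    q <- structure(diag(c(sp_mm, sp_mm, sp_mm, 1)), code = 2L)
    q[1:3, 4] <- off_mm
    RNifti::qform(img) <- q
    RNifti::writeNifti(img, path,
                       datatype = if (payload$integer) "int32" else "double")
  } else if (ext == ".nrrd") {
    write_nrrd(payload$value, path, spacing_mm = sp_mm, origin_mm = off_mm,
               integer = payload$integer)
  } else {
    stop("unsupported volume extension (use .nii, .nii.gz or .nrrd): ", path,
         call. = FALSE)
  }
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path A `.nii`, `.nii.gz` or `.nrrd` file with isotropic spacing
#'   (anisotropic spacing is an error: the grid contract is isotropic).
#' @return A list with elements `value` (array; integer for label volumes)
#'   and `grid` (a `voxel_grid` in micrometres).
#' @export
read_volume <- function(path) {
  ext <- tolower(sub("^.*?((\\.nii(\\.gz)?)|(\\.nrrd))$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    xf <- RNifti::xform(img)
    off <- xf[1:3, 4]
    value <- as.array(img)
    attributes(value) <- list(dim = dim(img))
    if (grepl("int", RNifti::niftiHeader(img)$datatype_string %||% "", fixed = TRUE) ||
        RNifti::niftiHeader(img)$datatype %in% c(2L, 4L, 8L, 256L, 512L, 768L)) {
      storage.mode(value) <- "integer"
    }
  } else if (ext == ".nrrd") {
    nr <- read_nrrd(path)
    sp <- nr$spacing_mm
    off <- nr$origin_mm
    value <- nr$value
  } else {
    stop("unsupported volume extension: ", path, call. = FALSE)
  }
  if (diff(range(sp)) > 1e-6) {
    stop(sprintf("anisotropic spacing (%s mm): the grid contract is isotropic",
                 paste(signif(sp, 6), collapse = " x ")), call. = FALSE)
  }
  vs_um <- mean(sp) * 1000
  origin_um <- off * 1000 - vs_um / 2
  list(value = value,
       grid = voxel_grid(dim(value), vs_um, origin_um))
}

# --- minimal NRRD0004 reader/writer (raw little-endian encoding) ----------
# Written in-package: the stack has no R NRRD support. Covers 3D scalar
# volumes with per-axis spacing and origin, which is all the package emits.

write_nrrd <- function(value, path, spacing_mm, origin_mm, integer = FALSE) {
  type <- if (integer) "int32" else "double"
  if (integer) storage.mode(value) <- "integer" else storage.mode(value) <- "double"
  dims <- dim(value)
  stopifnot(length(dims) == 3L)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- c(
    "NRRD0004",
    "# txtomo volume",
    paste0("type: ", type),
    "dimension: 3",
    "space: right-anterior-superior",
    paste0("sizes: ", paste(dims, collapse = " ")),
    paste0("space directions: ",
           sprintf("(%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
                   spacing_mm, spacing_mm, spacing_mm)),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    paste0("space origin: ",
           sprintf("(%.9g,%.9g,%.9g)", origin_mm[1], origin_mm[2], origin_mm[3])),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(value), con, size = if (integer) 4L else 8L,
           endian = "little")
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[1-5]$", magic)) stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header", call. = FALSE)
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  type <- fields[["type"]]
  if (is.null(type)) stop("NRRD header missing 'type'", call. = FALSE)
  dims <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(dims) != 3L) stop("only 3D NRRD volumes are supported", call. = FALSE)
  enc <- fields[["encoding"]] %||% "raw"
  if (enc != "raw") stop("only raw NRRD encoding is supported", call. = FALSE)
  endian <- fields[["endian"]] %||% "little"
  nums <- function(s) as.numeric(regmatches(s, gregexpr("-?[0-9.eE+-]+", s))[[1]])
  spacing <- if (!is.null(fields[["space directions"]])) {
    v <- nums(fields[["space directions"]])
    m <- matrix(v, nrow = 3L, byrow = TRUE)
    sqrt(rowSums(m^2))
  } else if (!is.null(fields[["spacings"]])) {
    nums(fields[["spacings"]])
  } else rep(1, 3)
  origin <- if (!is.null(fields[["space origin"]])) {
    nums(fields[["space origin"]])
  } else rep(0, 3)
  n <- prod(dims)
  value <- switch(type,
    "int32" = , "int" = , "signed int" =
      readBin(con, integer(), n = n, size = 4L, endian = endian),
    "int16" = , "short" =
      readBin(con, integer(), n = n, size = 2L, endian = endian),
    "uint8" = , "uchar" =
      readBin(con, integer(), n = n, size = 1L, signed = FALSE, endian = endian),
    "double" =
      readBin(con, numeric(), n = n, size = 8L, endian = endian),
    "float" =
      readBin(con, numeric(), n = n, size = 4L, endian = endian),
    stop("unsupported NRRD type: ", type, call. = FALSE)
  )
  if (length(value) != n) stop("truncated NRRD data", call. = FALSE)
  dim(value) <- dims
  list(value = value, spacing_mm = spacing, origin_mm = origin)
}

# --- sectioning-design serialization --------------------------------------

#' Write a sectioning design to JSON
#'
#' Each series is serialized as
#' `{series_id, normal, width_um, offset_um, n_fractions}`.
#'
#' @param design List of `sectioning_series`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(all(vapply(design, inherits, logical(1), "sectioning_series")))
  lst <- lapply(unname(design), function(s) {
    list(series_id = s$series_id, normal = s$normal, width_um = s$width,
         offset_um = s$offset, n_fractions = s$n_fractions)
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sectioning design from JSON
#' @param path JSON file written by [write_design()].
#' @return Named list of `sectioning_series`.
#' @export
read_design <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  out <- lapply(lst, function(s) {
    sectioning_series(s$series_id, as.numeric(s$normal), s$width_um,
                      s$offset_um, s$n_fractions)
  })
  names(out) <- vapply(out, `[[`, character(1), "series_id")
  out
}

# --- fraction matrix CSV ---------------------------------------------------

#' Read a probe x fraction intensity matrix from CSV/TSV
#'
#' The first column holds probe ids; remaining columns are fractions named
#' by series and slab ("S1".."Ho7"). An optional companion file of the same
#' shape holds present/absent flags (logical or P/A/M calls); when absent,
#' all probes are treated as present (with a warning).
#'
#' @param path CSV or TSV intensity file.
#' @param flags_path Optional CSV/TSV flags file with identical layout.
#' @return A [fraction_data()] object.
#' @export
read_fraction_matrix <- function(path, flags_path = NULL) {
  df <- readr::read_delim(path, delim = if (grepl("\\.tsv$", path)) "\t" else ",",
                          show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) stop("matrix needs a probe-id column plus fraction columns",
                          call. = FALSE)
  probes <- as.character(df[[1]])
  if (anyDuplicated(probes)) {
    stop("duplicate probe ids: ", paste(head(unique(probes[duplicated(probes)]), 3),
                                        collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric intensity values", call. = FALSE)
  if (any(is.na(m))) stop("missing intensity values", call. = FALSE)
  if (any(m < 0)) stop("negative intensities", call. = FALSE)
  rownames(m) <- probes
  present <- NULL
  if (!is.null(flags_path)) {
    fdf <- readr::read_delim(flags_path,
                             delim = if (grepl("\\.tsv$", flags_path)) "\t" else ",",
                             show_col_types = FALSE, progress = FALSE)
    if (!identical(dim(fdf), dim(df)) ||
        !identical(names(fdf)[-1], names(df)[-1]) ||
        !identical(as.character(fdf[[1]]), probes)) {
      stop("flags file does not match the intensity matrix layout", call. = FALSE)
    }
    fm <- as.matrix(fdf[, -1, drop = FALSE])
    present <- if (is.logical(fm)) fm else toupper(as.character(fm)) %in% c("P", "TRUE", "1")
    dim(present) <- dim(fm)
    rownames(present) <- probes
    colnames(present) <- colnames(m)
  } else {
    warning("no flags file given: treating every probe as present", call. = FALSE)
  }
  fraction_data(m, present)
}

#' Write a fraction matrix (and optional flags) to CSV
#'
#' @param fd A `fraction_data`.
#' @param path Output CSV for intensities.
#' @param flags_path Optional output CSV for present flags.
#' @return `path`, invisibly.
#' @export
write_fraction_matrix <- function(fd, path, flags_path = NULL) {
  stopifnot(inherits(fd, "fraction_data"))
  df <- tibble::as_tibble(fd$intensity, rownames = "probe_id")
  readr::write_csv(df, path, progress = FALSE)
  if (!is.null(flags_path)) {
    fdf <- tibble::as_tibble(fd$present, rownames = "probe_id")
    readr::write_csv(fdf, flags_path, progress = FALSE)
  }
  invisible(path)
}

#' Read sphere-area definitions from a JSON centroid list
#'
#' Expects a JSON array of objects
#' `{area_id, x_um, y_um, z_um, diameter_um}`.
#'
#' @param path JSON file of centroids.
#' @param grid A `voxel_grid`.
#' @param mirror Build bilateral (x-mirrored) areas.
#' @param coverage Optional coverage/brain mask for centroid validation.
#' @return List of `area_label`s.
#' @export
read_areas <- function(path, grid, mirror = FALSE, coverage = NULL) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(lst, function(a) {
    sphere_area(grid, c(a$x_um, a$y_um, a$z_um),
                diameter = a$diameter_um %||% 500,
                area_id = a$area_id %||% "area",
                mirror = mirror, coverage = coverage)
  })
}

#' Export an expression map with its JSON sidecar
#'
#' Writes the map volume (float; -1 outside coverage) and a sidecar
#' `<path>.json` recording `probe_id`, `threshold`, `keep_fraction` and
#' `series_ids`.
#'
#' @param map An `expression_map`.
#' @param path Volume path (`.nii`, `.nii.gz` or `.nrrd`).
#' @param series_ids Optional series labels recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, series_ids = NULL) {
  stopifnot(inherits(map, "expression_map"))
  write_volume(map, path)
  sidecar <- list(
    probe_id = map$probe_id,
    threshold = map$cutoff$threshold,
    keep_fraction = map$cutoff$keep_fraction,
    series_ids = series_ids
  )
  jsonlite::write_json(sidecar[!vapply(sidecar, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
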