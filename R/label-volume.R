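# MRI-like label volumes: rasterization of a parametric stem into an integer
# voxel array, and NRRD import/export.

#' Volume specification for label volumes
#'
#' The default mirrors the MSME acquisition geometry used for culm imaging:
#' a 4.2 x 4.2 x 13 mm field of view at a 168 x 168 x 26 matrix. Label codes:
#' 0 background, 1 culm matrix, 2 inner bundle, 3 outer bundle.
#'
#' @param shape integer vector (nx, ny, nz).
#' @param field_of_view numeric vector (fx, fy, fz) in mm.
#' @return object of class `volume_spec` with derived `voxel_size`.
#' @export
volume_spec <- function(shape = c(168L, 168L, 26L),
                        field_of_view = c(4.2, 4.2, 13)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape <= 0L)) {
    cf_stop("shape must be three positive integers", "cf_parameter_error")
  }
  if (length(field_of_view) != 3L || any(!is.finite(field_of_view)) ||
      any(field_of_view <= 0)) {
    cf_stop("field_of_view must be three positive lengths (mm)",
            "cf_parameter_error")
  }
  structure(
    list(
      shape = shape, field_of_view = as.numeric(field_of_view),
      voxel_size = as.numeric(field_of_view) / shape,
      labels = c(background = 0L, matrix = 1L, inner = 2L, outer = 3L)
    ),
    class = "volume_spec"
  )
}

#' @export
print.volume_spec <- function(x, ...) {
  cat(sprintf(
    "volume_spec: %d x %d x %d voxels over %.1f x %.1f x %.1f mm (voxel %.4g x %.4g x %.4g mm)\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$field_of_view[1], x$field_of_view[2], x$field_of_view[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  invisible(x)
}

#' Rasterize a stem geometry into a label volume
#'
#' Voxels whose center lies within `bundle_radius` of a fibre centerline get
#' that fibre's ring label (nearest centerline wins; exact distance ties go to
#' the outer ring, then to the lower fibre index). Remaining voxel centers
#' with `Ri <= r <= Ro` are culm matrix, everything else background. The stem
#' axis is centred in the field of view; slice z-centres start at half a voxel.
#'
#' @param geometry a `stem_geometry`.
#' @param spec a [volume_spec()].
#' @return 3D integer array of class `label_volume` with attributes `spec`
#'   and `provenance` (the generating parameters).
#' @export
rasterize_label_volume <- function(geometry, spec = volume_spec()) {
  stopifnot(inherits(geometry, "stem_geometry"))
  p <- geometry$params
  if (2 * p$outer_radius_Ro > min(spec$field_of_view[1:2])) {
    cf_stop(sprintf(
      "stem diameter %.2f mm exceeds the lateral field of view %.2f mm",
      2 * p$outer_radius_Ro, min(spec$field_of_view[1:2])
    ), "cf_spatial_error")
  }
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  vx <- spec$voxel_size[1]; vy <- spec$voxel_size[2]; vz <- spec$voxel_size[3]
  xs <- (seq_len(nx) - 0.5) * vx - spec$field_of_view[1] / 2
  ys <- (seq_len(ny) - 0.5) * vy - spec$field_of_view[2] / 2
  zc <- (seq_len(nz) - 0.5) * vz

  r2 <- outer(xs^2, ys^2, `+`)
  matrix_slice <- r2 >= p$inner_radius_Ri^2 & r2 <= p$outer_radius_Ro^2
  base <- matrix(0L, nx, ny)
  base[matrix_slice] <- 1L

  # order fibres outer-ring first, then id, so equal-distance ties resolve
  # deterministically by keeping the first claimant
  ord <- order(vapply(geometry$fibres, function(f) f$ring != "outer", logical(1)),
               vapply(geometry$fibres, function(f) f$id, integer(1)))
  fibres <- geometry$fibres[ord]
  br <- p$bundle_radius
  br2 <- br^2
  vol <- array(0L, dim = c(nx, ny, nz))

  for (iz in seq_len(nz)) {
    if (zc[iz] > p$length_L) {
      vol[, , iz] <- 0L
      next
    }
    lab <- base
    best <- matrix(Inf, nx, ny)
    for (f in fibres) {
      ctr <- fibre_xy_at(f, zc[iz])
      if (anyNA(ctr)) next
      ix <- which(abs(xs - ctr[1]) <= br)
      iy <- which(abs(ys - ctr[2]) <= br)
      if (!length(ix) || !length(iy)) next
      d2 <- outer((xs[ix] - ctr[1])^2, (ys[iy] - ctr[2])^2, `+`)
      inside <- d2 <= br2
      if (!any(inside)) next
      sub_best <- best[ix, iy, drop = FALSE]
      take <- inside & d2 < sub_best
      if (any(take)) {
        sub_lab <- lab[ix, iy, drop = FALSE]
        sub_lab[take] <- if (f$ring == "outer") 3L else 2L
        sub_best[take] <- d2[take]
        lab[ix, iy] <- sub_lab
        best[ix, iy] <- sub_best
      }
    }
    vol[, , iz] <- lab
  }
  structure(
    vol,
    spec = spec,
    provenance = list(params = p, seed = p$seed),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  tb <- table(factor(as.vector(x), levels = 0:3,
                     labels = c("background", "matrix", "inner", "outer")))
  cat(sprintf("label_volume %s; voxels: %s\n",
              paste(dim(x), collapse = " x "),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Write a label volume as NRRD
#'
#' Minimal NRRD writer (no NRRD package exists for this R installation).
#' Supports `ascii` (plain text, suitable for version control) and `raw`
#' (8-bit little-endian) encodings; voxel size is stored in the `spacings`
#' field in mm.
#'
#' @param volume a `label_volume` (or any 3D integer array with a `spec`
#'   attribute).
#' @param path output file path.
#' @param encoding "ascii" or "raw".
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(volume, path, encoding = c("ascii", "raw")) {
  encoding <- match.arg(encoding)
  spec <- attr(volume, "spec")
  dims <- dim(volume)
  spacings <- if (!is.null(spec)) spec$voxel_size else rep(1, 3)
  header <- c(
    "NRRD0004",
    "# label volume written by culmforce",
    "type: uint8",
    "dimension: 3",
    sprintf("sizes: %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("spacings: %.9g %.9g %.9g", spacings[1], spacings[2], spacings[3]),
    sprintf("encoding: %s", encoding),
    if (encoding == "raw") "endian: little" else NULL
  )
  con <- tryCatch(file(path, "wb"), error = function(e) {
    cf_stop(sprintf("cannot open '%s' for writing", path), "cf_io_error")
  })
  on.exit(close(con))
  writeLines(c(header, ""), con, sep = "\n")
  vals <- as.integer(volume)
  if (encoding == "ascii") {
    # one slice row per line keeps files diffable
    txt <- apply(matrix(vals, nrow = dims[1]), 2, paste, collapse = " ")
    writeLines(txt, con, sep = "\n")
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

#' Read a label volume from NRRD
#'
#' Counterpart of [write_nrrd()]; supports uint8 volumes with ascii or raw
#' little-endian encoding and reconstructs the [volume_spec()] from the
#' `sizes` and `spacings` fields.
#'
#' @param path NRRD file path.
#' @return a `label_volume`.
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) cf_stop(sprintf("no such file: %s", path), "cf_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    header <- c(header, line)
  }
  if (!grepl("^NRRD", header[1])) cf_stop("not an NRRD file", "cf_io_error")
  field <- function(key) {
    ln <- grep(sprintf("^%s:", key), header, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(sprintf("^%s:", key), "", ln[1]))
  }
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  spacings <- as.numeric(strsplit(field("spacings") %||% "1 1 1", "\\s+")[[1]])
  encoding <- field("encoding")
  n <- prod(sizes)
  vals <- if (identical(encoding, "ascii")) {
    scan(text = readLines(con), what = integer(), n = n, quiet = TRUE)
  } else {
    as.integer(readBin(con, "raw", n = n))
  }
  spec <- volume_spec(shape = sizes, field_of_view = sizes * spacings)
  structure(array(as.integer(vals), dim = sizes),
            spec = spec, class = "label_volume")
}
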