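# Extraction of fibre centerlines, counts and inclines from label volumes,
# plus the cylindrical analysis grid the mechanics model runs on.
#
# Coordinate convention (used everywhere): right-handed, stem axis = +z,
# azimuth alpha measured from +x counter-clockwise viewed from +z, degrees,
# half-open angular bins [alpha, alpha + d_alpha).

# Connected components of a logical slice mask (8-connectivity) via a pixel
# adjacency graph. Returns an integer matrix of component labels (0 = FALSE).
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, nx, ny)
  if (!length(idx)) return(out)
  ix <- ((idx - 1L) %% nx) + 1L
  iy <- ((idx - 1L) %/% nx) + 1L
  pos <- match(seq_len(nx * ny), idx) # pixel linear index -> node id
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    jx <- ix + off[1]; jy <- iy + off[2]
    ok <- jx >= 1L & jx <= nx & jy >= 1L & jy <= ny
    if (!any(ok)) next
    nb <- (jy[ok] - 1L) * nx + jx[ok]
    has <- !is.na(pos[nb])
    if (!any(has)) next
    from <- which(ok)[has]
    edges <- c(edges, rbind(from, pos[nb[has]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

# Per-slice centroids (mm) of the connected components of one label.
slice_centroids <- function(slice, label, xs, ys) {
  lab <- label_components(slice == label)
  k <- max(lab)
  if (k == 0L) return(NULL)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  ix <- ((idx - 1L) %% nrow(slice)) + 1L
  iy <- ((idx - 1L) %/% nrow(slice)) + 1L
  cbind(
    x = tapply(xs[ix], comp, mean),
    y = tapply(ys[iy], comp, mean)
  )
}

#' Extract vascular-bundle centerlines from a label volume
#'
#' Per slice, connected components (8-connectivity) of each bundle label are
#' reduced to their centroids; centroids are chained across slices by greedy
#' nearest-neighbour linkage. A chain may skip one slice (with a broken-fibre
#' warning the fibre is split if the gap exceeds one slice); the maximum
#' horizontal jump per slice is three times the drift a 45-degree incline
#' would produce, tolerant to rasterization jitter while preventing identity
#' swaps between neighbouring bundles.
#'
#' @param volume a `label_volume`.
#' @param max_jump_factor multiplier on the 45-degree per-slice drift used as
#'   linkage threshold.
#' @return object of class `fibre_set` (possibly empty) whose fibres carry
#'   ring labels, estimated incline and drift azimuth.
#' @export
extract_bundle_centerlines <- function(volume, max_jump_factor = 3) {
  stopifnot(inherits(volume, "label_volume"))
  spec <- attr(volume, "spec")
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  xs <- (seq_len(nx) - 0.5) * spec$voxel_size[1] - spec$field_of_view[1] / 2
  ys <- (seq_len(ny) - 0.5) * spec$voxel_size[2] - spec$field_of_view[2] / 2
  zc <- (seq_len(nz) - 0.5) * spec$voxel_size[3]
  threshold <- max_jump_factor * spec$voxel_size[3] # drift at 45 deg = dz

  fibres <- list()
  split_warned <- FALSE
  for (ring in c("outer", "inner")) {
    lab <- if (ring == "outer") 3L else 2L
    chains <- list() # each: list(xy matrix, slices, last_slice, open)
    for (iz in seq_len(nz)) {
      cen <- slice_centroids(volume[, , iz], lab, xs, ys)
      # close chains whose gap now exceeds one slice
      for (ci in seq_along(chains)) {
        if (chains[[ci]]$open && iz - chains[[ci]]$last_slice > 2L) {
          chains[[ci]]$open <- FALSE
          if (!split_warned && length(chains[[ci]]$slices) > 1L) {
            split_warned <- TRUE
            cf_warn("broken fibre: centroid chain had a gap > 1 slice; fibre split",
                    "cf_broken_fibre_warning")
          }
        }
      }
      if (is.null(cen)) next
      open_idx <- which(vapply(chains, function(ch) ch$open, logical(1)))
      taken_chain <- logical(length(open_idx))
      taken_cen <- logical(nrow(cen))
      if (length(open_idx)) {
        ends <- t(vapply(chains[open_idx], function(ch) {
          ch$xy[nrow(ch$xy), ]
        }, numeric(2)))
        d <- sqrt(outer(ends[, 1], cen[, 1], `-`)^2 +
                  outer(ends[, 2], cen[, 2], `-`)^2)
        repeat {
          d_ok <- d
          d_ok[taken_chain, ] <- Inf
          d_ok[, taken_cen] <- Inf
          m <- which.min(d_ok)
          if (!length(m) || d_ok[m] > threshold) break
          ci <- ((m - 1L) %% nrow(d)) + 1L
          cj <- ((m - 1L) %/% nrow(d)) + 1L
          ch <- chains[[open_idx[ci]]]
          ch$xy <- rbind(ch$xy, cen[cj, ])
          ch$slices <- c(ch$slices, iz)
          ch$last_slice <- iz
          chains[[open_idx[ci]]] <- ch
          taken_chain[ci] <- TRUE
          taken_cen[cj] <- TRUE
        }
      }
      for (cj in which(!taken_cen)) {
        chains[[length(chains) + 1L]] <- list(
          xy = cen[cj, , drop = FALSE], slices = iz, last_slice = iz,
          open = TRUE
        )
      }
    }
    for (ch in chains) {
      if (length(ch$slices) < 2L) next # single-slice blob: not a fibre
      pts <- cbind(ch$xy, zc[ch$slices])
      f <- new_fibre_centerline(pts, ring, NA_real_, NA_real_,
                                length(fibres) + 1L)
      f$incline_delta <- compute_incline(f)
      steps <- diff(pts)
      drift <- colMeans(steps[, 1:2, drop = FALSE] /
                          steps[, 3, drop = FALSE][, c(1, 1)])
      f$tilt_azimuth_phi <- if (sum(drift^2) > 0) {
        atan2_deg(drift[2], drift[1])
      } else {
        0
      }
      fibres[[length(fibres) + 1L]] <- f
    }
  }
  structure(
    list(fibres = fibres, source_spec = spec,
         provenance = attr(volume, "provenance")),
    class = "fibre_set"
  )
}

#' @export
print.fibre_set <- function(x, ...) {
  rings <- vapply(x$fibres, function(f) f$ring, character(1))
  cat(sprintf("fibre_set: %d fibres (%d outer, %d inner)\n",
              length(x$fibres), sum(rings == "outer"), sum(rings == "inner")))
  invisible(x)
}

#' Fibre set from a parametric geometry
#'
#' Wraps the generator's ground-truth centerlines in the same container the
#' extractor produces, so the mechanics model runs identically on parametric
#' and extracted fibres.
#'
#' @param geometry a `stem_geometry`.
#' @return a `fibre_set` carrying the generating parameters.
#' @export
as_fibre_set <- function(geometry) {
  stopifnot(inherits(geometry, "stem_geometry"))
  structure(
    list(fibres = geometry$fibres, source_spec = NULL,
         provenance = list(params = geometry$params)),
    class = "fibre_set"
  )
}

#' Incline of a fibre centerline
#'
#' Angle between the mean finite-difference tangent and the cross-sectional
#' plane: `atan(1 / mean(per-step horizontal drift per unit z))`, degrees in
#' (0, 90]; 90 when the horizontal drift is zero. Exact on noiseless
#' generated centerlines (their per-step drift is exactly `cot(delta)`).
#'
#' @param fibre a `fibre_centerline` or an n x 3 point matrix.
#' @return incline in degrees.
#' @examples
#' pts <- cbind(x = c(0, 1, 2), y = 0, z = c(0, 1, 2)) # 45 degree drift
#' compute_incline(pts)
#' @export
compute_incline <- function(fibre) {
  pts <- if (inherits(fibre, "fibre_centerline")) fibre$points else as.matrix(fibre)
  if (nrow(pts) < 2L) {
    cf_stop("incline needs at least 2 centerline points", "cf_degenerate_error")
  }
  steps <- diff(pts)
  dz <- steps[, 3]
  if (any(dz <= 0)) {
    cf_stop("degenerate fibre: duplicate or non-increasing z values",
            "cf_degenerate_error")
  }
  drift <- sqrt(steps[, 1]^2 + steps[, 2]^2) / dz
  m <- mean(drift)
  if (m == 0) return(90)
  rad2deg(atan2(1, m))
}

#' Count bundles per ring
#'
#' @param fibres a `fibre_set`.
#' @param wall_area culm wall cross-sectional area in mm^2 used for the
#'   per-area normalization; defaults to `pi * (Ro^2 - Ri^2)` when the set
#'   carries its generating parameters, else `NA`.
#' @return list with `counts` (named: outer, inner), `total` and
#'   `per_area_mm2` (counts normalized per wall area).
#' @export
count_bundles <- function(fibres, wall_area = NULL) {
  stopifnot(inherits(fibres, "fibre_set"))
  rings <- vapply(fibres$fibres, function(f) f$ring, character(1))
  counts <- c(outer = sum(rings == "outer"), inner = sum(rings == "inner"))
  if (is.null(wall_area)) {
    p <- fibres$provenance$params
    wall_area <- if (!is.null(p)) {
      pi * (p$outer_radius_Ro^2 - p$inner_radius_Ri^2)
    } else {
      NA_real_
    }
  }
  list(counts = counts, total = sum(counts),
       per_area_mm2 = counts / wall_area)
}

#' Incline summary per ring
#'
#' @param fibres a `fibre_set`.
#' @return data.frame with per-ring mean and sd of fibre incline (degrees),
#'   plus an attribute `per_fibre` with the individual values.
#' @export
incline_summary <- function(fibres) {
  stopifnot(inherits(fibres, "fibre_set"))
  per <- data.frame(
    fibre_id = vapply(fibres$fibres, function(f) f$id, integer(1)),
    ring = vapply(fibres$fibres, function(f) f$ring, character(1)),
    incline_deg = vapply(fibres$fibres, function(f) {
      f$incline_delta %||% compute_incline(f)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(split(per, per$ring), function(d) {
    data.frame(ring = d$ring[1], n = nrow(d),
               mean_incline_deg = mean(d$incline_deg),
               sd_incline_deg = stats::sd(d$incline_deg))
  }))
  rownames(out) <- NULL
  attr(out, "per_fibre") <- per
  out
}

#' Write a fibre set as CSV
#'
#' Long format: `fibre_id, ring, z_mm, x_mm, y_mm`.
#'
#' @param fibres a `fibre_set`.
#' @param path output CSV path.
#' @export
write_fibre_set <- function(fibres, path) {
  rows <- do.call(rbind, lapply(fibres$fibres, function(f) {
    data.frame(fibre_id = f$id, ring = f$ring,
               z_mm = f$points[, 3], x_mm = f$points[, 1],
               y_mm = f$points[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
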