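# Force-redistribution model: surface pressure loading, magnitude-conserving
# inward propagation with out-of-plane deflection at fibre voxels, per-fibre
# axial/bending partitioning, the 360-degree attack sweep and optimal-attack
# identification.
#
# No elastic constitutive law is applied: the model reproduces force
# bookkeeping only (composition-dependent moduli are deliberately neglected,
# mirroring the simplification of the published model).

#' Impact condition
#'
#' The attack azimuth is where the wind comes from; the force travels along
#' azimuth `attack_azimuth - 180` (toward the stem axis). Default pressure is
#' the fictive 1 N/m^2 surface load; `F_I` is the per-fibre impact force used
#' by the beam partitioning (1 N per fibre).
#'
#' @param attack_azimuth_deg attack azimuth, degrees in 1..360 (values
#'   outside are wrapped with a warning).
#' @param pressure_Nm2 surface pressure in N/m^2 (> 0).
#' @param F_I per-fibre impact force in N (> 0).
#' @return object of class `impact_condition`.
#' @export
impact_condition <- function(attack_azimuth_deg = 180, pressure_Nm2 = 1,
                             F_I = 1) {
  if (!is_scalar_number(pressure_Nm2) || pressure_Nm2 <= 0) {
    cf_stop("pressure must be > 0", "cf_parameter_error")
  }
  if (!is_scalar_number(F_I) || F_I <= 0) {
    cf_stop("per-fibre impact force must be > 0", "cf_parameter_error")
  }
  a <- attack_azimuth_deg
  if (a < 1 || a > 360) {
    cf_warn(sprintf("attack azimuth %.1f outside 1-360, wrapping", a),
            "cf_angle_wrap_warning")
    a <- ((a - 1) %% 360) + 1
  }
  structure(list(attack_azimuth_deg = a, pressure_Nm2 = pressure_Nm2,
                 F_I = F_I),
            class = "impact_condition")
}

attack_direction <- function(impact) {
  a <- impact$attack_azimuth_deg - 180
  c(cos_deg(a), sin_deg(a), 0)
}

#' Apply the surface pressure load
#'
#' Windward outer-surface voxels (outward normal facing the incoming wind)
#' receive `Fin = p x projected voxel area`, directed horizontally toward the
#' axis (azimuth `attack - 180`); all other voxels are zero. Areas are mm^2
#' internally and converted to m^2 for the pressure product, so forces are
#' newtons.
#'
#' @param grid a `cylindrical_grid`.
#' @param impact an [impact_condition()].
#' @return object of class `force_field` holding per-voxel `Fin`/`Fout`
#'   vector arrays (dims alpha x r x z x 3) and the scalar magnitude array.
#' @export
surface_load <- function(grid, impact = impact_condition()) {
  stopifnot(inherits(grid, "cylindrical_grid"))
  if (!inherits(impact, "impact_condition")) {
    cf_stop("impact must be an impact_condition", "cf_parameter_error")
  }
  dims <- grid$dims
  Fin <- array(0, c(dims, 3))
  d_hat <- attack_direction(impact)
  cosd <- cos_deg(grid$alpha_deg - impact$attack_azimuth_deg)
  wind <- which(cosd > 0)
  # projected area per windward surface voxel, mm^2 -> m^2
  mag <- impact$pressure_Nm2 * grid$surface_arc_area * cosd[wind] * 1e-6
  for (k in 1:3) {
    Fin[wind, dims[2], , k] <- mag * d_hat[k]
  }
  structure(
    list(Fin = Fin, Fout = array(0, c(dims, 3)),
         magnitude = vec_norm4(Fin), impact = impact, dims = dims,
         propagated = FALSE, total_load_N = sum(mag) * dims[3],
         conservation_residual = NA_real_),
    class = "force_field"
  )
}

vec_norm4 <- function(a) {
  d <- dim(a)
  sqrt(a[, , , 1]^2 + a[, , , 2]^2 + a[, , , 3]^2)
}

#' Propagate forces through the stem wall
#'
#' For each (alpha, z) column the loaded surface magnitude is passed
#' voxel-to-voxel radially inward. Every voxel re-expresses its incoming
#' force on its own major axes with `|Fout| = |Fin|`: matrix voxels transmit
#' the horizontal load unchanged (their axial component is always zero),
#' while fibre voxels retain the component along the fibre tangent —
#' deflecting it out of the attack plane — and pass the orthogonal
#' remainder inward. Deflected components accumulate into the warp field at
#' the fibre voxel's (alpha, r) cell; propagation stops at the inner wall,
#' where the unspent magnitude is recorded. Magnitude is conserved in the
#' Pythagorean sense per column:
#' `input^2 = sum(warp^2) + residual^2` (checked to 1e-9 relative).
#'
#' @param field a loaded `force_field` from [surface_load()].
#' @param grid the `cylindrical_grid` the field was built on.
#' @return list with the propagated `field` and a `warp_field` (alpha x r
#'   matrix of signed deflected force, N; positive = deflected toward +z).
#' @export
propagate_forces <- function(field, grid) {
  stopifnot(inherits(field, "force_field"), inherits(grid, "cylindrical_grid"))
  dims <- grid$dims
  n_alpha <- dims[1]; n_r <- dims[2]; n_z <- dims[3]
  warp <- matrix(0, n_alpha, n_r)
  inner_residual <- matrix(0, n_alpha, n_z)
  Fin <- field$Fin
  Fout <- field$Fout
  d_hat <- attack_direction(field$impact)
  max_rel_err <- 0
  for (ia in seq_len(n_alpha)) {
    for (iz in seq_len(n_z)) {
      M0 <- field$magnitude[ia, n_r, iz]
      if (M0 == 0) next
      M <- M0
      # transport keeps the horizontal attack direction through matrix
      # voxels (they never generate an axial component); only fibre voxels
      # change it, by rejecting the tangent component out of the plane
      dir <- d_hat
      warp_sq <- 0
      for (ir in n_r:1) {
        Fin[ia, ir, iz, ] <- M * dir
        if (grid$is_fibre[ia, ir, iz]) {
          t_hat <- c(grid$tangent$x[ia, ir, iz], grid$tangent$y[ia, ir, iz],
                     grid$tangent$z[ia, ir, iz])
          ft <- M * sum(dir * t_hat)
          rem <- M * dir - ft * t_hat
          rem_mag <- sqrt(sum(rem^2))
          Fout[ia, ir, iz, ] <- ft * t_hat + rem
          warp[ia, ir] <- warp[ia, ir] + ft
          warp_sq <- warp_sq + ft^2
          M <- rem_mag
          if (rem_mag > 0) dir <- rem / rem_mag
        } else {
          Fout[ia, ir, iz, ] <- M * dir
        }
      }
      inner_residual[ia, iz] <- M
      rel <- abs(M0^2 - (warp_sq + M^2)) / M0^2
      if (rel > max_rel_err) max_rel_err <- rel
    }
  }
  if (max_rel_err > 1e-9) {
    cf_stop(sprintf("force conservation violated (relative error %.3g)",
                    max_rel_err), "cf_conservation_error")
  }
  field$Fin <- Fin
  field$Fout <- Fout
  field$magnitude <- vec_norm4(Fin)
  field$propagated <- TRUE
  field$inner_residual <- inner_residual
  field$conservation_residual <- max_rel_err
  wf <- structure(
    list(warp = warp, alpha_deg = grid$alpha_deg, r_mm = grid$r_mm,
         Ro = grid$Ro, Ri = grid$Ri),
    class = "warp_field"
  )
  list(field = field, warp = wf)
}

#' Cartesian resampling of a warp field
#'
#' Back-transforms the (alpha, r) warp accumulation to a Cartesian raster
#' for rendering.
#'
#' @param warp a `warp_field`.
#' @param n raster size (n x n pixels).
#' @return list with `x`, `y` coordinate vectors and matrix `z` (NA outside
#'   the culm wall).
#' @export
warp_to_cartesian <- function(warp, n = 168) {
  xs <- seq(-warp$Ro, warp$Ro, length.out = n)
  grid_xy <- expand.grid(x = xs, y = xs)
  r <- sqrt(grid_xy$x^2 + grid_xy$y^2)
  a <- atan2_deg(grid_xy$y, grid_xy$x)
  ia <- findInterval(a, c(0, warp$alpha_deg + diff(warp$alpha_deg)[1] / 2),
                     all.inside = TRUE)
  dr <- diff(warp$r_mm)[1]
  ir <- pmin(length(warp$r_mm),
             pmax(1L, as.integer(ceiling((r - warp$Ri) / dr))))
  z <- ifelse(r >= warp$Ri & r <= warp$Ro, warp$warp[cbind(ia, ir)], NA_real_)
  list(x = xs, y = xs, z = matrix(z, n, n))
}

#' Partition an impact force onto a fibre
#'
#' Treats the bundle as a straight beam with the fibre's characteristic
#' incline `delta` and drift azimuth `phi` (tangent
#' `t = (cos d cos phi, cos d sin phi, sin d)`, canonicalized toward +z).
#' With the horizontal impact vector of magnitude `F_I` along azimuth
#' `attack - 180`: the axial force is the signed projection `F_N = F . t`
#' (positive = stretching, the force pulls along the upward tangent;
#' negative = compression) and the bending force is the orthogonal remainder
#' `F_b = sqrt(F_I^2 - F_N^2) >= 0`.
#'
#' @param fibre a `fibre_centerline` (its `incline_delta` /
#'   `tilt_azimuth_phi` fields define the tangent; they are computed from the
#'   points if absent).
#' @param impact an [impact_condition()].
#' @return object of class `fibre_force` with fields `F_N`, `F_b`.
#' @examples
#' f <- structure(list(incline_delta = 60, tilt_azimuth_phi = 0,
#'                     points = NULL, ring = "outer", id = 1L),
#'                class = "fibre_centerline")
#' fibre_force_partition(f, impact_condition(attack_azimuth_deg = 180))
#' @export
fibre_force_partition <- function(fibre, impact = impact_condition()) {
  if (is.na(fibre$incline_delta %||% NA) ||
      is.na(fibre$tilt_azimuth_phi %||% NA)) {
    if (is.null(fibre$points) || nrow(fibre$points) < 2L) {
      cf_stop("fibre has no defined tangent", "cf_degenerate_error")
    }
    fibre$incline_delta <- compute_incline(fibre)
    steps <- diff(fibre$points)
    drift <- colMeans(steps[, 1:2, drop = FALSE] /
                        steps[, 3, drop = FALSE][, c(1, 1)])
    fibre$tilt_azimuth_phi <- atan2_deg(drift[2], drift[1])
  }
  t_hat <- fibre_unit_tangent(fibre)
  d_hat <- attack_direction(impact)
  F_N <- impact$F_I * sum(d_hat * t_hat)
  F_b <- sqrt(max(impact$F_I^2 - F_N^2, 0))
  structure(list(F_N = F_N, F_b = F_b, F_I = impact$F_I,
                 attack_azimuth_deg = impact$attack_azimuth_deg),
            class = "fibre_force")
}

#' @export
print.fibre_force <- function(x, ...) {
  cat(sprintf("fibre_force at %.0f deg: F_N = %.4f N (%s), F_b = %.4f N\n",
              x$attack_azimuth_deg, x$F_N,
              if (x$F_N >= 0) "stretching" else "compression", x$F_b))
  invisible(x)
}

#' Sweep all 360 attack angles
#'
#' For every integer attack azimuth 1..360 degrees, computes the mean over
#' fibres of the normalized bending force `F_b / F_I` (unsigned) and axial
#' force `F_N / F_I` (signed), plus the amplitude (max - min) of each curve.
#'
#' @param fibres a `fibre_set` with at least one fibre.
#' @param impact an [impact_condition()]; its azimuth is ignored (swept).
#' @return data.frame of class `attack_sweep_profile` with columns
#'   `alpha_deg`, `mean_Fb_over_FI`, `mean_FN_over_FI`; amplitudes are
#'   attached as attribute `amplitude`.
#' @export
sweep_attack_angles <- function(fibres, impact = impact_condition()) {
  stopifnot(inherits(fibres, "fibre_set"))
  if (!length(fibres$fibres)) {
    cf_stop("attack sweep needs at least one fibre", "cf_parameter_error")
  }
  Tm <- t(vapply(fibres$fibres, function(f) {
    if (is.na(f$incline_delta %||% NA) || is.na(f$tilt_azimuth_phi %||% NA)) {
      f$incline_delta <- compute_incline(f)
      steps <- diff(f$points)
      drift <- colMeans(steps[, 1:2, drop = FALSE] /
                          steps[, 3, drop = FALSE][, c(1, 1)])
      f$tilt_azimuth_phi <- atan2_deg(drift[2], drift[1])
    }
    fibre_unit_tangent(f)
  }, numeric(3)))
  alpha <- 1:360
  a_d <- alpha - 180
  D <- cbind(cos_deg(a_d), sin_deg(a_d), 0) # 360 x 3 attack directions
  FN <- D %*% t(Tm) # 360 x n_fibres, per unit F_I
  FB <- sqrt(pmax(1 - FN^2, 0))
  prof <- data.frame(
    alpha_deg = alpha,
    mean_Fb_over_FI = rowMeans(FB),
    mean_FN_over_FI = rowMeans(FN)
  )
  class(prof) <- c("attack_sweep_profile", "data.frame")
  attr(prof, "amplitude") <- c(
    Fb = max(prof$mean_Fb_over_FI) - min(prof$mean_Fb_over_FI),
    FN = max(prof$mean_FN_over_FI) - min(prof$mean_FN_over_FI)
  )
  attr(prof, "F_I") <- impact$F_I
  prof
}

#' Amplitude of a sweep profile
#'
#' @param profile an `attack_sweep_profile`.
#' @param which `"FN"` (axial) or `"Fb"` (bending) curve.
#' @return max - min of the selected mean curve.
#' @export
sweep_amplitude <- function(profile, which = c("FN", "Fb")) {
  which <- match.arg(which)
  unname(attr(profile, "amplitude")[which])
}

#' Optimal attack angle
#'
#' The published model reports an "optimal" attack angle without defining
#' the criterion; the default here is the angle maximizing the mean bending
#' load, with the mean absolute axial load available as an alternative.
#' Ties return the smallest angle.
#'
#' @param profile an `attack_sweep_profile`.
#' @param criterion `"bending"` (max mean F_b/F_I, default) or `"axial"`
#'   (max |mean F_N/F_I|).
#' @return attack azimuth in degrees.
#' @export
find_optimal_attack <- function(profile, criterion = c("bending", "axial")) {
  criterion <- match.arg(criterion)
  score <- switch(criterion,
    bending = profile$mean_Fb_over_FI,
    axial = abs(profile$mean_FN_over_FI)
  )
  profile$alpha_deg[which.max(score)]
}

#' Render force and warp fields
#'
#' Writes PNG heatmaps: one cross-section of the per-voxel force magnitude
#' (blue = minimal to red = maximal load, Cartesian back-transform) and a
#' surface plot of the warped cross-sectional plane.
#'
#' @param field a propagated `force_field`.
#' @param warp a `warp_field`.
#' @param grid the `cylindrical_grid`.
#' @param out_dir output directory (created if missing).
#' @param slice 1-based z-slice to render.
#' @return character vector of written paths, invisibly.
#' @export
render_fields <- function(field, warp, grid, out_dir, slice = 1L) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    cf_stop(sprintf("cannot write to '%s'", out_dir), "cf_io_error")
  }
  pal <- grDevices::colorRampPalette(c("blue", "cyan", "yellow", "red"))(256)
  mag <- field$magnitude[, , slice]
  wf_slice <- structure(
    list(warp = mag, alpha_deg = grid$alpha_deg, r_mm = grid$r_mm,
         Ro = grid$Ro, Ri = grid$Ri),
    class = "warp_field"
  )
  cart <- warp_to_cartesian(wf_slice)
  p1 <- file.path(out_dir, sprintf("pressure_slice%02d.png", slice))
  grDevices::png(p1, width = 640, height = 640)
  graphics::image(cart$x, cart$y, cart$z, col = pal, useRaster = TRUE,
                  xlab = "x (mm)", ylab = "y (mm)", asp = 1,
                  main = sprintf("|F| per voxel, slice %d (N)", slice),
                  zlim = range(c(0, cart$z), na.rm = TRUE))
  grDevices::dev.off()
  cartw <- warp_to_cartesian(warp)
  p2 <- file.path(out_dir, "warp_surface.png")
  zw <- cartw$z
  zw[is.na(zw)] <- 0
  grDevices::png(p2, width = 640, height = 640)
  graphics::persp(cartw$x, cartw$y, zw, theta = 30, phi = 35,
                  col = "lightblue", shade = 0.5, ticktype = "detailed",
                  xlab = "x (mm)", ylab = "y (mm)",
                  zlab = "deflected force (N)",
                  main = "Out-of-plane force deflection")
  grDevices::dev.off()
  invisible(c(p1, p2))
}
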