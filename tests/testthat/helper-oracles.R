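# Independent oracles and small fixture builders used across the suite.

# Brute-force two-sided Mann-Whitney p-value: U computed by pair counting
# (not rank sums), symmetric-tail definition over all group assignments.
brute_force_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, `>`)) + 0.5 * sum(outer(xs, ys, `==`))
  }
  u_obs <- u_of(x, y)
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  center <- n1 * (n - n1) / 2
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# Mean silhouette coefficient (euclidean) for a 2-cluster labelling.
mean_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  d <- as.matrix(dist(X))
  sil <- vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(X)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# Closed-form per-fibre axial force for a horizontal unit impact:
# F_N(alpha) = F_I * cos(delta) * cos(alpha - 180 - phi), degrees.
closed_form_FN <- function(alpha_deg, delta_deg, phi_deg, F_I = 1) {
  F_I * cospi(delta_deg / 180) * cospi((alpha_deg - 180 - phi_deg) / 180)
}

# Minimal fibre carrying only the beam parameters.
beam_fibre <- function(delta, phi, id = 1L, ring = "outer") {
  structure(
    list(points = NULL, ring = ring, incline_delta = delta,
         tilt_azimuth_phi = phi, id = as.integer(id)),
    class = "fibre_centerline"
  )
}

beam_fibre_set <- function(...) {
  structure(list(fibres = list(...), source_spec = NULL, provenance = NULL),
            class = "fibre_set")
}

# Straight inclined fibre: drift azimuth phi constant along z (unlike the
# generator's helices), so "phi aligned with attack" scenarios are exact.
straight_fibre <- function(x0, y0, delta_deg, phi_deg, L = 15, z_step = 0.5,
                           id = 1L, ring = "outer") {
  z <- seq(0, L, by = z_step)
  h <- z / tanpi(delta_deg / 180)
  pts <- cbind(x = x0 + h * cospi(phi_deg / 180),
               y = y0 + h * sinpi(phi_deg / 180), z = z)
  structure(
    list(points = pts, ring = ring, incline_delta = delta_deg,
         tilt_azimuth_phi = phi_deg, id = as.integer(id)),
    class = "fibre_centerline"
  )
}

# Synthetic linkage map: n markers over 7 rye chromosomes with per-chromosome
# spans summing to `total_cM`.
synthetic_map <- function(n_markers = 1041, total_cM = 783.8) {
  chrom <- paste0(1:7, "R")
  per <- diff(round(seq(0, n_markers, length.out = 8)))
  spans <- total_cM * per / n_markers
  rows <- lapply(seq_along(chrom), function(k) {
    data.frame(
      marker_id = sprintf("%s_m%03d", chrom[k], seq_len(per[k])),
      chromosome = chrom[k],
      position_cM = seq(0, spans[k], length.out = per[k])
    )
  })
  do.call(rbind, rows)
}

# A small, fast stem: sparse rings so chaining is unambiguous at any incline.
small_stem <- function(incline = 76, sd = 0, n_outer = 8, n_inner = 4,
                       seed = 42L, ...) {
  stem_params(n_outer_bundles = n_outer, n_inner_bundles = n_inner,
              incline_mean_deg = incline, incline_sd_deg = sd,
              seed = seed, ...)
}
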