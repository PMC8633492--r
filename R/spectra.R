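# FTIR chemotyping: preprocessing, EMSC-style linear decomposition against a
# component reference library, lignin S/G ratios and PCA chemotype scores.
#
# The decomposition is ordinary least squares against an explicit component
# library plus polynomial baseline columns (the EMSC convention). A PLS
# variant would need a calibration response that is not available here.

#' Preprocess a spectrum
#'
#' Truncates to the retained window (1800-800 cm-1 by default) and applies
#' vector (L2) and/or min-max normalization, setting the corresponding
#' flags. A constant spectrum has no min-max range: it is flagged degenerate
#' and returned as zeros with a warning.
#'
#' @param raw a `spectrum` or `spectrum_set`.
#' @param lo,hi retained wavenumber window (cm-1), inclusive.
#' @param mode `"vector"`, `"minmax"` or `"both"` (vector then min-max).
#' @return the preprocessed object with updated flags.
#' @export
preprocess_spectrum <- function(raw, lo = 800, hi = 1800,
                                mode = c("vector", "minmax", "both")) {
  mode <- match.arg(mode)
  if (inherits(raw, "spectrum_set")) {
    keep <- raw$wavenumber >= lo & raw$wavenumber <= hi
    if (min(raw$wavenumber) > lo || max(raw$wavenumber) < hi) {
      cf_stop(sprintf("spectra cover %g-%g cm-1, requested %g-%g",
                      min(raw$wavenumber), max(raw$wavenumber), lo, hi),
              "cf_range_error")
    }
    out <- raw
    out$wavenumber <- raw$wavenumber[keep]
    out$A <- raw$A[, keep, drop = FALSE]
    for (i in seq_len(nrow(out$A))) {
      out$A[i, ] <- normalize_trace(out$A[i, ], mode)
    }
    out$flags$truncated <- TRUE
    out$flags$vector_normalized <- mode %in% c("vector", "both")
    out$flags$minmax_normalized <- mode %in% c("minmax", "both")
    return(out)
  }
  stopifnot(inherits(raw, "spectrum"))
  if (min(raw$wavenumber) > lo || max(raw$wavenumber) < hi) {
    cf_stop(sprintf("spectrum covers %g-%g cm-1, requested %g-%g",
                    min(raw$wavenumber), max(raw$wavenumber), lo, hi),
            "cf_range_error")
  }
  keep <- raw$wavenumber >= lo & raw$wavenumber <= hi
  wn <- raw$wavenumber[keep]
  ab <- raw$absorbance[keep]
  degenerate <- FALSE
  if (mode %in% c("minmax", "both") && diff(range(ab)) == 0) {
    cf_warn("constant spectrum: min-max normalization undefined, returning zeros",
            "cf_degenerate_warning")
    ab <- rep(0, length(ab))
    degenerate <- TRUE
  } else {
    ab <- normalize_trace(ab, mode)
  }
  spectrum(wn, ab, flags = list(
    truncated = TRUE,
    vector_normalized = mode %in% c("vector", "both"),
    minmax_normalized = mode %in% c("minmax", "both"),
    degenerate = degenerate
  ))
}

normalize_trace <- function(x, mode) {
  if (mode %in% c("vector", "both")) {
    n <- sqrt(sum(x^2))
    if (n > 0) x <- x / n
  }
  if (mode %in% c("minmax", "both")) {
    rg <- range(x)
    if (diff(rg) > 0) x <- (x - rg[1]) / diff(rg) else x <- rep(0, length(x))
  }
  x
}

#' EMSC-style component decomposition
#'
#' Least-squares fit of a spectrum against the design
#' `[baseline polynomial | component reference spectra]`. Coefficients may
#' be negative and are reported as-is (clipping would silently change the
#' derived ratios); `nonneg = TRUE` switches the component block to
#' nonnegative least squares (baseline stays unconstrained).
#'
#' @param s a `spectrum` (interpolated linearly onto the library grid; a
#'   grid that would require extrapolation is an error).
#' @param lib a [component_library()].
#' @param baseline_order polynomial baseline order; default from the library.
#' @param nonneg constrain component loadings to be nonnegative.
#' @return object of class `component_loadings`: named `loadings`, baseline
#'   coefficients, `residual_rms` and derived `ratios` (`lnS_lnG` and the
#'   xylan share of the hemicellulose-class loadings, which is 1 by
#'   construction for the default single-hemicellulose library).
#' @examples
#' lib <- component_library()
#' s <- spectrum(lib$wavenumber, 0.7 * lib$K[, "cellulose"])
#' emsc_decompose(s, lib)$loadings["cellulose"]
#' @export
emsc_decompose <- function(s, lib, baseline_order = NULL, nonneg = FALSE) {
  stopifnot(inherits(s, "spectrum"), inherits(lib, "component_library"))
  baseline_order <- baseline_order %||% lib$baseline_order
  wn <- lib$wavenumber
  if (min(s$wavenumber) > min(wn) || max(s$wavenumber) < max(wn)) {
    cf_stop("spectrum does not cover the library grid (extrapolation refused)",
            "cf_alignment_error")
  }
  y <- if (isTRUE(all.equal(s$wavenumber, wn))) {
    s$absorbance
  } else {
    stats::approx(s$wavenumber, s$absorbance, xout = wn)$y
  }
  P <- baseline_basis(wn, baseline_order)
  X <- cbind(P, lib$K)
  if (qr(X)$rank < ncol(X)) {
    cf_stop("design (baseline + library) is rank deficient", "cf_library_error")
  }
  if (nonneg) {
    # residualize against the baseline, then NNLS on the component block
    Q <- qr.Q(qr(P))
    y_t <- y - Q %*% crossprod(Q, y)
    K_t <- lib$K - Q %*% crossprod(Q, lib$K)
    cc <- nnls_lh(K_t, as.vector(y_t))
    b <- qr.coef(qr(P), y - lib$K %*% cc)
    coef <- c(b, cc)
  } else {
    coef <- qr.coef(qr(X), y)
  }
  k <- ncol(P)
  loadings <- coef[(k + 1):length(coef)]
  names(loadings) <- lib$components
  resid <- y - X %*% coef
  hemi <- lib$component_class == "hemicellulose"
  ratios <- c(
    lnS_lnG = if ("lignin_S" %in% lib$components &&
                  "lignin_G" %in% lib$components &&
                  abs(loadings["lignin_G"]) > 1e-12) {
      unname(loadings["lignin_S"] / loadings["lignin_G"])
    } else {
      NA_real_
    },
    xylan_share_hemicellulose = if (any(hemi) && sum(loadings[hemi]) != 0) {
      unname(loadings["hemicellulose_xylan"] / sum(loadings[hemi]))
    } else {
      NA_real_
    }
  )
  structure(
    list(loadings = loadings, baseline = coef[seq_len(k)],
         residual_rms = sqrt(mean(resid^2)), ratios = ratios,
         negative_loadings = any(loadings < -1e-12), nonneg = nonneg),
    class = "component_loadings"
  )
}

#' @export
print.component_loadings <- function(x, ...) {
  cat("component_loadings (residual RMS", format(x$residual_rms, digits = 3), ")\n")
  print(round(x$loadings, 4))
  cat(sprintf("  LnS/LnG = %.3f, xylan share = %.3f\n",
              x$ratios["lnS_lnG"], x$ratios["xylan_share_hemicellulose"]))
  invisible(x)
}

#' Decompose every spectrum of a set
#'
#' @param set a `spectrum_set` on (or covering) the library grid.
#' @param lib a [component_library()].
#' @param ... passed to [emsc_decompose()].
#' @return data.frame: one row per sample with loadings, residual RMS and
#'   ratios; `sample_id` and `group` carried from the set metadata.
#' @export
decompose_set <- function(set, lib, ...) {
  stopifnot(inherits(set, "spectrum_set"))
  rows <- lapply(seq_len(nrow(set$A)), function(i) {
    dec <- emsc_decompose(set_spectrum(set, i), lib, ...)
    cbind(
      data.frame(sample_id = set$meta$sample_id[i],
                 group = set$meta$group[i], stringsAsFactors = FALSE),
      as.data.frame(as.list(dec$loadings)),
      data.frame(residual_rms = dec$residual_rms,
                 lnS_lnG = dec$ratios["lnS_lnG"],
                 xylan_share = dec$ratios["xylan_share_hemicellulose"],
                 row.names = NULL)
    )
  })
  do.call(rbind, rows)
}

# Lawson-Hanson nonnegative least squares (small dense problems).
nnls_lh <- function(A, b, tol = 1e-10, max_iter = 300L) {
  n <- ncol(A)
  x <- rep(0, n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- rep(0, n)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      if (all(s[passive] > tol)) {
        x <- s
        break
      }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' PCA chemotype scores
#'
#' Centered principal component analysis of a (preprocessed) spectrum set.
#' Sign convention: each component is flipped so its largest-magnitude
#' loading is positive, making scores deterministic across platforms.
#'
#' @param set a `spectrum_set` with at least 2 spectra.
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `loadings`,
#'   `explained_variance` fractions and a `degenerate` flag (TRUE when the
#'   set has essentially zero total variance, e.g. duplicated spectra).
#' @export
pca_chemotype <- function(set, n_components = 2L) {
  stopifnot(inherits(set, "spectrum_set"))
  n <- nrow(set$A)
  if (n < 2L) cf_stop("PCA needs at least 2 spectra", "cf_parameter_error")
  if (n_components > min(n - 1L, ncol(set$A))) {
    cf_stop(sprintf("cannot extract %d components from %d spectra",
                    n_components, n), "cf_parameter_error")
  }
  X <- scale(set$A, center = TRUE, scale = FALSE)
  total_var <- sum(X^2) / (n - 1)
  if (total_var < 1e-24) {
    return(structure(list(
      scores = matrix(0, n, n_components),
      loadings = matrix(NA_real_, ncol(set$A), n_components),
      explained_variance = rep(NA_real_, n_components),
      degenerate = TRUE
    ), class = "pca_chemotype"))
  }
  sv <- svd(X, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_components)],
                                n_components, n_components),
                  2, flip, `*`)
  loadings <- sweep(sv$v, 2, flip, `*`)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  rownames(scores) <- set$meta$sample_id
  structure(list(
    scores = scores, loadings = loadings,
    explained_variance = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
    sdev = sv$d / sqrt(n - 1),
    degenerate = FALSE
  ), class = "pca_chemotype")
}

#' @export
print.pca_chemotype <- function(x, ...) {
  if (x$degenerate) {
    cat("pca_chemotype: degenerate (zero-variance set)\n")
  } else {
    cat("pca_chemotype: explained variance",
        paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Effect-size screen of component loadings
#'
#' Cohen's D for every component between two groups of samples, with the
#' effect classes used for chemotype contrasts (small > 0.2, medium > 0.5,
#' strong > 0.8).
#'
#' @param loadings data.frame or matrix of per-sample loadings (e.g. from
#'   [decompose_set()]; non-numeric columns are ignored).
#' @param group vector with exactly two levels, one entry per row.
#' @return data.frame with `component`, `D`, `class`.
#' @export
effect_screen <- function(loadings, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) {
    cf_stop("effect_screen needs exactly two groups", "cf_parameter_error")
  }
  M <- as.data.frame(loadings)
  num <- vapply(M, is.numeric, logical(1))
  M <- M[num]
  out <- do.call(rbind, lapply(names(M), function(cc) {
    es <- cohens_d(M[[cc]][g == levels(g)[1]], M[[cc]][g == levels(g)[2]])
    data.frame(component = cc, D = es$D, class = es$class,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
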