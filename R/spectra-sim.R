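# Synthetic FTIR machinery: a reference component library of Gaussian bands
# and a mixture-spectrum generator with baseline and noise.
#
# The band positions/widths (inst/extdata/component_bands.csv) are fixed
# plausible stand-ins for mid-infrared cell-wall bands; they version the
# library, they are not claims about true band assignments in rye.

#' Build a component reference library
#'
#' Reference spectra are sums of Gaussian bands evaluated on a descending
#' wavenumber grid (1800 -> 800 cm-1 by default, the spectral window retained
#' for cell-wall chemotyping).
#'
#' @param bands data.frame with columns `component`, `class`, `center_cm1`,
#'   `fwhm_cm1`, `height`; defaults to the versioned band table shipped with
#'   the package (7 components: cellulose, hemicellulose_xylan, lignin_G,
#'   lignin_S, pectin, protein, lipid).
#' @param wavenumber descending wavenumber grid in cm-1.
#' @param baseline_order polynomial baseline order used downstream.
#' @return object of class `component_library` with the reference matrix `K`
#'   (rows = wavenumbers, columns = components).
#' @export
component_library <- function(bands = NULL,
                              wavenumber = seq(1800, 800, by = -2),
                              baseline_order = 2L) {
  if (is.null(bands)) {
    path <- system.file("extdata", "component_bands.csv", package = "culmforce")
    bands <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("component", "class", "center_cm1", "fwhm_cm1", "height")
  if (!all(need %in% names(bands))) {
    cf_stop(sprintf("band table must have columns: %s", paste(need, collapse = ", ")),
            "cf_library_error")
  }
  if (any(diff(wavenumber) >= 0)) {
    cf_stop("wavenumber grid must be strictly descending", "cf_parameter_error")
  }
  comps <- unique(bands$component)
  K <- vapply(comps, function(cc) {
    b <- bands[bands$component == cc, ]
    rowSums(vapply(seq_len(nrow(b)), function(i) {
      s <- b$fwhm_cm1[i] / (2 * sqrt(2 * log(2)))
      b$height[i] * exp(-(wavenumber - b$center_cm1[i])^2 / (2 * s^2))
    }, numeric(length(wavenumber))))
  }, numeric(length(wavenumber)))
  colnames(K) <- comps
  if (any(!is.finite(K)) || any(K < 0)) {
    cf_stop("reference spectra must be finite and nonnegative", "cf_library_error")
  }
  if (qr(K)$rank < ncol(K)) {
    cf_stop("component library is rank deficient", "cf_library_error")
  }
  cls <- vapply(comps, function(cc) bands$class[bands$component == cc][1],
                character(1))
  structure(
    list(wavenumber = wavenumber, K = K, components = comps,
         component_class = cls, baseline_order = as.integer(baseline_order),
         bands = bands),
    class = "component_library"
  )
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf(
    "component_library: %d components on %d wavenumbers (%g -> %g cm-1), baseline order %d\n",
    ncol(x$K), length(x$wavenumber), x$wavenumber[1],
    x$wavenumber[length(x$wavenumber)], x$baseline_order
  ))
  cat(" ", paste(x$components, collapse = ", "), "\n")
  invisible(x)
}

# Polynomial baseline basis on the library grid, orthonormal-ish via scaling
# the wavenumber to [-1, 1].
baseline_basis <- function(wavenumber, order) {
  t <- 2 * (wavenumber - min(wavenumber)) / diff(range(wavenumber)) - 1
  vapply(0:order, function(k) t^k, numeric(length(wavenumber)))
}

#' Generate noisy mixture spectra
#'
#' Each spectrum is `K %*% c + baseline + noise`: a nonnegative linear
#' mixture of the library's reference spectra plus a random low-order
#' polynomial baseline and i.i.d. Gaussian noise. True weights are kept in
#' the returned set's metadata for recovery tests.
#'
#' @param library a [component_library()].
#' @param concentrations numeric vector (one sample) or matrix with one row
#'   per sample and one column per library component; all weights must be
#'   nonnegative.
#' @param noise_sd absorbance noise sd (a.u.).
#' @param baseline_sd sd of the random polynomial baseline coefficients.
#' @param group optional group label(s) recycled across samples.
#' @param seed integer seed.
#' @return object of class `spectrum_set`: absorbance matrix `A` (rows =
#'   samples), the grid, metadata and `true_weights`.
#' @export
generate_spectra <- function(library, concentrations, noise_sd = 0.01,
                             baseline_sd = 0, group = "sample", seed = 1L) {
  stopifnot(inherits(library, "component_library"))
  C <- concentrations
  if (is.null(dim(C))) C <- matrix(C, nrow = 1)
  if (ncol(C) != ncol(library$K)) {
    cf_stop(sprintf("weights have %d entries but the library has %d components",
                    ncol(C), ncol(library$K)), "cf_parameter_error")
  }
  if (any(!is.finite(C)) || any(C < 0)) {
    cf_stop("component weights must be finite and nonnegative",
            "cf_parameter_error")
  }
  colnames(C) <- colnames(library$K)
  n <- nrow(C)
  P <- baseline_basis(library$wavenumber, library$baseline_order)
  with_seed(seed, {
    A <- C %*% t(library$K)
    if (baseline_sd > 0) {
      B <- matrix(stats::rnorm(n * ncol(P), 0, baseline_sd), n, ncol(P))
      A <- A + B %*% t(P)
    }
    if (noise_sd > 0) {
      A <- A + matrix(stats::rnorm(length(A), 0, noise_sd), nrow = n)
    }
    spectrum_set(
      wavenumber = library$wavenumber, A = A,
      meta = data.frame(
        sample_id = sprintf("s%03d", seq_len(n)),
        group = rep_len(as.character(group), n),
        stringsAsFactors = FALSE
      ),
      true_weights = C
    )
  })
}

#' Construct a spectrum / spectrum set
#'
#' `spectrum()` holds one absorbance trace with its preprocessing flags;
#' `spectrum_set()` holds a sample x wavenumber absorbance matrix plus
#' per-sample metadata.
#'
#' @param wavenumber wavenumber grid (cm-1), strictly monotonic.
#' @param absorbance absorbance values (a.u.).
#' @param flags preprocessing state flags.
#' @return a `spectrum`.
#' @export
spectrum <- function(wavenumber, absorbance,
                     flags = list(truncated = FALSE, vector_normalized = FALSE,
                                  minmax_normalized = FALSE, degenerate = FALSE)) {
  if (length(wavenumber) != length(absorbance)) {
    cf_stop("wavenumber and absorbance lengths differ", "cf_parameter_error")
  }
  d <- diff(wavenumber)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    cf_stop("wavenumbers must be strictly monotonic", "cf_parameter_error")
  }
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 flags = flags), class = "spectrum")
}

#' @rdname spectrum
#' @param A absorbance matrix, rows = samples.
#' @param meta data.frame with at least `sample_id` and `group`.
#' @param true_weights optional matrix of generating weights.
#' @export
spectrum_set <- function(wavenumber, A, meta = NULL, true_weights = NULL) {
  A <- as.matrix(A)
  if (ncol(A) != length(wavenumber)) {
    cf_stop("absorbance matrix width must match the wavenumber grid",
            "cf_parameter_error")
  }
  if (is.null(meta)) {
    meta <- data.frame(sample_id = sprintf("s%03d", seq_len(nrow(A))),
                       group = "sample", stringsAsFactors = FALSE)
  }
  structure(
    list(wavenumber = wavenumber, A = A, meta = meta,
         true_weights = true_weights,
         flags = list(truncated = FALSE, vector_normalized = FALSE,
                      minmax_normalized = FALSE)),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d spectra on %d wavenumbers (%g -> %g cm-1)\n",
              nrow(x$A), length(x$wavenumber), x$wavenumber[1],
              x$wavenumber[length(x$wavenumber)]))
  invisible(x)
}

# i-th spectrum of a set as a `spectrum`
set_spectrum <- function(set, i) {
  spectrum(set$wavenumber, set$A[i, ],
           flags = c(set$flags, list(degenerate = FALSE)))
}

#' Write / read spectra as CSV
#'
#' One file per sample with columns `wavenumber_cm1, absorbance`, plus a
#' manifest CSV (`sample_id, group, path`).
#'
#' @param set a `spectrum_set`.
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV (write) or a `spectrum_set` (read).
#' @export
write_spectra <- function(set, dir) {
  stopifnot(inherits(set, "spectrum_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(set$A))
  for (i in seq_len(nrow(set$A))) {
    paths[i] <- file.path(dir, paste0(set$meta$sample_id[i], ".csv"))
    utils::write.csv(
      data.frame(wavenumber_cm1 = set$wavenumber, absorbance = set$A[i, ]),
      paths[i], row.names = FALSE
    )
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(
    data.frame(sample_id = set$meta$sample_id, group = set$meta$group,
               path = basename(paths), stringsAsFactors = FALSE),
    manifest, row.names = FALSE
  )
  invisible(manifest)
}

#' @rdname write_spectra
#' @param manifest path to a manifest CSV.
#' @export
read_spectra <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  specs <- lapply(man$path, function(p) {
    utils::read.csv(file.path(dir, p), stringsAsFactors = FALSE)
  })
  wn <- specs[[1]]$wavenumber_cm1
  A <- t(vapply(specs, function(s) {
    if (!isTRUE(all.equal(s$wavenumber_cm1, wn))) {
      cf_stop("spectra in the manifest are on different grids",
              "cf_alignment_error")
    }
    s$absorbance
  }, numeric(length(wn))))
  spectrum_set(wn, A, meta = data.frame(sample_id = man$sample_id,
                                        group = man$group,
                                        stringsAsFactors = FALSE))
}
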