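# Pipeline orchestration: configuration, staged execution with a JSON run
# manifest, and the resistant-vs-prone preset comparison report.

#' Run configuration
#'
#' Unknown keys are rejected so config typos fail loudly. A JSON config file
#' (no YAML parser is available for this R installation) may supply any
#' subset of the fields; explicit arguments win.
#'
#' @param preset preset name (see [stem_preset()]).
#' @param stages character subset of
#'   `c("simulate", "geometry", "mechanics", "spectra", "traits")`.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param attack_azimuth_deg,pressure_Nm2 mechanics stage parameters.
#' @param d_alpha,n_r,dz,segment grid parameters (see
#'   [build_cylindrical_grid()]).
#' @param volume logical: rasterize + write the label volume in `simulate`.
#' @param render logical: write PNG renderings in `mechanics`.
#' @param config_file optional path to a JSON file with these fields.
#' @return object of class `run_config`.
#' @export
run_config <- function(preset = "rye_resistant",
                       stages = c("simulate", "geometry", "mechanics",
                                  "spectra", "traits"),
                       seed = 1L, out_dir = tempfile("culmforce_run_"),
                       attack_azimuth_deg = 180, pressure_Nm2 = 1,
                       d_alpha = 1, n_r = 20, dz = 1, segment = 15,
                       volume = TRUE, render = FALSE, config_file = NULL) {
  known <- c("preset", "stages", "seed", "out_dir", "attack_azimuth_deg",
             "pressure_Nm2", "d_alpha", "n_r", "dz", "segment", "volume",
             "render")
  cfg <- list(preset = preset, stages = stages, seed = as.integer(seed),
              out_dir = out_dir, attack_azimuth_deg = attack_azimuth_deg,
              pressure_Nm2 = pressure_Nm2, d_alpha = d_alpha, n_r = n_r,
              dz = dz, segment = segment, volume = volume, render = render)
  if (!is.null(config_file)) {
    file_cfg <- jsonlite::read_json(config_file, simplifyVector = TRUE)
    extra <- setdiff(names(file_cfg), known)
    if (length(extra)) {
      cf_stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")),
              "cf_validation_error")
    }
    supplied <- names(as.list(match.call()))[-1]
    for (k in setdiff(names(file_cfg), supplied)) cfg[[k]] <- file_cfg[[k]]
  }
  cfg$stages <- match.arg(cfg$stages,
                          c("simulate", "geometry", "mechanics", "spectra",
                            "traits"),
                          several.ok = TRUE)
  cfg$preset <- match.arg(cfg$preset, names(.stem_presets))
  class(cfg) <- "run_config"
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the selected stages on a preset stem: simulate (geometry, label
#' volume, trait tables, spectra), geometry (centerline extraction, counts,
#' inclines), mechanics (grid, surface load, propagation, 360-degree sweep,
#' optimal attack), spectra (preprocess + decompose + PCA + effect screen on
#' a parental contrast), traits (parent comparisons, effect sizes,
#' heritability). Writes every artifact under `config$out_dir` and a run
#' manifest (`manifest.json`) with parameters, seeds, grid size,
#' conservation residual and md5 hashes of all outputs.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (a list; also written as JSON).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("culmforce")),
    config = unclass(config), stages = list()
  )
  outputs <- character(0)
  params <- stem_preset(config$preset, seed = config$seed)
  geo <- generate_stem_geometry(params)

  if ("simulate" %in% config$stages) {
    st <- list()
    write_fibre_set(as_fibre_set(geo),
                    fp <- file.path(config$out_dir, "fibres.csv"))
    outputs <- c(outputs, fp)
    if (isTRUE(config$volume)) {
      vol <- rasterize_label_volume(geo)
      write_nrrd(vol, vp <- file.path(config$out_dir, "label_volume.nrrd"),
                 encoding = "raw")
      outputs <- c(outputs, vp)
      st$volume_dims <- dim(vol)
    }
    traits_tab <- generate_trait_table(trait_preset("PH", seed = config$seed))
    for (tr in c("DWC", "DBI")) {
      m <- trait_preset(tr, seed = config$seed + match(tr, c("DWC", "DBI")))
      traits_tab[[m$trait]] <- generate_trait_table(m)[[m$trait]]
    }
    write_trait_table(traits_tab, tp <- file.path(config$out_dir, "traits.csv"))
    outputs <- c(outputs, tp)
    lib <- component_library()
    conc <- simulate_parental_concentrations(config$seed)
    spectra <- generate_spectra(lib, conc$weights, noise_sd = 0.01,
                                baseline_sd = 0.005, group = conc$group,
                                seed = config$seed)
    mp <- write_spectra(spectra, file.path(config$out_dir, "spectra"))
    outputs <- c(outputs, mp)
    st$n_fibres <- length(geo$fibres)
    manifest$stages$simulate <- st
  }

  if ("geometry" %in% config$stages) {
    vol <- rasterize_label_volume(geo)
    fs <- extract_bundle_centerlines(vol)
    counts <- count_bundles(fs)
    inc <- incline_summary(fs)
    utils::write.csv(inc, ip <- file.path(config$out_dir, "incline_summary.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, ip)
    manifest$stages$geometry <- list(
      counts = as.list(counts$counts),
      per_area_mm2 = as.list(counts$per_area_mm2),
      mean_incline_deg = stats::setNames(inc$mean_incline_deg, inc$ring)
    )
  }

  if ("mechanics" %in% config$stages) {
    grid <- build_cylindrical_grid(geo, d_alpha = config$d_alpha,
                                   n_r = config$n_r, dz = config$dz,
                                   segment = config$segment)
    impact <- impact_condition(config$attack_azimuth_deg, config$pressure_Nm2)
    loaded <- surface_load(grid, impact)
    prop <- propagate_forces(loaded, grid)
    sweep <- sweep_attack_angles(as_fibre_set(geo), impact)
    utils::write.csv(as.data.frame(sweep),
                     sp <- file.path(config$out_dir, "attack_sweep.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, sp)
    if (isTRUE(config$render)) {
      rp <- render_fields(prop$field, prop$warp, grid,
                          file.path(config$out_dir, "render"))
      outputs <- c(outputs, rp)
    }
    manifest$stages$mechanics <- list(
      grid_voxels = grid$n_voxels,
      fibre_voxels = sum(grid$is_fibre),
      total_surface_load_N = prop$field$total_load_N,
      conservation_residual = prop$field$conservation_residual,
      sweep_rows = nrow(sweep),
      amplitude_FN = sweep_amplitude(sweep, "FN"),
      amplitude_Fb = sweep_amplitude(sweep, "Fb"),
      optimal_attack_deg = find_optimal_attack(sweep)
    )
  }

  if ("spectra" %in% config$stages) {
    lib <- component_library()
    conc <- simulate_parental_concentrations(config$seed)
    raw <- generate_spectra(lib, conc$weights, noise_sd = 0.01,
                            baseline_sd = 0.005, group = conc$group,
                            seed = config$seed)
    pre <- preprocess_spectrum(raw, mode = "vector")
    dec <- decompose_set(pre, lib)
    utils::write.csv(dec, dp <- file.path(config$out_dir, "loadings.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, dp)
    pca <- pca_chemotype(pre, n_components = 2L)
    screen <- effect_screen(dec[lib$components], dec$group)
    utils::write.csv(screen, ep <- file.path(config$out_dir, "effect_screen.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, ep)
    manifest$stages$spectra <- list(
      explained_variance = pca$explained_variance,
      strongest_effect = screen$component[which.max(screen$D)]
    )
  }

  if ("traits" %in% config$stages) {
    rows <- list()
    for (tr in c("PH", "DWC", "DBI", "OVB")) {
      tab <- generate_trait_table(
        trait_preset(tr, seed = config$seed + match(tr, c("PH", "DWC", "DBI", "OVB")))
      )
      x <- tab[[tr]][tab$generation == "P1"]
      y <- tab[[tr]][tab$generation == "P2"]
      cmp <- compare_groups(x, y, "welch")
      es <- cohens_d(x, y)
      h2 <- heritability_h2(tab, tr)
      rows[[tr]] <- data.frame(
        trait = tr, mean_P1 = mean(x), mean_P2 = mean(y),
        welch_p = cmp$p_value, stars = cmp$stars, D = es$D,
        effect_class = es$class, H2 = h2$H2
      )
    }
    rep_tab <- do.call(rbind, rows)
    utils::write.csv(rep_tab, rp <- file.path(config$out_dir, "trait_report.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, rp)
    manifest$stages$traits <- list(traits = rep_tab$trait, H2 = rep_tab$H2)
  }

  manifest$outputs <- as.list(tools::md5sum(outputs[file.exists(outputs)]))
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

# Parental cell-wall weight profiles for the demo spectra: the resistant
# chemotype is richer in cellulose, xylan and lignin (S-shifted), slightly
# poorer in pectin.
simulate_parental_concentrations <- function(seed, n_per_group = 20L) {
  with_seed(seed, {
    base_res <- c(cellulose = 0.55, hemicellulose_xylan = 0.35,
                  lignin_G = 0.15, lignin_S = 0.30, pectin = 0.08,
                  protein = 0.10, lipid = 0.05)
    base_pro <- c(cellulose = 0.45, hemicellulose_xylan = 0.22,
                  lignin_G = 0.12, lignin_S = 0.15, pectin = 0.12,
                  protein = 0.10, lipid = 0.05)
    jitter <- function(mu) {
      t(vapply(seq_len(n_per_group),
               function(i) pmax(0, mu * (1 + stats::rnorm(length(mu), 0, 0.08))),
               numeric(length(mu))))
    }
    list(weights = rbind(jitter(base_res), jitter(base_pro)),
         group = rep(c("resistant", "prone"), each = n_per_group))
  })
}

#' Compare two presets
#'
#' Reproduces the qualitative resistant-vs-prone contrast: outer-bundle
#' counts recovered by the full rasterize-and-extract round trip, and the
#' amplitude of the mean axial-force curve F_N(alpha). Because synthetic
#' stems are near rotationally symmetric, a single stem's amplitude is
#' placement-noise dominated; the amplitude is therefore reported as the
#' mean over `n_rep` replicate stems per preset (seeds derived from `seed`).
#'
#' @param preset_a,preset_b preset names.
#' @param seed base seed.
#' @param n_rep replicate stems per preset for the amplitude estimate.
#' @return object of class `preset_comparison`: per-preset OVB/IVB counts,
#'   mean F_N and F_b amplitudes, mean inclines, and the two headline
#'   orderings.
#' @export
compare_presets <- function(preset_a = "rye_resistant",
                            preset_b = "rye_prone", seed = 1L, n_rep = 25L) {
  study <- function(name) {
    geo <- generate_stem_geometry(stem_preset(name, seed = seed))
    fs <- extract_bundle_centerlines(rasterize_label_volume(geo))
    counts <- count_bundles(fs)$counts
    amps <- vapply(seq_len(n_rep), function(k) {
      g <- generate_stem_geometry(stem_preset(name, seed = seed + k))
      prof <- sweep_attack_angles(as_fibre_set(g))
      c(FN = sweep_amplitude(prof, "FN"), Fb = sweep_amplitude(prof, "Fb"))
    }, numeric(2))
    list(name = name, counts = counts,
         amplitude_FN = mean(amps["FN", ]), amplitude_Fb = mean(amps["Fb", ]),
         mean_incline_deg = mean(vapply(geo$fibres,
                                        function(f) f$incline_delta,
                                        numeric(1))))
  }
  a <- study(preset_a)
  b <- study(preset_b)
  structure(
    list(a = a, b = b,
         ovb_a_gt_b = unname(a$counts["outer"] > b$counts["outer"]),
         amplitude_a_gt_b = a$amplitude_FN > b$amplitude_FN),
    class = "preset_comparison"
  )
}

#' @export
print.preset_comparison <- function(x, ...) {
  fmt <- function(s) {
    sprintf("  %-16s OVB = %2d, IVB = %2d, mean F_N amplitude = %.4f, mean incline = %.1f deg",
            s$name, s$counts["outer"], s$counts["inner"], s$amplitude_FN,
            s$mean_incline_deg)
  }
  cat("preset comparison\n", fmt(x$a), "\n", fmt(x$b), "\n", sep = "")
  cat(sprintf("  OVB(%s) > OVB(%s): %s\n", x$a$name, x$b$name, x$ovb_a_gt_b))
  cat(sprintf("  F_N amplitude(%s) > (%s): %s\n",
              x$a$name, x$b$name, x$amplitude_a_gt_b))
  invisible(x)
}
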