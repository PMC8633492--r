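# Named presets emulating the contrasted genotypes: lodging-resistant vs
# lodging-prone rye (and a wheat pair for the comparative analysis).
#
# Printed anchors: outer-bundle counts 27.4 +- 2.1 (resistant) vs 18.8 +- 2.8
# (prone), inner ring comparable between lines (11 both); basal internode
# diameters 3.6 vs 4.4 mm (the prone radius is trimmed to 2.0 mm so the stem
# fits the 4.2 mm imaging field of view). No numeric incline values are
# printed anywhere, only the qualitative statement that resistant bundles are
# more inclined; the presets encode that as a larger from-axis tilt
# (14 +- 3 deg resistant vs 6 +- 2 deg prone), i.e. incline-from-plane
# 76 vs 84 degrees; the sd keeps helical ring rotation per image slice well
# below half the bundle spacing, so centerline chaining is unambiguous. Wheat presets are plausible stand-ins for the (unprinted)
# wheat panel: both semi-dwarf, resistant thicker-walled with more bundles.

.stem_presets <- list(
  rye_resistant = list(
    outer_radius_Ro = 1.8, inner_radius_Ri = 1.1, length_L = 15,
    n_outer_bundles = 27L, n_inner_bundles = 11L,
    ring_radius_outer = 1.62, ring_radius_inner = 1.28, bundle_radius = 0.12,
    incline_mean_deg = 76, incline_sd_deg = 3, azimuth_jitter_deg = 0.8
  ),
  rye_prone = list(
    outer_radius_Ro = 2.0, inner_radius_Ri = 1.25, length_L = 15,
    n_outer_bundles = 19L, n_inner_bundles = 11L,
    ring_radius_outer = 1.8, ring_radius_inner = 1.45, bundle_radius = 0.12,
    incline_mean_deg = 84, incline_sd_deg = 2, azimuth_jitter_deg = 0.8
  ),
  wheat_resistant = list(
    outer_radius_Ro = 2.05, inner_radius_Ri = 1.15, length_L = 15,
    n_outer_bundles = 32L, n_inner_bundles = 14L,
    ring_radius_outer = 1.85, ring_radius_inner = 1.4, bundle_radius = 0.1,
    incline_mean_deg = 78, incline_sd_deg = 3, azimuth_jitter_deg = 0.8
  ),
  wheat_prone = list(
    outer_radius_Ro = 1.9, inner_radius_Ri = 1.25, length_L = 15,
    n_outer_bundles = 24L, n_inner_bundles = 10L,
    ring_radius_outer = 1.72, ring_radius_inner = 1.45, bundle_radius = 0.1,
    incline_mean_deg = 83, incline_sd_deg = 2, azimuth_jitter_deg = 0.8
  )
)

#' Stem parameter presets
#'
#' @param name one of `"rye_resistant"`, `"rye_prone"`, `"wheat_resistant"`,
#'   `"wheat_prone"`.
#' @param seed seed forwarded to [stem_params()].
#' @param ... overrides for individual [stem_params()] fields.
#' @return a [stem_params()] object.
#' @examples
#' stem_preset("rye_resistant")$n_outer_bundles # 27
#' @export
stem_preset <- function(name = c("rye_resistant", "rye_prone",
                                 "wheat_resistant", "wheat_prone"),
                        seed = 1L, ...) {
  name <- match.arg(name)
  args <- utils::modifyList(.stem_presets[[name]], list(seed = seed, ...))
  do.call(stem_params, args)
}

#' Trait generation presets for the parental contrast
#'
#' Parent means/sds are the printed values for the lodging-resistant
#' ('ms135', P1) vs lodging-prone ('R1124', P2) rye lines where available
#' (plant height 110.7 +- 6.9 vs 95 +- 15.2 cm; culm dry weight 13.7 +- 5.0
#' vs 1.7 +- 1.6 g; basal internode diameter 3.6 +- 0.5 vs 4.4 +- 0.6 mm;
#' outer bundles 27.4 +- 2.1 vs 18.8 +- 2.8; sclerenchyma layer 70.8 +- 13.1
#' vs 49.6 +- 10.2 um; epidermal cell wall 0.87 +- 0.26 vs 0.50 +- 0.16 um);
#' the tiller preset encodes the reported roughly fivefold contrast.
#'
#' @param trait one of the trait codes below.
#' @param seed seed for [generate_trait_table()].
#' @param ... overrides for [trait_gen_model()] fields.
#' @return a [trait_gen_model()].
#' @export
trait_preset <- function(trait = c("PH", "DWC", "DBI", "NoT", "OVB",
                                   "ScL", "EpCW"),
                         seed = 1L, ...) {
  trait <- match.arg(trait)
  base <- switch(trait,
    PH   = list(parent1_mean = 110.7, parent1_sd = 6.9,
                parent2_mean = 95,    parent2_sd = 15.2),
    DWC  = list(parent1_mean = 13.7,  parent1_sd = 5.0,
                parent2_mean = 1.7,   parent2_sd = 1.6),
    DBI  = list(parent1_mean = 3.6,   parent1_sd = 0.5,
                parent2_mean = 4.4,   parent2_sd = 0.6),
    NoT  = list(parent1_mean = 20,    parent1_sd = 6,
                parent2_mean = 4,     parent2_sd = 2),
    OVB  = list(parent1_mean = 27.4,  parent1_sd = 2.1,
                parent2_mean = 18.8,  parent2_sd = 2.8),
    ScL  = list(parent1_mean = 70.8,  parent1_sd = 13.1,
                parent2_mean = 49.6,  parent2_sd = 10.2),
    EpCW = list(parent1_mean = 0.87,  parent1_sd = 0.26,
                parent2_mean = 0.50,  parent2_sd = 0.16)
  )
  base$trait <- trait
  base$seed <- seed
  do.call(trait_gen_model, utils::modifyList(base, list(...)))
}
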