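#' Named synthetic-scene presets
#'
#' Presets encode the study conditions used throughout the test-suite and the
#' acceptance analyses. Each preset defines a control cell and a knockout-like
#' (`"ko"`) cell differing by the published effect size:
#' \describe{
#'   \item{`lc3`}{autophagosome counting; LC3 puncta rate 6 per cell in
#'     control, 12 in KO (twofold increase).}
#'   \item{`parkin`}{Parkin recruitment; bright-patch area fraction 0.002 of
#'     the cell area in control, 0.05 in KO (25-fold).}
#'   \item{`cox8_48h`}{acid-quenched mitophagy reporter at 48 h; mCherry-only
#'     punctum rate 1.5 per cell in control, 15 in KO (10-fold), on top of a
#'     dual-labelled (GFP + mCherry) mitochondrial network.}
#'   \item{`morpho`}{3D morphometry; KO cells get longer, straighter tubes and
#'     more MDV-sized objects.}
#'   \item{`timelapse`}{2D motility scenes with ten well-separated tubes for
#'     tracking validation (speeds are supplied to [generate_timelapse()]).}
#' }
#'
#' Absolute per-cell rates are not published, only fold changes; the control
#' rates above are chosen as typical of the assays and documented in the
#' methods vignette.
#'
#' @param name one of `"lc3"`, `"parkin"`, `"cox8_48h"`, `"morpho"`,
#'   `"timelapse"`.
#' @param condition `"control"` or `"ko"`.
#' @param seed integer seed passed to [scene_config()].
#' @param ... overrides forwarded to [scene_config()].
#' @return A `SceneConfig`.
#' @examples
#' cfg <- scene_preset("lc3", "ko", seed = 3)
#' cfg$puncta_rate
#' @export
scene_preset <- function(name = c("lc3", "parkin", "cox8_48h", "morpho", "timelapse"),
                         condition = c("control", "ko"), seed = 1L, ...) {
  name <- match.arg(name)
  condition <- match.arg(condition)
  ko <- condition == "ko"
  args <- switch(name,
    lc3 = list(
      grid_shape = c(y = 128, x = 128, z = 6),
      n_mito = 0,
      puncta_rate = if (ko) 12 else 6,
      puncta_channels = "lc3",
      puncta_amplitude = 6,
      cyto_level = 0.1
    ),
    parkin = list(
      grid_shape = c(y = 128, x = 128, z = 1),
      n_mito = 0,
      parkin_area_fraction = if (ko) 0.05 else 0.002,
      parkin_patch_radius = 0.25,
      parkin_amplitude = 6,
      cyto_level = 0.1
    ),
    cox8_48h = list(
      grid_shape = c(y = 192, x = 192, z = 1),
      n_mito = 8,
      tube_channels = c("gfp", "mcherry"),
      tube_amplitude = 1.5,
      tube_length_meanlog = log(1.2),
      puncta_rate = if (ko) 15 else 1.5,
      puncta_channels = "mcherry",
      puncta_amplitude = 8,
      cyto_level = 0.1
    ),
    morpho = list(
      grid_shape = c(y = 128, x = 128, z = 10),
      n_mito = 10,
      tube_radius = 0.15,
      tube_length_meanlog = if (ko) log(2.2) else log(0.8),
      tube_length_sdlog = 0.3,
      persistence = if (ko) 0.97 else 0.85,
      z_wiggle = 0.05,
      tube_amplitude = 4,
      # MDV-sized objects are a minor fraction of a cell's mitochondria; the
      # rates keep the threefold KO increase at the scene's 10-tube scale
      mdv_rate = if (ko) 3 else 1,
      mdv_amplitude = 2,
      mdv_channels = c("tom20", "pdh"),
      cyto_level = 0.02,
      min_separation = 2.0
    ),
    timelapse = list(
      grid_shape = c(y = 192, x = 192, z = 1),
      n_mito = 10,
      tube_radius = 0.15,
      tube_length_meanlog = log(0.8),
      tube_length_sdlog = 0.2,
      persistence = 0.95,
      tube_amplitude = 2,
      cyto_level = 0,
      min_separation = 3.5
    )
  )
  over <- list(...)
  args[names(over)] <- over
  args$seed <- seed
  do.call(scene_config, args)
}
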