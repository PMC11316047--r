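#' Pipeline configuration
#'
#' Bundles every tunable threshold of the analysis pipelines with its default.
#' Defaults encode the published analysis constants: puncta must exceed
#' 0.01 um^2, mitochondria-derived-vesicle (MDV) sized objects are < 0.03 um^3
#' and networks > 1 um^3, the mCherry-only mitophagy call requires a
#' background-subtracted peak at least 2x background, and the vesselness
#' semantic threshold is 1e-5 of the normalised Frangi response.
#'
#' @param morpho_intensity_threshold counts, or `"auto"` for Otsu's method.
#' @param morpho_clean_min_voxels minimum component size kept by the clean
#'   filter (voxels).
#' @param morpho_v_mdv upper volume bound for MDV-sized objects, um^3.
#' @param morpho_v_network lower volume bound for network objects, um^3.
#' @param puncta_min_area minimum punctum area, um^2 (strictly greater-than).
#' @param puncta_mcherry_ratio minimum (peak - background)/background ratio on
#'   the mCherry channel for a mitolysosome call.
#' @param puncta_gfp_absent_ratio maximum GFP ratio compatible with "absent"
#'   GFP fluorescence.
#' @param puncta_match_radius centroid match radius for cargo-selective MDV
#'   calling, um.
#' @param puncta_background_radius rolling-ball radius for background
#'   subtraction, um.
#' @param dynamics_frangi_scales Gaussian scales for the Frangi filter, pixels.
#' @param dynamics_semantic_threshold threshold on normalised vesselness.
#' @param dynamics_max_speed tracking gate, um/s.
#' @param stats_rout_q ROUT false discovery rate Q.
#' @param stats_alpha significance level for group comparisons.
#'
#' @return A list of class `PipelineConfig`.
#' @seealso [read_config()], [config_hash()]
#' @export
pipeline_config <- function(morpho_intensity_threshold = "auto",
                            morpho_clean_min_voxels = 5,
                            morpho_v_mdv = 0.03,
                            morpho_v_network = 1.0,
                            puncta_min_area = 0.01,
                            puncta_mcherry_ratio = 2.0,
                            puncta_gfp_absent_ratio = 0.5,
                            puncta_match_radius = 0.15,
                            puncta_background_radius = 0.5,
                            dynamics_frangi_scales = c(1, 1.5, 2),
                            dynamics_semantic_threshold = 1e-5,
                            dynamics_max_speed = 1.0,
                            stats_rout_q = 0.01,
                            stats_alpha = 0.05) {
  cfg <- list(
    morpho_intensity_threshold = morpho_intensity_threshold,
    morpho_clean_min_voxels = morpho_clean_min_voxels,
    morpho_v_mdv = morpho_v_mdv,
    morpho_v_network = morpho_v_network,
    puncta_min_area = puncta_min_area,
    puncta_mcherry_ratio = puncta_mcherry_ratio,
    puncta_gfp_absent_ratio = puncta_gfp_absent_ratio,
    puncta_match_radius = puncta_match_radius,
    puncta_background_radius = puncta_background_radius,
    dynamics_frangi_scales = dynamics_frangi_scales,
    dynamics_semantic_threshold = dynamics_semantic_threshold,
    dynamics_max_speed = dynamics_max_speed,
    stats_rout_q = stats_rout_q,
    stats_alpha = stats_alpha
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "PipelineConfig")
}

validate_pipeline_config <- function(cfg) {
  num_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("config field '", field, "' must be positive and finite")
    }
  }
  thr <- cfg$morpho_intensity_threshold
  if (!(identical(thr, "auto") || (is.numeric(thr) && length(thr) == 1L && is.finite(thr)))) {
    stop("morpho_intensity_threshold must be a number or \"auto\"")
  }
  for (f in c("morpho_clean_min_voxels", "morpho_v_mdv", "morpho_v_network",
              "puncta_min_area", "puncta_mcherry_ratio", "puncta_gfp_absent_ratio",
              "puncta_match_radius", "puncta_background_radius",
              "dynamics_frangi_scales", "dynamics_semantic_threshold",
              "dynamics_max_speed", "stats_rout_q")) num_pos(f)
  if (cfg$morpho_v_mdv >= cfg$morpho_v_network) {
    stop("morpho_v_mdv must be smaller than morpho_v_network")
  }
  if (!is.numeric(cfg$stats_alpha) || cfg$stats_alpha <= 0 || cfg$stats_alpha >= 1) {
    stop("stats_alpha must lie in (0, 1)")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown fields are rejected; missing fields take their defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file whose keys match the
#'   arguments of [pipeline_config()].
#' @return A `PipelineConfig`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format '.", ext, "' (use JSON or YAML)")
  )
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration as JSON
#'
#' @param config a `PipelineConfig`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Provenance hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; embedded in every output table so
#' results can be traced back to the exact parameter set.
#'
#' @param config a `PipelineConfig` (or any list of plain values).
#' @return A 32-character hexadecimal string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  keys <- order(names(unclass(config)))
  jsonlite::write_json(unclass(config)[keys], tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
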