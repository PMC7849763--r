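#' Parse a YAML pipeline configuration
#'
#' Reads the configuration blocks `phantom`, `geometry`, `recon`, `tv`,
#' `demons`, `dvf`, `bilateral` and `pipeline`, applies defaults for every
#' missing key, validates invariants through the constructors, and rejects
#' unknown keys with the offending key path in the message. An empty or
#' missing file yields the full default (desk-scale) configuration.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @return a [pipeline_config()] with attribute `geometry_overrides`.
#' @export
parse_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  known_blocks <- c("phantom", "geometry", "recon", "tv", "demons", "dvf",
                    "bilateral", "pipeline")
  extra <- setdiff(names(raw), known_blocks)
  if (length(extra))
    stop("unknown configuration block(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  take <- function(block, allowed) {
    b <- raw[[block]]
    if (is.null(b)) return(list())
    bad <- setdiff(names(b), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in `%s`: %s", block,
                   paste0(block, ".", bad, collapse = ", ")), call. = FALSE)
    b
  }
  ph <- take("phantom", c("grid_shape", "voxel_mm", "n_phases", "period_s",
                          "diaphragm_si_mm", "chest_ap_mm", "heart_si_mm",
                          "attenuation", "tumor_center", "tumor_radius_mm",
                          "edge_mm", "seed"))
  if (!is.null(ph$attenuation)) ph$attenuation <- unlist(ph$attenuation)
  spec <- do.call(phantom_spec, ph)
  rc <- do.call(recon_config, utils::modifyList(
    list(lambda = 1, n_iter = 25L, lambda_decay = 1, tv_weight = 0),
    take("recon", c("lambda", "n_iter", "lambda_decay", "positivity",
                    "tv_weight", "tv_steps", "tol"))))
  tvc <- do.call(recon_config, utils::modifyList(
    list(n_iter = 10L, tv_weight = 0.3, tv_steps = 8L),
    take("tv", c("lambda", "n_iter", "lambda_decay", "positivity",
                 "tv_weight", "tv_steps", "tol"))))
  dm <- do.call(demons_config, take("demons", c("levels", "iterations",
                                                "sigma_fluid",
                                                "sigma_diffusion",
                                                "max_step_mm")))
  en <- do.call(energy_config, utils::modifyList(
    list(max_iter = 10L),
    take("dvf", c("beta", "beta_fraction", "regularizer", "max_iter",
                  "proj_interval", "tol", "tol_window", "ls_max", "ls_c",
                  "step0_vox"))))
  bl <- do.call(bilateral_params, take("bilateral", c("sigma_x", "sigma_mu",
                                                      "sigma_v", "halfwidth")))
  pl <- take("pipeline", c("outer", "views_per_phase", "seed"))
  cfg <- pipeline_config(phantom = spec, recon = rc, tv = tvc, demons = dm,
                         energy = en, bilateral = bl,
                         outer = pl$outer %||% 2L,
                         views_per_phase = pl$views_per_phase %||% 20L,
                         seed = pl$seed %||% 1L)
  attr(cfg, "geometry_overrides") <- take("geometry",
                                          c("sad", "sdd", "pitch", "margin"))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
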