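#' Pipeline run configuration
#'
#' Bundles the options of a full image-analysis run. A YAML file with
#' any of the same keys can be loaded first; explicit arguments
#' override file values, which override the defaults.
#'
#' @param method decomposition method: `"differential"`,
#'   `"lu_chipman"`, or `"both"`.
#' @param noise_floor_deg azimuth retardance floor in degrees (> 0).
#' @param cloude_tol Cloude realizability tolerance (> 0).
#' @param quiver_step_px quiver grid step in pixels (>= 1).
#' @param substrate_ref_path optional path to a 16-band reference TIFF
#'   whose mean matrix is used for substrate correction.
#' @param seed integer seed recorded with the run.
#' @param output_dir artifact directory.
#' @param yaml_path optional YAML config file.
#' @return an object of class `run_config`.
#' @export
run_config <- function(method = "both", noise_floor_deg = 3,
                       cloude_tol = 1e-6, quiver_step_px = 20L,
                       substrate_ref_path = NULL, seed = 1L,
                       output_dir = "muellerpol-out", yaml_path = NULL) {
  cfg <- list(method = method, noise_floor_deg = noise_floor_deg,
              cloude_tol = cloude_tol,
              quiver_step_px = as.integer(quiver_step_px),
              substrate_ref_path = substrate_ref_path,
              seed = as.integer(seed), output_dir = output_dir)
  if (!is.null(yaml_path)) {
    file_cfg <- yaml::read_yaml(yaml_path)
    supplied <- names(as.list(match.call()))[-1]
    for (k in names(file_cfg))
      if (k %in% names(cfg) && !(k %in% supplied)) cfg[[k]] <- file_cfg[[k]]
  }
  cfg$method <- match.arg(cfg$method, c("both", "differential", "lu_chipman"))
  if (cfg$noise_floor_deg < 0 || cfg$cloude_tol <= 0 ||
      cfg$quiver_step_px < 1)
    stop("invalid configuration: tolerances must be positive, step >= 1")
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline on a Mueller image file
#'
#' Reads a 16-band Mueller TIFF, applies normalization, optional
#' substrate correction and Cloude filtering, decomposes every pixel
#' with the configured method(s), and writes all artifacts to
#' `config$output_dir`: property-band TIFFs with CSV summary sidecars,
#' retardance/azimuth/depolarization box-whisker summaries, a quiver
#' CSV of the azimuth field, a cross-method comparison CSV when both
#' methods run, and a JSON run log echoing the configuration and the
#' per-reason pixel failure counts.
#'
#' @param config a [run_config()].
#' @param input_path path to a 16-band Mueller TIFF.
#' @return invisibly, a list with the artifact paths, the decomposition
#'   result, and the run log.
#' @export
run_pipeline <- function(config, input_path) {
  stopifnot(inherits(config, "run_config"))
  img <- read_mueller_image(input_path)
  ref <- NULL
  if (!is.null(config$substrate_ref_path)) {
    rimg <- read_mueller_image(config$substrate_ref_path)
    ref <- apply(rimg$pixels, c(3, 4), mean)
  }
  dec <- decompose_image(img, method = config$method,
                         config = list(noise_floor_deg = config$noise_floor_deg,
                                       cloude_tol = config$cloude_tol,
                                       substrate_ref = ref))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  summaries <- list()
  for (m in intersect(c("differential", "lu_chipman"), names(dec))) {
    g <- dec[[m]]
    p <- file.path(config$output_dir, paste0(m, "-maps.tif"))
    write_maps(list(rt_deg = g$rt_deg, theta_deg = g$theta_deg,
                    alpha_t = g$alpha_t),
               dec$mask, p)
    paths[[paste0(m, "_maps")]] <- p
    summaries[[m]] <- rbind(
      cbind(method = m, quantity = "retardance_deg",
            boxwhisker_summary(g$rt_deg, dec$mask, "rt_deg")),
      cbind(method = m, quantity = "azimuth_deg",
            azimuth_summary(g$theta_deg, g$rt_deg, dec$mask,
                            floor_deg = config$noise_floor_deg)),
      cbind(method = m, quantity = "depolarization",
            boxwhisker_summary(g$alpha_t, dec$mask, "alpha_t")))
    qv <- quiver_export(g$theta_deg, g$rt_deg, dec$mask,
                        grid_step_px = config$quiver_step_px)
    qp <- file.path(config$output_dir, paste0(m, "-quiver.csv"))
    utils::write.csv(qv, qp, row.names = FALSE)
    paths[[paste0(m, "_quiver")]] <- qp
  }
  sp <- file.path(config$output_dir, "summaries.csv")
  utils::write.csv(do.call(rbind, summaries), sp, row.names = FALSE)
  paths$summaries <- sp
  if (config$method == "both") {
    cmp <- compare_methods(dec$differential, dec$lu_chipman, dec$mask)
    cp <- file.path(config$output_dir, "method-comparison.csv")
    utils::write.csv(cmp$stats, cp, row.names = FALSE)
    paths$comparison <- cp
  }
  reasons <- table(factor(dec$mask$reason[!dec$mask$valid],
                          levels = c("non-physical", "decomposition-failed",
                                     "below-noise-floor", "no-tissue")))
  log <- list(config = unclass(config), input = input_path,
              n_pixels = prod(dim(img)), n_valid = sum(dec$mask$valid),
              failures = as.list(reasons))
  lp <- file.path(config$output_dir, "run-log.json")
  jsonlite::write_json(log, lp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  paths$log <- lp
  invisible(list(paths = paths, decomposition = dec, log = log))
}
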