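#' Write point features as GeoJSON
#'
#' Plain GeoJSON FeatureCollection of Point geometries in planar metre
#' coordinates; the (non-EPSG, simulation-local) CRS is declared in the
#' collection metadata.
#'
#' @param tbl data.table with an id column plus `x`, `y`.
#' @param path output file.
#' @param id_col name of the identifier column.
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(tbl, path, id_col = "point_id") {
  props <- setdiff(names(tbl), c("x", "y"))
  features <- lapply(seq_len(nrow(tbl)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(tbl$x[i], tbl$y[i])),
         properties = as.list(tbl[i, props, with = FALSE]))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(
                          name = "urn:perceptPA:planar-metres")),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read point features from GeoJSON written by [write_points_geojson()]
#' @param path GeoJSON file.
#' @return data.table with the properties plus `x`, `y`.
#' @export
read_points_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(fc$features, function(f) {
    out <- data.table::as.data.table(f$properties)
    out$x <- f$geometry$coordinates[[1]]
    out$y <- f$geometry$coordinates[[2]]
    out
  })
  data.table::rbindlist(rows)
}

#' Write the simulation ground truth as JSON
#' @param truth a [simulation_truth()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  obj <- unclass(truth)
  obj$indicator_weights <- as.data.frame(truth$indicator_weights)
  # named atomic vectors must serialise as objects, not bare arrays
  obj$beta <- as.list(truth$beta)
  obj$indicator_intercepts <- as.list(truth$indicator_intercepts)
  obj$pa_shares_alpha <- as.list(truth$pa_shares_alpha)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a simulation truth written by [write_truth_json()]
#' @param path JSON file.
#' @return a `simulation_truth` object.
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  simulation_truth(
    n_object_classes = obj$n_object_classes,
    indicator_weights = as.matrix(obj$indicator_weights),
    indicator_intercepts = obj$indicator_intercepts,
    rater_sd = obj$rater_sd,
    beta = unlist(obj$beta),
    sigma2_u = obj$sigma2_u,
    sigma2_e = obj$sigma2_e,
    outcome_transform = obj$outcome_transform,
    nbhd_concentration = obj$nbhd_concentration,
    image_concentration = obj$image_concentration,
    pa_shares_alpha = unlist(obj$pa_shares_alpha),
    days_lambda = obj$days_lambda)
}

#' Default pipeline configuration
#'
#' The single nested configuration consumed by [run_all()] and the CLI:
#' `world` ([world_config()] arguments), `truth` (overrides passed to
#' [simulation_truth()]), `scoring` ([scoring_config()] arguments) and
#' `pipeline` (primary/sensitivity buffer radii, outcome transform,
#' estimation method).
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(world = list(),
       truth = list(),
       scoring = list(initial_batch = 300L, max_calibration_images = 2000L),
       pipeline = list(radius_primary_m = 1000, radius_sensitivity_m = 1500,
                       transform = "log1p", method = "REML"))
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys fall back to [default_config()].
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config sections: ", paste(bad, collapse = ", "))
  for (sec in names(user)) cfg[[sec]] <- utils::modifyList(cfg[[sec]],
                                                           user[[sec]])
  cfg
}
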