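#' World configuration for the synthetic streetscape generator
#'
#' Describes the simulated study region: a planar rectangular grid road
#' network in projected metres, sampling points at a fixed spacing along the
#' roads, and neighbourhood centroids, mirroring a survey of 35 residential
#' neighbourhoods imaged at sampling points 100 m apart in four cardinal
#' headings with 1 km exposure buffers.
#'
#' @param n_neighbourhoods number of neighbourhoods (default 35).
#' @param respondents_per_nbhd_mean mean respondents per neighbourhood
#'   (default 23, so about 805 in total).
#' @param point_spacing_m sampling-point spacing along roads, metres
#'   (default 100).
#' @param n_object_classes scene object classes K (default 12 for the
#'   synthetic world; 150+ in real segmentations).
#' @param headings camera headings in degrees (default 0, 90, 180, 270).
#' @param buffer_radius_m exposure buffer radius, metres (default 1000).
#' @param block_m road-grid block size, metres (default 300).
#' @param cell_m neighbourhood layout cell size, metres (default 900).
#' @param seed integer seed driving world construction.
#' @return a validated `world_config` list.
#' @export
world_config <- function(n_neighbourhoods = 35L,
                         respondents_per_nbhd_mean = 23,
                         point_spacing_m = 100,
                         n_object_classes = 12L,
                         headings = c(0, 90, 180, 270),
                         buffer_radius_m = 1000,
                         block_m = 300,
                         cell_m = 900,
                         seed = 1L) {
  cfg <- list(n_neighbourhoods = as.integer(n_neighbourhoods),
              respondents_per_nbhd_mean = respondents_per_nbhd_mean,
              point_spacing_m = point_spacing_m,
              n_object_classes = as.integer(n_object_classes),
              headings = as.numeric(headings),
              buffer_radius_m = buffer_radius_m,
              block_m = block_m, cell_m = cell_m,
              seed = as.integer(seed))
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  if (cfg$n_neighbourhoods < 1L) stop("n_neighbourhoods must be >= 1")
  if (cfg$respondents_per_nbhd_mean < 1) stop("respondents mean must be >= 1")
  if (cfg$point_spacing_m <= 0) stop("point_spacing_m must be > 0")
  if (cfg$n_object_classes < 1L) stop("n_object_classes must be >= 1")
  if (anyDuplicated(cfg$headings)) stop("headings must be distinct")
  if (any(cfg$headings < 0 | cfg$headings >= 360))
    stop("headings must lie in [0, 360)")
  if (cfg$point_spacing_m > 2 * cfg$buffer_radius_m)
    stop("config error: point spacing exceeds twice the buffer radius; ",
         "neighbourhood centroids could be stranded without sampling points")
  invisible(cfg)
}

#' Positions of sampling points along a straight road segment
#'
#' Points are placed every `spacing_m` metres starting at 0, so a segment of
#' length L carries `floor(L / spacing) + 1` points.
#'
#' @param length_m segment length in metres.
#' @param spacing_m spacing in metres.
#' @return numeric vector of positions.
#' @export
sample_segment <- function(length_m, spacing_m) {
  if (spacing_m <= 0) stop("spacing must be > 0")
  seq(0, length_m, by = spacing_m)
}

#' Generate the synthetic world: sampling points and neighbourhood centroids
#'
#' Builds a rectangular grid of roads (`block_m` apart) over a square region
#' sized to hold all neighbourhoods, places sampling points every
#' `point_spacing_m` along each road (deduplicated at intersections), and
#' scatters one neighbourhood centroid per layout cell with a seeded jitter.
#' Every centroid is guaranteed at least one sampling point within the
#' buffer radius. Deterministic given `cfg$seed`.
#'
#' @param cfg a [world_config()].
#' @return list with `points` (point_id, x, y) and `neighbourhoods`
#'   (nbhd_id, x, y) data.tables.
#' @export
generate_world <- function(cfg) {
  validate_world_config(cfg)
  set.seed(stage_seed(cfg$seed, 1L))
  ncell <- ceiling(sqrt(cfg$n_neighbourhoods))
  region <- ncell * cfg$cell_m

  lines <- seq(0, region, by = cfg$block_m)
  along <- sample_segment(region, cfg$point_spacing_m)
  horiz <- data.table::CJ(y = lines, x = along)
  vert <- data.table::CJ(x = lines, y = along)
  pts <- unique(rbind(horiz[, .(x, y)], vert[, .(x, y)]))
  data.table::setorder(pts, x, y)
  pts[, point_id := sprintf("pt%05d", .I)]
  data.table::setcolorder(pts, c("point_id", "x", "y"))

  cells <- data.table::CJ(cx = seq_len(ncell), cy = seq_len(ncell))
  cells <- cells[seq_len(cfg$n_neighbourhoods)]
  jitter_scale <- cfg$cell_m / 4.5
  nb <- data.table::data.table(
    nbhd_id = sprintf("nb%02d", seq_len(cfg$n_neighbourhoods)),
    x = (cells$cx - 0.5) * cfg$cell_m +
      runif(cfg$n_neighbourhoods, -jitter_scale, jitter_scale),
    y = (cells$cy - 0.5) * cfg$cell_m +
      runif(cfg$n_neighbourhoods, -jitter_scale, jitter_scale))

  for (j in seq_len(nrow(nb))) {
    d2 <- (pts$x - nb$x[j])^2 + (pts$y - nb$y[j])^2
    if (min(d2) > cfg$buffer_radius_m^2)
      stop("internal: neighbourhood ", nb$nbhd_id[j],
           " has no sampling point within the buffer radius")
  }
  list(points = pts[], neighbourhoods = nb[])
}
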