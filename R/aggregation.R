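#' Point score from heading-level image scores
#'
#' Arithmetic mean of the image scores taken at one sampling point in its
#' different headings. With fewer than the expected number of headings the
#' mean is computed over what exists and flagged.
#'
#' @param scores numeric vector of heading scores (>= 1 required).
#' @param expected_headings number of headings expected (default 4).
#' @return list with `score`, `n_headings`, `flagged`.
#' @export
point_score <- function(scores, expected_headings = 4L) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L)
    stop("point has zero heading scores; cannot compute a point score")
  list(score = mean(scores), n_headings = length(scores),
       flagged = length(scores) < expected_headings)
}

#' Point-level score table from image scores
#'
#' Collapses a long image-score table to one row per (point, indicator) set
#' of mean scores, merged onto the point coordinates.
#'
#' @param image_scores long data.table: image_id, point_id, indicator, score.
#' @param points data.table with point_id, x, y.
#' @param expected_headings number of headings expected per point.
#' @return wide data.table: point_id, x, y, one score column per indicator,
#'   `n_headings`, `flagged`.
#' @export
point_score_table <- function(image_scores, points, expected_headings = 4L) {
  dt <- data.table::as.data.table(image_scores)
  agg <- dt[!is.na(score),
            .(score = mean(score), n_headings = .N),
            by = .(point_id, indicator)]
  wide <- data.table::dcast(agg, point_id ~ indicator, value.var = "score")
  nh <- agg[, .(n_headings = min(n_headings)), by = point_id]
  wide <- merge(wide, nh, by = "point_id")
  wide[, flagged := n_headings < expected_headings]
  out <- merge(data.table::as.data.table(points), wide, by = "point_id")
  data.table::setorder(out, point_id)
  out[]
}

#' Neighbourhood exposure score from sampling points in a circular buffer
#'
#' Mean of the point scores whose planar Euclidean distance from the
#' neighbourhood centroid is at most `radius_m` (boundary inclusive).
#'
#' @param points_scored data.table with x, y and the indicator column.
#' @param centroid length-2 numeric (x, y) in metres.
#' @param radius_m buffer radius in metres.
#' @param indicator name of the score column to aggregate.
#' @param nbhd_id label used in the empty-buffer error message.
#' @return list with `score` and `n_points`.
#' @export
neighbourhood_score <- function(points_scored, centroid, radius_m, indicator,
                                nbhd_id = "<unnamed>") {
  d2 <- (points_scored$x - centroid[1])^2 + (points_scored$y - centroid[2])^2
  inside <- d2 <= radius_m^2
  if (!any(inside))
    stop(sprintf("neighbourhood %s: no sampling points within %g m buffer",
                 nbhd_id, radius_m))
  list(score = mean(points_scored[[indicator]][inside]),
       n_points = sum(inside))
}

#' Neighbourhood exposure table over all indicators
#'
#' Applies [neighbourhood_score()] for every neighbourhood and indicator at
#' the given buffer radius. Points may contribute to several overlapping
#' buffers. Re-runnable at any radius for sensitivity analyses.
#'
#' @param points_scored point-level score table (from [point_score_table()]
#'   or [true_neighbourhood_scores()]'s internals).
#' @param neighbourhoods data.table with nbhd_id, x, y.
#' @param radius_m buffer radius in metres.
#' @param indicators indicator columns to aggregate.
#' @return data.table: nbhd_id, one column per indicator, n_points, radius_m.
#' @export
build_exposure_table <- function(points_scored, neighbourhoods, radius_m,
                                 indicators = PERCEPT_INDICATORS) {
  missing_ind <- setdiff(indicators, names(points_scored))
  if (length(missing_ind))
    stop("point table lacks indicator columns: ",
         paste(missing_ind, collapse = ", "))
  rows <- lapply(seq_len(nrow(neighbourhoods)), function(j) {
    centroid <- c(neighbourhoods$x[j], neighbourhoods$y[j])
    cell <- lapply(indicators, function(ind)
      neighbourhood_score(points_scored, centroid, radius_m, ind,
                          nbhd_id = neighbourhoods$nbhd_id[j]))
    out <- data.table::as.data.table(
      setNames(lapply(cell, `[[`, "score"), indicators))
    out[, nbhd_id := neighbourhoods$nbhd_id[j]]
    out[, n_points := cell[[1]]$n_points]
    out
  })
  tbl <- data.table::rbindlist(rows)
  tbl[, radius_m := radius_m]
  data.table::setcolorder(tbl, c("nbhd_id", indicators,
                                 "n_points", "radius_m"))
  tbl[]
}
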