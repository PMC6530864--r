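## Cluster-geometry statistics: separation angle, NTC distance,
## compactness, and per-cluster summaries.  All geometry is anchored on
## the NTC centroid; angles are in radians throughout.

## floor tiny negatives (|delta| < 1e-12) to 0, then restrict to the
## first quadrant
.clamp_angle <- function(a) pmin(pmax(a, 0), pi / 2)

.deltas <- function(x, y, ntc) {
  if (inherits(ntc, "ntc_reference")) ntc <- ntc$centroid
  dx <- x - ntc[1]; dy <- y - ntc[2]
  dx[abs(dx) < 1e-12] <- 0
  dy[abs(dy) < 1e-12] <- 0
  list(dx = dx, dy = dy)
}

#' Separation angle of a point from the X axis, anchored at the NTC
#'
#' The angle between the horizontal axis and the line joining the NTC
#' centroid to a data point: \eqn{\alpha = \arctan(\Delta y / \Delta x)}
#' with \eqn{\Delta x, \Delta y} the channel differences from the NTC
#' centroid.  Computed via \code{atan2} so that on-axis allele-2 points
#' (\eqn{\Delta x = 0}) are well defined, and clamped to \eqn{[0, \pi/2]}
#' (genotyping signal sits in the first quadrant relative to the NTC;
#' deltas smaller than 1e-12 in magnitude are floored to zero first).
#'
#' @param x,y Signal coordinates (vectors of equal length).
#' @param ntc An [ntc_reference()] or a length-2 numeric centroid.
#' @return Angle(s) in radians, in \eqn{[0, \pi/2]}.
#' @examples
#' separation_angle(4, 4, c(1, 1))   # pi/4
#' separation_angle(3, 4, c(0, 0))   # atan(4/3)
#' @export
separation_angle <- function(x, y, ntc) {
  d <- .deltas(x, y, ntc)
  if (any(d$dx == 0 & d$dy == 0))
    stop("separation angle undefined: point coincides with NTC centroid",
         call. = FALSE)
  .clamp_angle(atan2(d$dy, d$dx))
}

#' Euclidean distance from the NTC centroid
#'
#' \eqn{D = \sqrt{\Delta x^2 + \Delta y^2}} with deltas taken from the NTC
#' centroid.
#'
#' @inheritParams separation_angle
#' @return Non-negative distance(s).
#' @examples
#' ntc_distance(3, 4, c(0, 0))  # 5
#' @export
ntc_distance <- function(x, y, ntc) {
  d <- .deltas(x, y, ntc)
  sqrt(d$dx^2 + d$dy^2)
}

#' Cluster compactness
#'
#' The sample standard deviation (divisor n - 1) of the Euclidean
#' distances between each cluster member and the cluster centroid (the
#' per-channel mean).  Small values mean tight clusters.  Undefined
#' (\code{NA}) for clusters of fewer than two points.
#'
#' @param x,y Coordinates of the cluster members.
#' @return Non-negative scalar, or \code{NA_real_} when n < 2.
#' @examples
#' compactness(c(0, 0, 1, -1), c(1, -1, 0, 0))  # equidistant ring: 0
#' @export
compactness <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2L) return(NA_real_)
  cx <- mean(x); cy <- mean(y)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  stats::sd(d)
}

#' Per-cluster geometry summaries
#'
#' Computes, for every (assay, platform, genotype label) cluster of called
#' points, the centroid, size, compactness, separation angle and NTC
#' distance.  With \code{unit = "per_cluster"} (default) the angle and
#' distance are evaluated once at the cluster centroid; with
#' \code{"per_point"} they are the arithmetic means of the per-point
#' values (angles stay well below \eqn{\pi/2} wrap-around, so plain
#' averaging is appropriate).  The conventional platform comparison
#' restricts angle and compactness to the allele-1 homozygote cluster;
#' set \code{a11_only = TRUE} for that view.
#'
#' @param points Plate fluorescence table (provides coordinates and NTC
#'   wells).
#' @param calls Matching call table.
#' @param unit \code{"per_cluster"} or \code{"per_point"} aggregation for
#'   angle and distance.
#' @param a11_only If \code{TRUE}, keep only A11 clusters.
#' @return Data frame with columns \code{assay_id}, \code{platform_id},
#'   \code{label}, \code{n}, \code{centroid_x}, \code{centroid_y},
#'   \code{mean_angle}, \code{mean_ntc_distance}, \code{compactness}.
#'   Labels with zero called points are omitted.
#' @export
summarize_clusters <- function(points, calls,
                               unit = c("per_cluster", "per_point"),
                               a11_only = FALSE) {
  unit <- match.arg(unit)
  key <- c("sample_id", "assay_id", "platform_id")
  m <- merge(points, calls, by = key, sort = FALSE)
  m <- m[m$label %in% c("A11", "A12", "A22"), , drop = FALSE]
  if (a11_only) m <- m[m$label == "A11", , drop = FALSE]
  if (!nrow(m)) return(data.frame())
  ntc_key <- paste(points$assay_id, points$platform_id, sep = "\r")
  ntc_refs <- lapply(split(points, ntc_key), ntc_reference)
  grp <- interaction(m$assay_id, m$platform_id, m$label, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(m)), grp), function(i) {
    blk <- m[i, , drop = FALSE]
    ntc <- ntc_refs[[paste(blk$assay_id[1], blk$platform_id[1],
                           sep = "\r")]]
    cx <- mean(blk$signal_x); cy <- mean(blk$signal_y)
    if (unit == "per_cluster") {
      ang <- separation_angle(cx, cy, ntc)
      dist <- ntc_distance(cx, cy, ntc)
    } else {
      ang <- mean(separation_angle(blk$signal_x, blk$signal_y, ntc))
      dist <- mean(ntc_distance(blk$signal_x, blk$signal_y, ntc))
    }
    data.frame(assay_id = blk$assay_id[1],
               platform_id = blk$platform_id[1], label = blk$label[1],
               n = nrow(blk), centroid_x = cx, centroid_y = cy,
               mean_angle = ang, mean_ntc_distance = dist,
               compactness = compactness(blk$signal_x, blk$signal_y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$assay_id, out$platform_id, out$label), ]
  rownames(out) <- NULL
  out
}
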