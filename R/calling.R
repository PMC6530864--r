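## Allele calling anchored on the no-template-control (NTC) centroid.
##
## Three-stage caller, run independently per assay x platform:
##   1. FAILED  — background-level wells near the NTC centroid;
##   2. INVALID — amplified but too dim to classify;
##   3. genotype assignment by angle-ordered k-means in
##      (separation angle, log NTC distance), labels A11/A12/A22 by
##      ascending mean angle, quality = posterior under an
##      isotropic-Gaussian mixture over the final clusters.
## All thresholds are relative to the assay's own fluorescence scale, so
## calling is invariant under rescaling of both channels.

#' NTC reference for one assay on one platform
#'
#' Summarizes the no-template-control wells whose mean signal anchors all
#' cluster geometry: the per-channel mean (centroid) and the RMS distance
#' of NTC wells from that centroid (spread; 0 when there is a single NTC).
#'
#' @param points Data frame of fluorescence points for one assay x
#'   platform, containing at least one row with \code{is_ntc = TRUE}.
#' @return An object of class \code{"ntc_reference"}: list with
#'   \code{centroid} (length-2 numeric), \code{spread}, \code{n_ntc}.
#' @examples
#' pts <- data.frame(signal_x = c(1, 3), signal_y = c(1, 3),
#'                   is_ntc = TRUE)
#' ntc_reference(pts)  # centroid (2, 2), spread sqrt(2)
#' @export
ntc_reference <- function(points) {
  ntc <- points[points$is_ntc, , drop = FALSE]
  if (!nrow(ntc))
    stop("no NTC wells found: cannot build an NTC reference",
         call. = FALSE)
  cx <- mean(ntc$signal_x); cy <- mean(ntc$signal_y)
  d2 <- (ntc$signal_x - cx)^2 + (ntc$signal_y - cy)^2
  structure(list(centroid = c(cx, cy), spread = sqrt(mean(d2)),
                 n_ntc = nrow(ntc)),
            class = "ntc_reference")
}

#' @export
print.ntc_reference <- function(x, ...) {
  cat(sprintf("NTC reference: centroid (%.4g, %.4g), spread %.4g, n = %d\n",
              x$centroid[1], x$centroid[2], x$spread, x$n_ntc))
  invisible(x)
}

#' Caller parameters
#'
#' Tuning parameters of the three-stage allele caller.
#'
#' @param failed_radius_mult Wells within this multiple of the NTC spread
#'   of the NTC centroid are FAILED (default 3).
#' @param failed_floor_frac Lower bound on the FAILED radius, as a fraction
#'   of the assay's 90th-percentile NTC distance (default 0.05).  With very
#'   few NTC wells the RMS spread badly underestimates the background
#'   scatter (with two NTCs it is half their separation), so the
#'   multiplier alone misses a sizeable share of true dropouts; the floor
#'   keeps the FAILED radius at background scale regardless.
#' @param invalid_radius_frac Amplified wells closer to the NTC centroid
#'   than this fraction of the assay's 90th-percentile NTC distance are
#'   INVALID (default 0.25).
#' @param min_quality Genotype calls with mixture-posterior quality below
#'   this value are demoted to INVALID (default 0, i.e. disabled).
#' @return An object of class \code{"caller_params"}.
#' @export
caller_params <- function(failed_radius_mult = 3, failed_floor_frac = 0.05,
                          invalid_radius_frac = 0.25, min_quality = 0) {
  stopifnot(failed_radius_mult > 0, failed_floor_frac >= 0,
            invalid_radius_frac > 0, invalid_radius_frac < 1,
            min_quality >= 0, min_quality <= 1)
  structure(list(failed_radius_mult = failed_radius_mult,
                 failed_floor_frac = failed_floor_frac,
                 invalid_radius_frac = invalid_radius_frac,
                 min_quality = min_quality, k = 3L),
            class = "caller_params")
}

## deterministic Lloyd k-means with fixed initial centers; empty clusters
## simply keep their center and end up with zero members
.lloyd <- function(feat, centers, iter_max = 100L) {
  assign <- integer(nrow(feat))
  for (it in seq_len(iter_max)) {
    d2 <- vapply(seq_len(nrow(centers)), function(k)
      (feat[, 1] - centers[k, 1])^2 + (feat[, 2] - centers[k, 2])^2,
      numeric(nrow(feat)))
    new_assign <- max.col(-d2, ties.method = "first")
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (k in seq_len(nrow(centers))) {
      m <- assign == k
      if (any(m)) centers[k, ] <- colMeans(feat[m, , drop = FALSE])
    }
  }
  assign
}

## reference angles used for initialization and for labelling clusters
## when fewer than three survive (degrees: 15, 45, 75)
.ref_angles <- c(A11 = 15, A12 = 45, A22 = 75) * pi / 180

#' Call alleles for one assay on one platform
#'
#' Classifies every non-NTC well of one assay x platform into
#' A11/A12/A22/INVALID/FAILED with a quality score, using the documented
#' three-stage algorithm described in \code{vignette("snpplate-methods")}:
#' a background (FAILED) radius around the NTC centroid, a low-fluorescence
#' (INVALID) radius relative to the assay's own signal scale, then
#' angle-ordered k-means with k = 3 in (separation angle, log NTC
#' distance) with clusters labelled by ascending mean angle.  Cluster
#' membership quality is the posterior probability of the assigned
#' component under an isotropic Gaussian mixture fitted to the final
#' clusters in the fluorescence plane.  Clusters with fewer than two
#' members are merged into their angular neighbour before labelling.
#'
#' @param points Fluorescence points of a single assay x platform
#'   (including its NTC wells, which are passed through labelled
#'   \code{"NTC"}).
#' @param ntc An [ntc_reference()] for the same assay x platform; computed
#'   from \code{points} when omitted.
#' @param params A [caller_params()] object.
#' @return A call table: data frame with columns \code{sample_id},
#'   \code{assay_id}, \code{platform_id}, \code{label}, \code{quality}
#'   (quality is \code{NA} for non-genotype labels), one row per input
#'   point, in input order.
#' @export
call_assay <- function(points, ntc = NULL, params = caller_params()) {
  if (length(unique(points$assay_id[!points$is_ntc])) > 1L ||
      length(unique(points$platform_id)) > 1L)
    stop("call_assay() expects points from a single assay x platform",
         call. = FALSE)
  if (is.null(ntc)) ntc <- ntc_reference(points)
  out <- data.frame(sample_id = points$sample_id,
                    assay_id = points$assay_id,
                    platform_id = points$platform_id,
                    label = NA_character_, quality = NA_real_,
                    stringsAsFactors = FALSE)
  out$label[points$is_ntc] <- "NTC"
  idx <- which(!points$is_ntc)
  if (!length(idx)) return(out)

  dx <- points$signal_x[idx] - ntc$centroid[1]
  dy <- points$signal_y[idx] - ntc$centroid[2]
  d <- sqrt(dx^2 + dy^2)
  q90 <- stats::quantile(d, 0.9, names = FALSE, type = 7)

  ## stage 1: FAILED
  r_fail <- max(params$failed_radius_mult * ntc$spread,
                params$failed_floor_frac * q90)
  failed <- d <= r_fail
  out$label[idx[failed]] <- "FAILED"

  ## stage 2: INVALID (relative to amplified signal scale)
  amp <- !failed
  if (any(amp)) {
    q90_amp <- stats::quantile(d[amp], 0.9, names = FALSE, type = 7)
    invalid <- amp & d < params$invalid_radius_frac * q90_amp
    out$label[idx[invalid]] <- "INVALID"
  } else invalid <- amp

  ## stage 3: genotype clusters
  keep <- amp & !invalid
  if (sum(keep) < 3L) {
    out$label[idx[keep]] <- "INVALID"   # assay uncallable
    attr(out, "uncallable") <- TRUE
    return(out)
  }
  ang <- .clamp_angle(atan2(dy[keep], dx[keep]))
  lr <- log(d[keep])
  feat <- cbind(ang, lr)
  centers <- cbind(.ref_angles, rep(log(stats::median(d[keep])), 3))
  cl <- .lloyd(feat, centers)

  ## merge clusters with < 2 members into the angular neighbour
  repeat {
    sizes <- tabulate(cl, nbins = max(cl))
    live <- which(sizes > 0)
    small <- live[sizes[live] < 2]
    if (!length(small) || length(live) == 1L) break
    means <- vapply(live, function(k) mean(ang[cl == k]), 0)
    k <- small[1]
    others <- setdiff(live, k)
    tgt <- others[which.min(abs(means[match(others, live)] -
                                  means[match(k, live)]))]
    cl[cl == k] <- tgt
  }

  ## label clusters: three -> ascending mean angle; fewer -> nearest
  ## reference angle, disambiguated by angle order
  live <- sort(unique(cl))
  means <- vapply(live, function(k) mean(ang[cl == k]), 0)
  ord <- order(means)
  lbl <- character(length(live))
  if (length(live) == 3L) {
    lbl[ord] <- c("A11", "A12", "A22")
  } else {
    nearest <- vapply(means, function(m)
      which.min(abs(.ref_angles - m)), 0L)
    if (anyDuplicated(nearest)) {
      ## fall back to pure angle ordering over the label alphabet
      lbl[ord] <- c("A11", "A12", "A22")[seq_along(live)]
    } else lbl <- c("A11", "A12", "A22")[nearest]
  }
  geno <- lbl[match(cl, live)]
  out$label[idx[keep]] <- geno

  ## quality: posterior under isotropic Gaussian mixture on (x, y)
  X <- cbind(points$signal_x[idx[keep]], points$signal_y[idx[keep]])
  sig_floor <- 1e-9 * max(q90, .Machine$double.eps)
  logdens <- matrix(-Inf, nrow(X), length(live))
  for (j in seq_along(live)) {
    m <- cl == live[j]
    mu <- colMeans(X[m, , drop = FALSE])
    s2 <- mean((X[m, 1] - mu[1])^2 + (X[m, 2] - mu[2])^2) / 2
    s <- max(sqrt(s2), sig_floor)
    d2 <- (X[, 1] - mu[1])^2 + (X[, 2] - mu[2])^2
    logdens[, j] <- log(sum(m) / nrow(X)) - log(2 * pi * s^2) -
      d2 / (2 * s^2)
  }
  own <- match(cl, live)
  mx <- apply(logdens, 1, max)
  post <- exp(logdens - mx)
  qual <- post[cbind(seq_len(nrow(X)), own)] / rowSums(post)
  out$quality[idx[keep]] <- qual

  if (params$min_quality > 0) {
    demote <- idx[keep][qual < params$min_quality]
    out$label[demote] <- "INVALID"
    out$quality[demote] <- NA_real_
  }
  out
}

#' Call alleles for a whole experiment
#'
#' Applies [call_assay()] to every assay x platform combination of a plate
#' table (each with its own NTC reference) and binds the results.
#'
#' @param points Plate fluorescence table (any number of assays and
#'   platforms; NTC wells present per assay x platform).
#' @param params A [caller_params()] object.
#' @return A call table covering all points, in input order within each
#'   assay x platform block.
#' @examples
#' exp <- simulate_experiment(default_three_platform_config(seed = 1))
#' calls <- call_plate(exp$points)
#' table(calls$platform_id, calls$label)
#' @export
call_plate <- function(points, params = caller_params()) {
  key <- interaction(points$assay_id, points$platform_id, drop = TRUE)
  parts <- lapply(split(seq_len(nrow(points)), key), function(i) {
    blk <- points[i, , drop = FALSE]
    call_assay(blk, ntc_reference(blk), params)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Per-platform call-rate summary
#'
#' Tabulates, per platform, the number of non-NTC wells, the failed and
#' amplified percentages, and the invalid and genotype-called counts.
#' Invalid wells count as amplified (they produced signal, too dim to
#' classify).
#'
#' @param calls A call table (from [call_plate()] or [read_calls()]).
#' @return Data frame with one row per platform: \code{platform_id},
#'   \code{n_points}, \code{n_called}, \code{n_invalid}, \code{n_failed},
#'   \code{failed_pct}, \code{amplified_pct}.
#' @export
call_rate_summary <- function(calls) {
  calls <- calls[calls$label != "NTC", , drop = FALSE]
  if (!nrow(calls)) stop("empty call table", call. = FALSE)
  platforms <- unique(calls$platform_id)
  rows <- lapply(platforms, function(p) {
    cl <- calls$label[calls$platform_id == p]
    n <- length(cl)
    nf <- sum(cl == "FAILED")
    data.frame(platform_id = p, n_points = n,
               n_called = sum(cl %in% c("A11", "A12", "A22")),
               n_invalid = sum(cl == "INVALID"), n_failed = nf,
               failed_pct = 100 * nf / n,
               amplified_pct = 100 - 100 * nf / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
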