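#' Platform fluorescence profile
#'
#' Describes how one genotyping chemistry (e.g. KASP, TaqMan, rhAmp) maps
#' genotype clusters into the two-channel endpoint-fluorescence plane.
#' Cluster centroids are parameterized in polar coordinates around the
#' no-template-control (NTC) centre: a homozygote sits at radius
#' \code{gain} along its allele axis, the heterozygote at radius
#' \code{het_radius * gain} along the diagonal, and every called well is
#' scattered isotropically around its centroid with standard deviation
#' \code{noise_sd} per channel.
#'
#' @param platform_id Platform name (character scalar).
#' @param gain Mean NTC-to-homozygote-centroid distance, in normalized
#'   fluorescence units. Strictly positive.
#' @param angle_a11 Mean separation angle (radians) of the allele-1
#'   homozygote cluster from the X axis; in (0, pi/4).
#' @param angle_a22 Mean separation angle of the allele-2 homozygote
#'   cluster; in (pi/4, pi/2).
#' @param angle_a12 Mean separation angle of the heterozygote cluster;
#'   defaults to the diagonal, pi/4.
#' @param noise_sd Isotropic per-channel fluorescence standard deviation of
#'   called wells (non-negative; 0 gives noiseless clusters).
#' @param fail_rate Probability that a well fails to amplify; such wells
#'   emit NTC-like background only.
#' @param invalid_rate Probability that a well amplifies with fluorescence
#'   too low to classify.
#' @param ntc_center Background fluorescence centre, length-2 non-negative
#'   numeric (x, y).
#' @param ntc_sd Standard deviation of NTC/background scatter per channel
#'   (non-negative).
#' @param het_radius Heterozygote radius as a fraction of \code{gain};
#'   defaults to 1/sqrt(2) so each channel carries roughly one allele's
#'   worth of signal.
#' @param angle_jitter_sd Per-assay jitter (radians, SD) applied to the
#'   planted cluster angles; 0 by default (all assays share the profile
#'   geometry).
#'
#' @return An object of class \code{"platform_profile"}.
#' @seealso [sim_config()], [default_three_platform_config()]
#' @export
platform_profile <- function(platform_id, gain, angle_a11, angle_a22,
                             angle_a12 = pi / 4, noise_sd,
                             fail_rate = 0, invalid_rate = 0,
                             ntc_center = c(0.25, 0.25), ntc_sd = 0.02,
                             het_radius = 1 / sqrt(2),
                             angle_jitter_sd = 0) {
  stopifnot(is.character(platform_id), length(platform_id) == 1L)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a finite numeric scalar", nm), call. = FALSE)
    x
  }
  gain <- num1(gain, "gain"); noise_sd <- num1(noise_sd, "noise_sd")
  angle_a11 <- num1(angle_a11, "angle_a11")
  angle_a12 <- num1(angle_a12, "angle_a12")
  angle_a22 <- num1(angle_a22, "angle_a22")
  fail_rate <- num1(fail_rate, "fail_rate")
  invalid_rate <- num1(invalid_rate, "invalid_rate")
  ntc_sd <- num1(ntc_sd, "ntc_sd")
  het_radius <- num1(het_radius, "het_radius")
  angle_jitter_sd <- num1(angle_jitter_sd, "angle_jitter_sd")
  if (gain <= 0) stop("'gain' must be > 0", call. = FALSE)
  if (noise_sd < 0 || ntc_sd < 0 || angle_jitter_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (!(angle_a11 > 0 && angle_a11 < angle_a12 && angle_a12 < angle_a22 &&
        angle_a22 < pi / 2))
    stop("need 0 < angle_a11 < angle_a12 < angle_a22 < pi/2", call. = FALSE)
  if (fail_rate < 0 || invalid_rate < 0 || fail_rate + invalid_rate > 1)
    stop("fail_rate + invalid_rate must lie in [0, 1]", call. = FALSE)
  if (length(ntc_center) != 2L || any(!is.finite(ntc_center)) ||
      any(ntc_center < 0))
    stop("'ntc_center' must be two non-negative finite values", call. = FALSE)
  if (het_radius <= 0) stop("'het_radius' must be > 0", call. = FALSE)
  structure(list(platform_id = platform_id, gain = gain,
                 angle_a11 = angle_a11, angle_a12 = angle_a12,
                 angle_a22 = angle_a22, noise_sd = noise_sd,
                 fail_rate = fail_rate, invalid_rate = invalid_rate,
                 ntc_center = as.numeric(ntc_center), ntc_sd = ntc_sd,
                 het_radius = het_radius, angle_jitter_sd = angle_jitter_sd),
            class = "platform_profile")
}

#' Simulation configuration for a multi-platform genotyping experiment
#'
#' Bundles the experimental layout (samples, NTC wells, assays), the
#' genotype-frequency model and the platform profiles into one seeded,
#' reproducible configuration. The genotype of a sample at an assay is a
#' property of the DNA: it is drawn once and shared by every platform.
#'
#' @param platforms List of [platform_profile()] objects (at least one).
#' @param n_samples Number of DNA samples per assay plate (default 94).
#' @param n_ntc Number of no-template-control wells per assay (default 2).
#' @param n_assays Number of SNP assays (default 29).
#' @param maf Allele-2 frequency per assay: a scalar in (0,1), a vector of
#'   length \code{n_assays}, or \code{NULL} (default) to draw each assay's
#'   frequency uniformly from \code{maf_range}.
#' @param maf_range Range used when \code{maf} is \code{NULL};
#'   default \code{c(0.15, 0.5)}.
#' @param het_model Either \code{"fixed_fraction"} (default; a fixed
#'   expected heterozygote fraction, appropriate for largely inbred panels)
#'   or \code{"hardy_weinberg"}.
#' @param het_fraction Expected heterozygote fraction under
#'   \code{"fixed_fraction"}; default 0.05.
#' @param seed Integer seed; the single entropy source for the experiment.
#'
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(platforms, n_samples = 94L, n_ntc = 2L,
                       n_assays = 29L, maf = NULL,
                       maf_range = c(0.15, 0.5),
                       het_model = c("fixed_fraction", "hardy_weinberg"),
                       het_fraction = 0.05, seed = 1L) {
  het_model <- match.arg(het_model)
  if (inherits(platforms, "platform_profile")) platforms <- list(platforms)
  if (!length(platforms) ||
      !all(vapply(platforms, inherits, TRUE, "platform_profile")))
    stop("'platforms' must be a list of platform_profile objects",
         call. = FALSE)
  ids <- vapply(platforms, `[[`, "", "platform_id")
  if (anyDuplicated(ids)) stop("duplicate platform_id", call. = FALSE)
  n_samples <- as.integer(n_samples); n_ntc <- as.integer(n_ntc)
  n_assays <- as.integer(n_assays)
  if (n_samples < 1L || n_assays < 1L || n_ntc < 0L)
    stop("invalid layout sizes", call. = FALSE)
  if (!is.null(maf)) {
    if (!length(maf) %in% c(1L, n_assays) || any(maf <= 0) || any(maf >= 1))
      stop("'maf' must be in (0,1), length 1 or n_assays", call. = FALSE)
  }
  if (het_fraction < 0 || het_fraction > 1)
    stop("'het_fraction' must be in [0,1]", call. = FALSE)
  structure(list(platforms = platforms, n_samples = n_samples,
                 n_ntc = n_ntc, n_assays = n_assays, maf = maf,
                 maf_range = maf_range, het_model = het_model,
                 het_fraction = het_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default three-platform configuration
#'
#' Returns the package's reference scenario: a 94-sample + 2-NTC, 29-assay
#' experiment genotyped on rhAmp, KASP and TaqMan profiles.  The planted
#' geometry encodes the qualitative contrasts reported for these
#' chemistries: rhAmp has by far the highest fluorescence gain (longest
#' NTC-to-cluster distance), TaqMan the tightest clusters but the widest
#' allele-1 separation angle, and the failed/invalid rates follow the
#' observed ordering (TaqMan most dropouts, rhAmp fewest).  Profile
#' parameters are fixed constants; \code{seed} only selects the sampling
#' stream.
#'
#' @param seed Integer seed forwarded to [sim_config()].
#' @return A \code{"sim_config"} object with three platform profiles.
#' @export
default_three_platform_config <- function(seed = 1L) {
  rh <- platform_profile("rhAmp", gain = 5.01,
                         angle_a11 = 0.19, angle_a22 = pi / 2 - 0.19,
                         noise_sd = 0.20, fail_rate = 0.030,
                         invalid_rate = 7 / 2784,
                         ntc_center = c(0.40, 0.40), ntc_sd = 0.075)
  ka <- platform_profile("KASP", gain = 1.51,
                         angle_a11 = 0.19, angle_a22 = pi / 2 - 0.19,
                         noise_sd = 0.10, fail_rate = 0.065,
                         invalid_rate = 13 / 2784,
                         ntc_center = c(0.20, 0.20), ntc_sd = 0.023)
  tq <- platform_profile("TaqMan", gain = 1.93,
                         angle_a11 = 0.35, angle_a22 = pi / 2 - 0.35,
                         noise_sd = 0.055, fail_rate = 0.070,
                         invalid_rate = 57 / 2784,
                         ntc_center = c(0.25, 0.25), ntc_sd = 0.029)
  sim_config(list(rh, ka, tq), seed = seed)
}

# deterministic per-platform substream seed, kept < 2^31
.platform_seed <- function(seed, i) {
  (abs(as.integer(seed)) + 10007L * i) %% 2147483629L
}

.well_label <- function(idx) {
  pos <- (idx - 1L) %% 384L
  sprintf("%s%02d", LETTERS[pos %/% 24L + 1L], pos %% 24L + 1L)
}

#' Simulate a multi-platform endpoint-fluorescence experiment
#'
#' Generates per-well two-channel fluorescence for every platform in the
#' configuration, together with the ground truth (planted genotype and
#' per-platform well outcome).  Genotypes are drawn once per sample x assay
#' and shared across platforms; amplification outcomes and fluorescence are
#' platform-specific and generated from deterministic per-platform
#' substreams of the single configuration seed.
#'
#' For a called well the signal is isotropic Gaussian around the planted
#' centroid; a failed well emits NTC-like background; an invalid well is
#' placed at its genotype's angle at a radius drawn uniformly between
#' \code{2 * ntc_sd} and \code{0.25 * gain} (amplified, but too dim to
#' classify). NTC wells are background draws flagged \code{is_ntc}.
#'
#' @param config A [sim_config()] object.
#' @return An object of class \code{"plate_experiment"}: a list with
#'   \itemize{
#'     \item \code{points}: data frame with columns \code{well_id},
#'       \code{sample_id}, \code{assay_id}, \code{platform_id},
#'       \code{signal_x}, \code{signal_y}, \code{is_ntc};
#'     \item \code{truth}: data frame with \code{sample_id},
#'       \code{assay_id}, \code{true_genotype} and one
#'       \code{outcome_<platform>} column per platform
#'       (\code{"called"}, \code{"failed"} or \code{"invalid"});
#'     \item \code{config}: the configuration used.
#'   }
#' @examples
#' cfg <- default_three_platform_config(seed = 7)
#' exp <- simulate_experiment(cfg)
#' table(exp$points$platform_id)
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object", call. = FALSE)
  ns <- config$n_samples; nn <- config$n_ntc; na <- config$n_assays
  sample_ids <- sprintf("S%03d", seq_len(ns))
  assay_ids <- sprintf("ASSAY%02d", seq_len(na))

  ## --- truth: genotypes shared across platforms -------------------------
  set.seed(config$seed)
  maf <- config$maf
  if (is.null(maf)) {
    maf <- stats::runif(na, config$maf_range[1], config$maf_range[2])
  } else if (length(maf) == 1L) maf <- rep(maf, na)
  geno <- matrix("", nrow = ns, ncol = na)
  for (a in seq_len(na)) {
    q <- maf[a]
    pr <- if (config$het_model == "hardy_weinberg") {
      c(A11 = (1 - q)^2, A12 = 2 * q * (1 - q), A22 = q^2)
    } else {
      h <- config$het_fraction
      c(A11 = (1 - h) * (1 - q), A12 = h, A22 = (1 - h) * q)
    }
    geno[, a] <- sample(names(pr), ns, replace = TRUE, prob = pr)
  }
  truth <- data.frame(
    sample_id = rep(sample_ids, times = na),
    assay_id = rep(assay_ids, each = ns),
    true_genotype = as.vector(geno),
    stringsAsFactors = FALSE)

  ## --- per-platform outcomes and signals --------------------------------
  points <- vector("list", length(config$platforms))
  for (i in seq_along(config$platforms)) {
    p <- config$platforms[[i]]
    set.seed(.platform_seed(config$seed, i))
    ang <- c(A11 = p$angle_a11, A12 = p$angle_a12, A22 = p$angle_a22)
    rad <- c(A11 = 1, A12 = p$het_radius, A22 = 1) * p$gain
    n_cells <- ns * na
    u <- stats::runif(n_cells)
    outcome <- ifelse(u < p$fail_rate, "failed",
                      ifelse(u < p$fail_rate + p$invalid_rate,
                             "invalid", "called"))
    jit <- if (p$angle_jitter_sd > 0)
      stats::rnorm(na, 0, p$angle_jitter_sd) else numeric(na)
    g <- truth$true_genotype
    a_idx <- rep(seq_len(na), each = ns)
    theta <- ang[g] + jit[a_idx]
    r <- rad[g]
    sx <- p$ntc_center[1] + r * cos(theta)
    sy <- p$ntc_center[2] + r * sin(theta)
    called <- outcome == "called"
    sx[called] <- sx[called] + stats::rnorm(sum(called), 0, p$noise_sd)
    sy[called] <- sy[called] + stats::rnorm(sum(called), 0, p$noise_sd)
    failed <- outcome == "failed"
    sx[failed] <- p$ntc_center[1] + stats::rnorm(sum(failed), 0, p$ntc_sd)
    sy[failed] <- p$ntc_center[2] + stats::rnorm(sum(failed), 0, p$ntc_sd)
    invalid <- outcome == "invalid"
    if (any(invalid)) {
      rin <- stats::runif(sum(invalid), 2 * p$ntc_sd, 0.25 * p$gain)
      sx[invalid] <- p$ntc_center[1] + rin * cos(theta[invalid])
      sy[invalid] <- p$ntc_center[2] + rin * sin(theta[invalid])
    }
    dat <- data.frame(
      sample_id = truth$sample_id, assay_id = truth$assay_id,
      platform_id = p$platform_id, signal_x = sx, signal_y = sy,
      is_ntc = FALSE, outcome = outcome, stringsAsFactors = FALSE)
    if (nn > 0L) {
      ntc <- data.frame(
        sample_id = "NTC",
        assay_id = rep(assay_ids, each = nn),
        platform_id = p$platform_id,
        signal_x = p$ntc_center[1] + stats::rnorm(nn * na, 0, p$ntc_sd),
        signal_y = p$ntc_center[2] + stats::rnorm(nn * na, 0, p$ntc_sd),
        is_ntc = TRUE, outcome = NA_character_, stringsAsFactors = FALSE)
      dat <- rbind(dat, ntc)
    }
    ## assay-major well layout: each assay fills a contiguous block
    dat <- dat[order(match(dat$assay_id, assay_ids), dat$is_ntc), ]
    dat$well_id <- .well_label(seq_len(nrow(dat)))
    points[[i]] <- dat
    truth[[paste0("outcome_", p$platform_id)]] <- outcome
  }
  points <- do.call(rbind, points)
  rownames(points) <- NULL
  points <- points[, c("well_id", "sample_id", "assay_id", "platform_id",
                       "signal_x", "signal_y", "is_ntc", "outcome")]
  out <- list(points = points[, 1:7], truth = truth, config = config)
  class(out) <- "plate_experiment"
  out
}

#' @export
print.plate_experiment <- function(x, ...) {
  cfg <- x$config
  cat("Simulated endpoint-fluorescence experiment\n")
  cat(sprintf("  %d samples + %d NTC wells x %d assays x %d platform(s)\n",
              cfg$n_samples, cfg$n_ntc, cfg$n_assays,
              length(cfg$platforms)))
  cat(sprintf("  %d fluorescence points (%d per platform), seed %d\n",
              nrow(x$points), nrow(x$points) / length(cfg$platforms),
              cfg$seed))
  invisible(x)
}

#' @export
print.platform_profile <- function(x, ...) {
  cat(sprintf("platform_profile '%s': gain %.3g, angles (%.3g, %.3g, %.3g) rad,\n",
              x$platform_id, x$gain, x$angle_a11, x$angle_a12, x$angle_a22))
  cat(sprintf("  noise_sd %.3g, fail %.3g, invalid %.3g, ntc (%.3g, %.3g) sd %.3g\n",
              x$noise_sd, x$fail_rate, x$invalid_rate,
              x$ntc_center[1], x$ntc_center[2], x$ntc_sd))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d samples + %d NTC x %d assays, %s genotypes, seed %d\n",
              x$n_samples, x$n_ntc, x$n_assays, x$het_model, x$seed))
  for (p in x$platforms) print(p)
  invisible(x)
}
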