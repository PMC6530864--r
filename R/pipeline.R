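## End-to-end platform comparison: metrics, ANOVA + LSD per metric,
## call rates and concordance, bundled in one classed result.

#' Compare genotyping platforms on a called experiment
#'
#' Runs the full statistical comparison on a plate table and its calls:
#' per-platform call rates; one-way CRD ANOVA with Fisher LSD letter
#' groups for allele call quality (per called point), cluster separation
#' angle and cluster compactness (per allele-1 homozygote cluster, the
#' conventional view) and NTC-to-cluster distance (per cluster, all
#' genotype labels); and the pairwise genotype concordance matrix.
#' Replication units follow the convention that call quality is observed
#' per successful amplification while the geometric metrics are observed
#' per assay cluster; both are overridable.
#'
#' @param points Plate fluorescence table.
#' @param calls Matching call table (default: [call_plate()] on
#'   \code{points}).
#' @param alpha Significance level for LSD letters (default 0.05).
#' @param unit Aggregation for the geometric metrics, \code{"per_cluster"}
#'   (default) or \code{"per_point"}.
#' @param a11_only Restrict angle and compactness to the A11 cluster
#'   (default \code{TRUE}).
#' @return An object of class \code{"platform_comparison"}: list with
#'   \code{call_rates}, \code{clusters} (cluster summary table),
#'   \code{anova} and \code{lsd} (named lists over metrics
#'   \code{quality}, \code{angle}, \code{compactness}, \code{distance}),
#'   \code{concordance}, \code{alpha}.  No multiplicity correction is
#'   applied across the four metrics; p-values are per-metric.
#' @examples
#' exp <- simulate_experiment(default_three_platform_config(seed = 1))
#' calls <- call_plate(exp$points)
#' cmp <- compare_platforms(exp$points, calls)
#' print(cmp)
#' @export
compare_platforms <- function(points, calls = call_plate(points),
                              alpha = 0.05,
                              unit = c("per_cluster", "per_point"),
                              a11_only = TRUE) {
  unit <- match.arg(unit)
  rates <- call_rate_summary(calls)
  all_cl <- summarize_clusters(points, calls, unit = unit,
                               a11_only = FALSE)
  a11_cl <- if (a11_only) all_cl[all_cl$label == "A11", , drop = FALSE]
            else all_cl
  called <- calls[calls$label %in% c("A11", "A12", "A22") &
                    is.finite(calls$quality), , drop = FALSE]
  anovas <- list(
    quality = anova_crd(called$quality, called$platform_id,
                        metric = "allele call quality"),
    angle = anova_crd(a11_cl$mean_angle, a11_cl$platform_id,
                      metric = "cluster separation angle (rad)"),
    compactness = anova_crd(a11_cl$compactness, a11_cl$platform_id,
                            metric = "cluster compactness"),
    distance = anova_crd(all_cl$mean_ntc_distance, all_cl$platform_id,
                         metric = "NTC to cluster distance"))
  lsds <- lapply(anovas, lsd_letters, alpha = alpha)
  structure(list(call_rates = rates, clusters = all_cl, anova = anovas,
                 lsd = lsds, concordance = concordance_matrix(calls),
                 alpha = alpha, unit = unit, a11_only = a11_only),
            class = "platform_comparison")
}

#' @export
print.platform_comparison <- function(x, ...) {
  cat("Genotyping platform comparison\n\n")
  cat("Call rates:\n")
  print(transform(x$call_rates,
                  failed_pct = round(failed_pct, 2),
                  amplified_pct = round(amplified_pct, 2)))
  cat("\n")
  for (nm in names(x$anova)) {
    print(x$anova[[nm]])
    print(x$lsd[[nm]])
    cat("\n")
  }
  print(x$concordance)
  cat("\n(No multiplicity correction is applied across metrics.)\n")
  invisible(x)
}

#' @export
summary.platform_comparison <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$anova), function(nm) {
    a <- object$anova[[nm]]
    l <- object$lsd[[nm]]
    data.frame(metric = nm, df_between = a$df_between,
               df_within = a$df_within, f = a$f, p = a$p,
               groups = paste(sprintf("%s=%.3g(%s)", names(l$means),
                                      l$means, l$letters),
                              collapse = " "),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab
}

#' Allele-discrimination scatter plot
#'
#' Base-graphics scatter of the two fluorescence channels, one panel per
#' platform, coloured by call label, with the NTC wells marked.  This is
#' the standard endpoint-genotyping cluster view (allele-1 homozygotes
#' near the X axis, heterozygotes along the diagonal, allele-2
#' homozygotes near the Y axis).
#'
#' @param x A \code{"platform_comparison"} object, or a plate table via
#'   \code{plot_discrimination()}.
#' @param points Plate table (required by the method; stored objects do
#'   not retain raw signals).
#' @param calls Call table used for colouring.
#' @param ... Passed to \code{plot()}.
#' @return Invisibly, \code{NULL}.
#' @export
plot_discrimination <- function(points, calls, ...) {
  labs <- c(A11 = "#1b9e77", A12 = "#7570b3", A22 = "#d95f02",
            INVALID = "grey55", FAILED = "grey30", NTC = "black")
  key <- c("sample_id", "assay_id", "platform_id")
  m <- merge(points, calls, by = key, sort = FALSE)
  platforms <- unique(m$platform_id)
  op <- graphics::par(mfrow = c(1, length(platforms)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in platforms) {
    blk <- m[m$platform_id == p, ]
    graphics::plot(blk$signal_x, blk$signal_y,
                   col = labs[blk$label], pch = 20,
                   xlab = "allele-1 signal", ylab = "allele-2 signal",
                   main = p, ...)
  }
  graphics::legend("topright", legend = names(labs), col = labs,
                   pch = 20, cex = 0.8, bty = "n")
  invisible(NULL)
}

#' @rdname plot_discrimination
#' @export
plot.platform_comparison <- function(x, points, calls, ...) {
  plot_discrimination(points, calls, ...)
}
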