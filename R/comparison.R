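## Platform comparison statistics: one-way CRD ANOVA, Fisher LSD letter
## groupings, and cross-platform genotype concordance.

#' One-way ANOVA under a completely randomized design
#'
#' Fixed-effects one-way decomposition of a metric over groups (each
#' successful observation is one replication).  The sums of squares are
#' computed directly from the group means:
#' \eqn{SS_B = \sum_g n_g (\bar y_g - \bar y)^2},
#' \eqn{SS_W = \sum_i (y_i - \bar y_{g(i)})^2}, with
#' \eqn{F = MS_B / MS_W} referred to the F distribution on
#' (groups - 1, N - groups) degrees of freedom.
#'
#' Degenerate cases: identical group means give \eqn{F = 0, p = 1}; zero
#' within-group variance with unequal means gives \eqn{F = +\infty,
#' p = 0}.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as \code{values}.
#' @param metric Optional metric name carried into printing.
#' @return An object of class \code{"crd_anova"}: a list with
#'   \code{df_between}, \code{ss_between}, \code{ms_between},
#'   \code{df_within}, \code{ss_within}, \code{ms_within}, \code{f},
#'   \code{p}, \code{grand_mean}, \code{group_means}, \code{group_sizes},
#'   \code{metric}.
#' @examples
#' a <- anova_crd(c(1, 2, 3, 4, 5, 6), rep(c("p1", "p2"), each = 3))
#' a$f   # 13.5
#' @export
anova_crd <- function(values, groups, metric = NULL) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  g <- unique(groups)
  if (length(g) < 2L)
    stop("ANOVA needs at least two groups", call. = FALSE)
  sizes <- vapply(g, function(gg) sum(groups == gg), 0L)
  if (any(sizes < 2L))
    stop(sprintf("group '%s' has fewer than 2 observations",
                 g[which(sizes < 2L)[1]]), call. = FALSE)
  means <- vapply(g, function(gg) mean(values[groups == gg]), 0)
  grand <- mean(values)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((values - means[match(groups, g)])^2)
  dfb <- length(g) - 1L
  dfw <- length(values) - length(g)
  msb <- ssb / dfb
  msw <- ssw / dfw
  if (ssb <= 0) { f <- 0; p <- 1 }
  else if (msw == 0) { f <- Inf; p <- 0 }
  else { f <- msb / msw; p <- stats::pf(f, dfb, dfw, lower.tail = FALSE) }
  structure(list(df_between = dfb, ss_between = ssb, ms_between = msb,
                 df_within = dfw, ss_within = ssw, ms_within = msw,
                 f = f, p = p, grand_mean = grand,
                 group_means = stats::setNames(means, g),
                 group_sizes = stats::setNames(as.integer(sizes), g),
                 metric = metric),
            class = "crd_anova")
}

#' @export
print.crd_anova <- function(x, ...) {
  if (!is.null(x$metric)) cat(sprintf("One-way CRD ANOVA: %s\n", x$metric))
  else cat("One-way CRD ANOVA\n")
  tab <- data.frame(
    Df = c(x$df_between, x$df_within),
    `Sum Sq` = c(x$ss_between, x$ss_within),
    `Mean Sq` = c(x$ms_between, x$ms_within),
    `F value` = c(x$f, NA),
    `Pr(>F)` = c(x$p, NA),
    row.names = c("platform", "residuals"), check.names = FALSE)
  print(format(tab, digits = 4, na.encode = FALSE))
  invisible(x)
}

## maximal cliques of a small undirected graph (adjacency matrix),
## by subset enumeration — fine for the handful of platforms compared
.maximal_cliques <- function(adj) {
  k <- nrow(adj)
  subsets <- lapply(seq_len(2^k) - 1L, function(m)
    which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0))
  is_clique <- vapply(subsets, function(s) {
    if (length(s) < 2L) return(length(s) == 1L)
    all(adj[s, s][upper.tri(matrix(0, length(s), length(s)))])
  }, TRUE)
  cl <- subsets[is_clique]
  keep <- vapply(seq_along(cl), function(i)
    !any(vapply(seq_along(cl), function(j)
      i != j && all(cl[[i]] %in% cl[[j]]), TRUE)), TRUE)
  cl[keep]
}

#' Fisher LSD mean separation with letter groups
#'
#' Pairwise least-significant-difference comparison of the group means of
#' a fitted [anova_crd()], with compact letter display.  The pairwise
#' threshold is
#' \eqn{LSD_{ij} = t_{1-\alpha/2, df_W}\sqrt{MS_W (1/n_i + 1/n_j)}},
#' which handles unequal group sizes.  Letters are assigned so that two
#' groups share a letter exactly when their mean difference does not
#' exceed their pairwise LSD (one letter per maximal clique of the
#' non-significance relation, ordered by descending mean, starting at
#' "a").
#'
#' @param anova A \code{"crd_anova"} object.
#' @param alpha Significance level (default 0.05).
#' @return An object of class \code{"lsd_grouping"}: list with
#'   \code{alpha}, \code{means} (descending), \code{letters} (named
#'   character, e.g. \code{"a"}, \code{"ab"}), \code{lsd_value} (the
#'   threshold at the mean group size), and \code{lsd_matrix} /
#'   \code{significant} pairwise matrices.
#' @export
lsd_letters <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "crd_anova"), alpha > 0, alpha < 1)
  if (anova$df_within < 1L) stop("no residual degrees of freedom",
                                 call. = FALSE)
  means <- sort(anova$group_means, decreasing = TRUE)
  n <- anova$group_sizes[names(means)]
  k <- length(means)
  tcrit <- stats::qt(1 - alpha / 2, anova$df_within)
  lsd <- outer(seq_len(k), seq_len(k), function(i, j)
    tcrit * sqrt(anova$ms_within * (1 / n[i] + 1 / n[j])))
  dimnames(lsd) <- list(names(means), names(means))
  diff <- abs(outer(means, means, `-`))
  sig <- diff > lsd
  diag(sig) <- FALSE
  cliques <- .maximal_cliques(!sig)
  ## order letters by the best (largest) mean they contain
  ord <- order(vapply(cliques, min, 0L))
  cliques <- cliques[ord]
  lett <- rep("", k)
  for (i in seq_along(cliques))
    lett[cliques[[i]]] <- paste0(lett[cliques[[i]]], letters[i])
  nbar <- mean(n)
  structure(list(alpha = alpha, means = means,
                 group_sizes = n,
                 letters = stats::setNames(lett, names(means)),
                 lsd_value = tcrit * sqrt(anova$ms_within * 2 / nbar),
                 lsd_matrix = lsd, significant = sig,
                 metric = anova$metric),
            class = "lsd_grouping")
}

#' @export
print.lsd_grouping <- function(x, ...) {
  if (!is.null(x$metric))
    cat(sprintf("LSD mean separation (alpha = %g): %s\n", x$alpha,
                x$metric))
  else cat(sprintf("LSD mean separation (alpha = %g)\n", x$alpha))
  print(data.frame(mean = x$means, n = x$group_sizes,
                   group = x$letters))
  cat(sprintf("LSD (mean group size): %.4g\n", x$lsd_value))
  invisible(x)
}

#' Genotype concordance between two platforms
#'
#' Fraction of sample x assay cells assigned the same genotype by two call
#' tables, among cells where both produced a genotype call (A11/A12/A22).
#' FAILED, INVALID and NTC rows enter neither numerator nor denominator.
#' Heterozygote-vs-homozygote disagreements count as discordant.
#'
#' @param calls_a,calls_b Call tables (typically one platform each).
#' @return List with \code{n_joint}, \code{n_agree}, \code{concordance}
#'   (in \[0,1\]; \code{NA} when no jointly-called cells exist).
#' @export
concordance <- function(calls_a, calls_b) {
  geno <- c("A11", "A12", "A22")
  a <- calls_a[calls_a$label %in% geno, c("sample_id", "assay_id", "label")]
  b <- calls_b[calls_b$label %in% geno, c("sample_id", "assay_id", "label")]
  m <- merge(a, b, by = c("sample_id", "assay_id"),
             suffixes = c("_a", "_b"))
  n_joint <- nrow(m)
  n_agree <- sum(m$label_a == m$label_b)
  list(n_joint = n_joint, n_agree = n_agree,
       concordance = if (n_joint > 0) n_agree / n_joint else NA_real_)
}

#' Pairwise concordance matrix across platforms
#'
#' Applies [concordance()] to every pair of platforms present in a call
#' table.
#'
#' @param calls A call table covering several platforms.
#' @return A symmetric matrix of concordances (diagonal 1 where a platform
#'   has any genotype call), with counts in attributes \code{n_joint} and
#'   \code{n_agree}.
#' @export
concordance_matrix <- function(calls) {
  platforms <- unique(calls$platform_id)
  k <- length(platforms)
  conc <- matrix(NA_real_, k, k, dimnames = list(platforms, platforms))
  nj <- na <- matrix(0L, k, k, dimnames = dimnames(conc))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i) next
    r <- concordance(calls[calls$platform_id == platforms[i], ],
                     calls[calls$platform_id == platforms[j], ])
    conc[i, j] <- conc[j, i] <- r$concordance
    nj[i, j] <- nj[j, i] <- r$n_joint
    na[i, j] <- na[j, i] <- r$n_agree
  }
  attr(conc, "n_joint") <- nj
  attr(conc, "n_agree") <- na
  class(conc) <- c("concordance_matrix", class(conc))
  conc
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat("Pairwise genotype concordance (jointly-called cells)\n")
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(round(100 * y, 2))
  invisible(x)
}
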