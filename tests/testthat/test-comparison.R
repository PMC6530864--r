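test_that("one-way CRD ANOVA matches the textbook closed form", {
  a <- anova_crd(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(a$ss_between, 13.5)
  expect_equal(a$ss_within, 4)
  expect_identical(a$df_between, 1L)
  expect_identical(a$df_within, 4L)
  expect_equal(a$f, 13.5)
  expect_equal(a$p, 0.02131, tolerance = 1e-3)  # F(1,4) upper tail
  expect_equal(a$ss_between + a$ss_within,
               sum((c(1:6) - mean(1:6))^2))
})

test_that("degenerate ANOVA cases follow the stated contracts", {
  # identical groups: no between-group signal
  a0 <- anova_crd(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_identical(a0$f, 0)
  expect_identical(a0$p, 1)
  # zero within-variance with unequal means
  a1 <- anova_crd(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_identical(a1$f, Inf)
  expect_identical(a1$p, 0)
  # a group with < 2 observations errors, naming the group
  expect_error(anova_crd(c(1, 2, 3), c("a", "a", "tiny")), "tiny")
  expect_error(anova_crd(1:4, rep("only", 4)), "two groups")
})

test_that("ANOVA agrees with the linear-model oracle on random data", {
  set.seed(57)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    n <- sample(3:12, k, replace = TRUE)
    g <- rep(sprintf("g%d", seq_len(k)), n)
    y <- rnorm(length(g), mean = rep(runif(k, -2, 2), n),
               sd = runif(1, 0.5, 2))
    a <- anova_crd(y, g)
    oracle <- anova(lm(y ~ factor(g)))
    expect_equal(a$f, oracle$`F value`[1], tolerance = 1e-8)
    expect_equal(a$p, oracle$`Pr(>F)`[1], tolerance = 1e-8)
    expect_equal(a$ss_between, oracle$`Sum Sq`[1], tolerance = 1e-10)
    expect_equal(a$ss_within, oracle$`Sum Sq`[2], tolerance = 1e-10)
  }
})

test_that("ANOVA is shift-invariant and scales quadratically", {
  set.seed(58)
  y <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  a <- anova_crd(y, g)
  sh <- anova_crd(y + 100, g)
  expect_equal(sh$ss_between, a$ss_between, tolerance = 1e-8)
  expect_equal(sh$ss_within, a$ss_within, tolerance = 1e-8)
  sc <- anova_crd(3 * y, g)
  expect_equal(sc$ss_between, 9 * a$ss_between)
  expect_equal(sc$ss_within, 9 * a$ss_within)
  expect_equal(sc$f, a$f)
})

test_that("LSD letters: equal means share a letter; separated means split", {
  g <- rep(c("p1", "p2", "p3"), each = 4)
  same <- anova_crd(rep(c(9.8, 10.2, 10.1, 9.9), 3), g)
  l_same <- lsd_letters(same)
  expect_true(all(l_same$letters == "a"))

  # means 20, 10.1, 10 with a small LSD: pattern a, b, b
  y <- c(20, 10.1, 10) [match(g, c("p1", "p2", "p3"))] +
    rep(c(-0.1, 0.1, -0.1, 0.1), 3)
  l <- lsd_letters(anova_crd(y, g))
  expect_identical(unname(l$letters[names(l$means) == "p1"]), "a")
  expect_identical(unname(l$letters[names(l$means) == "p2"]), "b")
  expect_identical(unname(l$letters[names(l$means) == "p3"]), "b")
  expect_gt(l$lsd_value, 0)
})

test_that("shared letters exactly mirror pairwise LSD non-significance", {
  set.seed(71)
  for (rep in 1:25) {
    k <- sample(3:6, 1)
    n <- sample(3:8, k, replace = TRUE)
    mu <- runif(k, 0, 3)
    g <- rep(sprintf("p%d", seq_len(k)), n)
    y <- rnorm(length(g), rep(mu, n), 0.7)
    a <- anova_crd(y, g)
    l <- lsd_letters(a, alpha = 0.05)
    tcrit <- qt(0.975, a$df_within)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      gi <- sprintf("p%d", i); gj <- sprintf("p%d", j)
      lsd_ij <- tcrit * sqrt(a$ms_within *
                               (1 / a$group_sizes[gi] +
                                  1 / a$group_sizes[gj]))
      nonsig <- abs(a$group_means[gi] - a$group_means[gj]) <= lsd_ij
      share <- length(intersect(
        strsplit(l$letters[gi], "")[[1]],
        strsplit(l$letters[gj], "")[[1]])) > 0
      expect_identical(share, unname(nonsig),
                       label = sprintf("rep %d pair %s-%s", rep, gi, gj))
    }
    expect_true(all(nchar(l$letters) >= 1))  # valid covering
  }
})

test_that("concordance counts only jointly-called genotype cells", {
  mk <- function(labels, platform = "p") data.frame(
    sample_id = sprintf("S%02d", seq_along(labels)), assay_id = "A1",
    platform_id = platform, label = labels,
    quality = ifelse(labels %in% c("A11", "A12", "A22"), 0.9, NA),
    stringsAsFactors = FALSE)

  a <- mk(c(rep("A11", 6), rep("A22", 4), "FAILED", "INVALID"))
  expect_equal(concordance(a, a)$concordance, 1.0)

  b <- mk(c(rep("A11", 5), "A12", rep("A22", 4), "A11", "FAILED"), "q")
  r <- concordance(a, b)
  expect_identical(r$n_joint, 10L)   # FAILED/INVALID cells excluded
  expect_identical(r$n_agree, 9L)
  expect_equal(r$concordance, 0.9)
  r_rev <- concordance(b, a)
  expect_identical(r_rev$concordance, r$concordance)

  disjoint <- mk(rep("A11", 3)); disjoint$assay_id <- "OTHER"
  r0 <- concordance(a, disjoint)
  expect_identical(r0$n_joint, 0L)
  expect_true(is.na(r0$concordance))
})

test_that("concordance matrix is symmetric with unit diagonal", {
  exp <- simulate_experiment(tiny_config(seed = 23))
  calls <- call_plate(exp$points)
  cm <- concordance_matrix(calls)
  m <- unclass(cm); attributes(m) <- attributes(m)[c("dim", "dimnames")]
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), c(1, 1))
  expect_identical(attr(cm, "n_joint"), t(attr(cm, "n_joint")))
})

test_that("cross-metric comparison object assembles all four ANOVAs", {
  exp <- simulate_experiment(tiny_config(seed = 29, n_assays = 5))
  calls <- call_plate(exp$points)
  cmp <- compare_platforms(exp$points, calls)
  expect_s3_class(cmp, "platform_comparison")
  expect_named(cmp$anova, c("quality", "angle", "compactness",
                            "distance"))
  tab <- summary(cmp)
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_output(print(cmp), "CRD ANOVA")
  expect_output(print(cmp$lsd$angle), "LSD")
})
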