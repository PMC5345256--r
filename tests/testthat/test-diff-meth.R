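test_that("per-CpG F statistics match stats::oneway.test row by row", {
  withr::local_seed(11)
  dat <- purrr::map_dfr(1:20, function(i) {
    meth_row(list(A = rnorm(3, 50, 5), B = rnorm(4, 52, 5), C = rnorm(3, 55, 5)),
             cpg = sprintf("cpg%02d", i))
  })
  res <- anova_bh(dat)
  for (id in unique(dat$cpg)) {
    d <- dat[dat$cpg == id, ]
    ot <- stats::oneway.test(percent ~ group, d, var.equal = TRUE)
    expect_equal(res$f[res$cpg == id], unname(ot$statistic), tolerance = 1e-10)
    expect_equal(res$p[res$cpg == id], unname(ot$p.value), tolerance = 1e-10)
  }
  expect_equal(res$q, stats::p.adjust(res$p, "BH"))
})

test_that("identical group profiles give F 0 and p 1", {
  d <- meth_row(list(A = c(1, 2, 3), B = c(1, 2, 3)))
  res <- anova_bh(d)
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
  expect_false(res$significant)
})

test_that("degenerate variance rows are flagged and handled", {
  flat <- meth_row(list(A = c(5, 5, 5), B = c(5, 5, 5)))
  res1 <- anova_bh(flat)
  expect_equal(res1$flag, "zero_variance")
  expect_equal(res1$p, 1)

  sep <- meth_row(list(A = c(0, 0, 0), B = c(100, 100, 100)))
  res2 <- anova_bh(sep)
  expect_equal(res2$flag, "variance_floored")
  expect_true(res2$significant)
})

test_that("input validation catches single groups and missing values", {
  expect_error(anova_bh(meth_row(list(A = c(1, 2, 3)))), "2 groups")
  single_rep <- tibble::tibble(cpg = "x", sample = c("a1", "b1"),
                               group = c("A", "B"), percent = c(1, 2))
  expect_error(anova_bh(single_rep), "replicates")
})

test_that("null p-values are approximately uniform", {
  withr::local_seed(17)
  n <- 10000
  mat <- matrix(rnorm(n * 9, 50, 5), n)
  dat <- tibble::tibble(
    cpg = rep(sprintf("c%05d", 1:n), 9),
    sample = rep(sprintf("%s_%d", rep(c("A", "B", "C"), each = 3), 1:3),
                 each = n),
    group = rep(rep(c("A", "B", "C"), each = 3), each = n),
    percent = as.vector(mat))
  res <- anova_bh(dat)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("Tukey HSD separates the distant group and matches ptukey", {
  d <- meth_row(list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(10, 11, 12)))
  tk <- tukey_hsd(d)
  sig <- tk[tk$significant, ]
  expect_setequal(paste(sig$group1, sig$group2),
                  c("C A", "C B"))
  # independent studentized-range computation
  fit <- stats::aov(percent ~ group, d)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  for (i in seq_len(nrow(tk))) {
    gm <- tapply(d$percent, d$group, mean)
    q <- abs(gm[tk$group1[i]] - gm[tk$group2[i]]) / sqrt(mse / 3)
    p_ref <- stats::ptukey(q, nmeans = 3, df = fit$df.residual,
                           lower.tail = FALSE)
    expect_equal(tk$p_adj[i], unname(p_ref), tolerance = 1e-8)
  }
})

test_that("identical groups yield an adjusted p of 1 and zero effects", {
  d <- meth_row(list(A = c(5, 5, 5), B = c(5, 5, 5), C = c(5, 5, 5)))
  tk <- tukey_hsd(d)
  expect_equal(tk$p_adj, rep(1, 3))
  expect_equal(tk$delta, rep(0, 3))
})

test_that("effect sizes delta and rho use group mean percents", {
  d <- meth_row(list(A = c(39, 40, 41), B = c(41, 42, 43)))
  tk <- tukey_hsd(d)
  expect_equal(tk$delta, 2)
  expect_equal(tk$rho, 42 / 40)
  expect_true(all(tk$rho >= 1))
})

test_that("the subtle filter applies both effect-size gates", {
  tk <- tibble::tibble(
    cpg = c("a", "b", "c"), group1 = "X", group2 = "Y",
    diff = c(4, 4, 8), p_adj = 0.01,
    delta = c(4, 4, 8), rho = c(1.08, 1.2, 1.05),
    significant = TRUE)
  kept <- subtle_filter(tk, max_delta = 5, max_ratio = 1.1)
  expect_equal(kept$cpg, "a")
  tk$significant[1] <- FALSE
  expect_equal(nrow(subtle_filter(tk)), 0L)
})

test_that("two-stage wrapper restricts Tukey to ANOVA-significant CpGs", {
  withr::local_seed(5)
  dat <- dplyr::bind_rows(
    meth_row(list(A = rnorm(3, 50, 0.5), B = rnorm(3, 50, 0.5),
                  C = rnorm(3, 50, 0.5)), "null_cpg"),
    meth_row(list(A = rnorm(3, 20, 0.5), B = rnorm(3, 50, 0.5),
                  C = rnorm(3, 80, 0.5)), "hot_cpg"))
  res <- diff_methylation(dat)
  expect_true("hot_cpg" %in% res$tukey$cpg)
  expect_false("null_cpg" %in% res$tukey$cpg)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_cpgs, 2L)
})

test_that("z-scores use the n-1 SD convention and drop constant rows", {
  d <- dplyr::bind_rows(
    meth_row(list(A = c(10), B = c(20), C = c(30)), "varies"),
    meth_row(list(A = c(7), B = c(7), C = c(7)), "flat"),
    meth_row(list(A = c(1), B = c(5), C = c(9)), "varies2"))
  expect_message(ord <- zscore_pca_cluster(d), "constant")
  expect_equal(unname(ord$z["varies", ]), c(-1, 0, 1))
  expect_equal(ord$dropped_cpgs, "flat")
})

test_that("identical samples join first in the UPGMA tree", {
  withr::local_seed(3)
  base <- rnorm(20, 50, 10)
  d <- tibble::tibble(
    cpg = rep(sprintf("c%02d", 1:20), 3),
    sample = rep(c("s1", "s2", "s3"), each = 20),
    group = rep(c("g", "g", "g"), each = 20),
    percent = c(base, base, base + rnorm(20, 0, 8)))
  ord <- zscore_pca_cluster(d)
  expect_equal(ord$hclust$height[1], 0)
  first_pair <- sort(ord$hclust$labels[-ord$hclust$merge[1, ]])
  expect_equal(first_pair, c("s1", "s2"))
  expect_s3_class(ape::read.tree(text = ord$newick), "phylo")
})

test_that("PCA separates two planted sample groups along a leading axis", {
  withr::local_seed(9)
  n <- 40
  grp <- rep(c("L", "H"), each = 3)
  mat <- sapply(seq_along(grp), function(j) {
    rnorm(n, mean = ifelse(grp[j] == "H", 60, 40), sd = 1)
  })
  d <- tibble::tibble(
    cpg = rep(sprintf("c%02d", 1:n), length(grp)),
    sample = rep(sprintf("%s_%d", grp, rep(1:3, 2)), each = n),
    group = rep(grp, each = n),
    percent = as.vector(mat))
  ord <- zscore_pca_cluster(d)
  pc1 <- ord$scores$PC1
  grp_means <- tapply(pc1, ord$scores$group, mean)
  gap <- abs(diff(grp_means))
  spread <- max(tapply(pc1, ord$scores$group, stats::sd))
  expect_gt(gap, 3 * spread)
})
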