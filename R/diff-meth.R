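as_meth_long <- function(data) {
  data <- as_tibble(data)
  stop_if_missing_cols(data, c("cpg", "sample", "group", "percent"),
                       "methylation data")
  data
}

meth_wide <- function(data) {
  if (anyDuplicated(data[, c("cpg", "sample")])) {
    abort(paste0("methylation data must carry one percent value per cpg and ",
                 "sample; aggregate or re-key duplicate rows first"))
  }
  wide <- data |>
    select("cpg", "sample", "percent") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "percent")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$cpg
  groups <- data |> distinct(.data$sample, .data$group)
  list(mat = mat, groups = setNames(groups$group, groups$sample)[colnames(mat)])
}

# Row-wise one-way fixed-effects ANOVA on a CpG x sample matrix.
# Vectorized sums of squares + stats::pf; agreement with
# stats::oneway.test(var.equal = TRUE) is asserted in the unit suite.
row_anova <- function(mat, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- ncol(mat)
  if (k < 2) abort("need at least 2 groups")
  if (any(table(groups) < 2)) abort("need >= 2 replicates per group")
  if (anyNA(mat)) abort("missing percent values are not supported")
  gsizes <- as.vector(table(groups)[levels(groups)])
  gmeans <- vapply(levels(groups), function(g) {
    rowMeans(mat[, groups == g, drop = FALSE])
  }, numeric(nrow(mat)))
  if (nrow(mat) == 1) gmeans <- matrix(gmeans, nrow = 1)
  grand <- rowMeans(mat)
  ssb <- as.vector((gmeans - grand)^2 %*% gsizes)
  ssw <- rowSums((mat - gmeans[, as.integer(groups), drop = FALSE])^2)
  zero_between <- ssb < 1e-24
  zero_within <- ssw < 1e-24
  # degenerate rows: identical everywhere -> p 1; separated but zero within-
  # group variance -> tiny variance floor so the row is testable
  ssw_f <- ifelse(zero_within & !zero_between, 1e-12, ssw)
  fstat <- (ssb / (k - 1)) / (ssw_f / (n - k))
  p <- pf(fstat, k - 1, n - k, lower.tail = FALSE)
  p[zero_between & zero_within] <- 1
  fstat[zero_between & zero_within] <- 0
  flag <- dplyr::case_when(
    zero_between & zero_within ~ "zero_variance",
    zero_within ~ "variance_floored",
    .default = "ok"
  )
  tibble(cpg = rownames(mat), f = unname(fstat), p = unname(p), flag = flag)
}

#' Per-CpG one-way ANOVA with Benjamini-Hochberg FDR control
#'
#' Classical fixed-effects one-way ANOVA of percent methylation across groups
#' (tissues), computed per CpG, with BH step-up adjustment applied jointly
#' across all CpGs in the batch (all selective subsets pooled into one
#' analysis, as one study is one multiple-testing family). A CpG is called
#' significant when its adjusted value `q` is at most `alpha`. Rows with no
#' variation anywhere are flagged `zero_variance` and given p = 1; rows with
#' separated group means but zero within-group variance are floored to stay
#' testable and flagged.
#'
#' @param data Long tibble with columns `cpg`, `sample`, `group`, `percent`.
#' @param alpha FDR threshold (default 0.05).
#' @return Tibble: `cpg`, `f`, `p`, `q`, `significant`, `flag`.
#' @export
anova_bh <- function(data, alpha = 0.05) {
  data <- as_meth_long(data)
  w <- meth_wide(data)
  if (nrow(w$mat) == 0) abort("empty methylation matrix")
  res <- row_anova(w$mat, w$groups)
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q <= alpha
  res
}

#' Tukey HSD post hoc tests and effect sizes
#'
#' Runs [stats::TukeyHSD()] on each requested CpG (by default the
#' ANOVA-significant ones, mirroring the two-stage analysis) and augments
#' each group pair with the two effect sizes used to define *subtle*
#' differential methylation: `delta`, the absolute difference of group mean
#' percents, and `rho`, the max/min ratio of group mean percents (so
#' `rho >= 1`), with a floor of `eps` percentage points on the denominator.
#'
#' @param data Long tibble (`cpg`, `sample`, `group`, `percent`).
#' @param cpgs CpGs to test; default all (pass `anova_bh()` significant CpGs
#'   for the two-stage analysis, or use [diff_methylation()]).
#' @param alpha Pairwise significance threshold on the Tukey-adjusted p.
#' @param eps Denominator floor (percent) for `rho`.
#' @return Tibble: `cpg`, `group1`, `group2`, `diff`, `p_adj`, `delta`,
#'   `rho`, `significant`.
#' @export
tukey_hsd <- function(data, cpgs = NULL, alpha = 0.05, eps = 0.1) {
  data <- as_meth_long(data)
  if (length(unique(data$group)) < 2) abort("need at least 2 groups")
  if (is.null(cpgs)) cpgs <- unique(data$cpg)
  data <- data |> filter(.data$cpg %in% .env$cpgs)
  if (nrow(data) == 0) {
    return(tibble(cpg = character(), group1 = character(),
                  group2 = character(), diff = double(), p_adj = double(),
                  delta = double(), rho = double(), significant = logical()))
  }
  purrr::map_dfr(split(data, data$cpg), function(d) {
    d$group <- factor(d$group)
    gm <- tapply(d$percent, d$group, mean)
    if (sd(d$percent) < 1e-12) {
      # all values identical: every pairwise contrast is null
      cmb <- utils::combn(levels(d$group), 2)
      tk <- tibble(group1 = cmb[2, ], group2 = cmb[1, ], diff = 0, p_adj = 1)
    } else {
      fit <- aov(percent ~ group, data = d)
      tt <- TukeyHSD(fit)$group
      nm <- strsplit(rownames(tt), "-", fixed = TRUE)
      tk <- tibble(group1 = vapply(nm, `[`, "", 1),
                   group2 = vapply(nm, `[`, "", 2),
                   diff = unname(tt[, "diff"]), p_adj = unname(tt[, "p adj"]))
    }
    tk |>
      mutate(
        cpg = d$cpg[1],
        delta = as.numeric(abs(gm[.data$group1] - gm[.data$group2])),
        rho = as.numeric(pmax(gm[.data$group1], gm[.data$group2]) /
          pmax(pmin(gm[.data$group1], gm[.data$group2]), eps)),
        significant = .data$p_adj <= alpha
      ) |>
      select("cpg", "group1", "group2", "diff", "p_adj", "delta", "rho",
             "significant")
  })
}

#' Filter for subtle but significant methylation differences
#'
#' Keeps Tukey-significant group pairs whose effects are *small*: absolute
#' mean difference below `max_delta` percentage points and mean ratio below
#' `max_ratio`-fold — the sensitivity showcase of the method (calling
#' differences of less than 5 percent and 1.1-fold).
#'
#' @param tukey A [tukey_hsd()] result.
#' @param max_delta Maximum absolute difference of group mean percents.
#' @param max_ratio Maximum max/min ratio of group mean percents.
#' @return The qualifying rows of `tukey`.
#' @export
subtle_filter <- function(tukey, max_delta = 5, max_ratio = 1.1) {
  stop_if_missing_cols(tukey, c("significant", "delta", "rho"), "Tukey table")
  tukey |>
    filter(.data$significant, .data$delta < .env$max_delta,
           .data$rho < .env$max_ratio)
}

#' Two-stage differential-methylation analysis
#'
#' Convenience wrapper running [anova_bh()], then [tukey_hsd()] on the
#' ANOVA-significant CpGs, then [subtle_filter()].
#'
#' @inheritParams anova_bh
#' @inheritParams subtle_filter
#' @param tukey_all Run Tukey on every CpG instead of only the
#'   ANOVA-significant ones.
#' @return List of class `diff_meth`: `anova`, `tukey`, `subtle` tibbles and
#'   the thresholds used.
#' @export
diff_methylation <- function(data, alpha = 0.05, max_delta = 5,
                             max_ratio = 1.1, tukey_all = FALSE) {
  data <- as_meth_long(data)
  an <- anova_bh(data, alpha)
  sig <- an$cpg[an$significant]
  tk <- tukey_hsd(data, cpgs = if (tukey_all) NULL else sig, alpha = alpha)
  structure(
    list(anova = an, tukey = tk,
         subtle = subtle_filter(tk, max_delta, max_ratio),
         alpha = alpha, max_delta = max_delta, max_ratio = max_ratio),
    class = "diff_meth"
  )
}

#' @export
print.diff_meth <- function(x, ...) {
  cat(sprintf(
    "Differential methylation (one-way ANOVA + BH + Tukey HSD)\n  CpGs tested: %d\n  significant at q <= %g: %d\n  significant group pairs: %d\n  subtle (delta < %g pp, ratio < %g-fold): %d\n",
    nrow(x$anova), x$alpha, sum(x$anova$significant),
    sum(x$tukey$significant), x$max_delta, x$max_ratio, nrow(x$subtle)))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy diff_meth
#' @export
tidy.diff_meth <- function(x, ...) x$tukey

#' @importFrom generics glance
#' @method glance diff_meth
#' @export
glance.diff_meth <- function(x, ...) {
  tibble(n_cpgs = nrow(x$anova), n_significant = sum(x$anova$significant),
         n_pairs_significant = sum(x$tukey$significant),
         n_subtle = nrow(x$subtle), alpha = x$alpha)
}

#' z-score normalization, PCA and UPGMA clustering of methylation patterns
#'
#' Normalizes each CpG row to a z-score (mean 0, unit SD across samples,
#' `n - 1` denominator; zero-variance rows are dropped and listed), runs a
#' sample-space PCA on the z-scores, and builds a UPGMA (average-linkage)
#' dendrogram over samples from Euclidean distances, exported as a newick
#' string.
#'
#' @param data Long tibble (`cpg`, `sample`, `group`, `percent`); at least 3
#'   samples.
#' @return List of class `meth_ordination`: `z` (CpG x sample matrix),
#'   `scores` (tibble of sample PC scores and group labels),
#'   `var_explained`, `hclust`, `phylo` ([ape::as.phylo()]), `newick`,
#'   `dropped_cpgs`.
#' @export
zscore_pca_cluster <- function(data) {
  data <- as_meth_long(data)
  w <- meth_wide(data)
  if (ncol(w$mat) < 3) abort("need at least 3 samples")
  rsd <- apply(w$mat, 1, sd)
  dropped <- rownames(w$mat)[rsd < 1e-12]
  keep <- rsd >= 1e-12
  if (!any(keep)) abort("all CpG rows are constant; nothing to ordinate")
  if (length(dropped) > 0) {
    inform(sprintf("dropped %d constant CpG row(s) before z-scoring",
                   length(dropped)))
  }
  z <- (w$mat[keep, , drop = FALSE] - rowMeans(w$mat[keep, , drop = FALSE])) /
    rsd[keep]
  pca <- prcomp(t(z), center = TRUE, scale. = FALSE)
  scores <- as_tibble(pca$x, rownames = "sample") |>
    mutate(group = unname(w$groups[.data$sample]), .after = "sample")
  hc <- hclust(dist(t(z)), method = "average")
  phylo <- ape::as.phylo(hc)
  structure(
    list(z = z, scores = scores,
         var_explained = pca$sdev^2 / sum(pca$sdev^2),
         hclust = hc, phylo = phylo,
         newick = ape::write.tree(phylo),
         dropped_cpgs = dropped),
    class = "meth_ordination"
  )
}

#' @export
print.meth_ordination <- function(x, ...) {
  cat(sprintf(
    "Methylation-pattern ordination\n  CpGs: %d (dropped %d constant)\n  samples: %d\n  PC1/PC2 variance explained: %.1f%% / %.1f%%\n  UPGMA newick: %s\n",
    nrow(x$z), length(x$dropped_cpgs), ncol(x$z),
    100 * x$var_explained[1], 100 * x$var_explained[2],
    substr(x$newick, 1, 60)))
  invisible(x)
}
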