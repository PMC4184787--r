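# The four-part activation-gene filter (presence, one-way ANOVA, pairwise
# fold, replicate CV), fold-change tables vs a reference condition,
# cross-condition correlation/slope, strict and relaxed three-set Venn
# counts, condition-specific gene lists, and the pairwise category-count
# test.

# Condition-labelled submatrix helpers -------------------------------------

condition_samples <- function(m, conditions) {
  keep <- m$popmap$condition %in% conditions
  list(values = m$values[, keep, drop = FALSE],
       condition = factor(m$popmap$condition[keep], levels = conditions))
}

# Row-wise one-way fixed-effects ANOVA, vectorized over genes the way
# array packages compute per-gene F statistics.
row_anova_p <- function(x, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  n <- ncol(x)
  if (k < 2) stop("ANOVA requires >= 2 conditions")
  grand <- rowMeans(x)
  ss_tot <- rowSums((x - grand)^2)
  ss_within <- 0
  for (lev in levels(group)) {
    cols <- group == lev
    gm <- rowMeans(x[, cols, drop = FALSE])
    ss_within <- ss_within + rowSums((x[, cols, drop = FALSE] - gm)^2)
  }
  ss_between <- ss_tot - ss_within
  df1 <- k - 1
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # no residual variation: identical replicates everywhere -> no evidence
  p[ss_within <= 0 & ss_between <= 0] <- 1
  p[ss_within <= 0 & ss_between > 0] <- 0
  list(f = f, p = p, df1 = df1, df2 = df2)
}

#' Multi-criterion activation-gene filter
#'
#' Retains genes that (1) have mean expression above the presence threshold
#' in at least one condition, (2) vary significantly across conditions by
#' one-way ANOVA on log2 replicate values, (3) show a fold difference of at
#' least `min_fold` in some pairwise comparison of condition means, and
#' (4) have within-condition coefficient of variation of the linear-scale
#' replicates below `max_cv` (in every condition by default).
#'
#' @param m An [expression_matrix()].
#' @param conditions Condition labels to compare (each needs >= 2
#'   replicates).
#' @param cfg An [analysis_config()].
#' @param cv_scope `"all"` (default) requires the CV criterion in every
#'   condition; `"any"` in at least one.
#' @param anova_mode `"p"` (default) thresholds the raw ANOVA p at
#'   `cfg$anova_p`; `"q"` thresholds the BH-adjusted p at `cfg$q_module`.
#' @return `data.frame` of class `FilteredGeneSet`: per-gene diagnostics
#'   (`max_mean`, `anova_p`, `anova_q`, `max_fold`, `max_cv`,
#'   `worst_cv`), the four flags, and the composite `pass`.
#' @export
variation_filter <- function(m, conditions, cfg = analysis_config(),
                             cv_scope = c("all", "any"),
                             anova_mode = c("p", "q")) {
  cv_scope <- match.arg(cv_scope)
  anova_mode <- match.arg(anova_mode)
  if (length(conditions) < 2) stop("need >= 2 conditions")
  sub <- condition_samples(m, conditions)
  tab <- table(sub$condition)
  if (any(tab < 2))
    stop("condition(s) with a single replicate: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  if (any(sub$values <= 0))
    stop("all replicate values must be > 0 for the log2 ANOVA")

  n_genes <- nrow(sub$values)
  cond_means <- matrix(vapply(conditions, function(cc)
    rowMeans(sub$values[, sub$condition == cc, drop = FALSE]),
    numeric(n_genes)), nrow = n_genes)
  cond_sds <- matrix(vapply(conditions, function(cc)
    apply(sub$values[, sub$condition == cc, drop = FALSE], 1, stats::sd),
    numeric(n_genes)), nrow = n_genes)
  cvs <- cond_sds / cond_means

  an <- row_anova_p(log2(sub$values), sub$condition)
  anova_q <- stats::p.adjust(an$p, method = "BH")

  pairs <- utils::combn(length(conditions), 2)
  max_fold <- rep(1, nrow(cond_means))
  for (j in seq_len(ncol(pairs))) {
    a <- cond_means[, pairs[1, j]]
    b <- cond_means[, pairs[2, j]]
    max_fold <- pmax(max_fold, pmax(a, b) / pmin(a, b))
  }

  worst_cv <- apply(cvs, 1, max)
  best_cv <- apply(cvs, 1, min)
  pass_presence <- apply(cond_means, 1, max) > cfg$presence_threshold
  pass_anova <- if (anova_mode == "p") an$p < cfg$anova_p
                else anova_q < cfg$q_module
  pass_fold <- max_fold >= cfg$min_fold
  pass_cv <- if (cv_scope == "all") worst_cv < cfg$max_cv
             else best_cv < cfg$max_cv

  out <- data.frame(
    gene_id = rownames(m$values),
    max_mean = apply(cond_means, 1, max),
    anova_p = an$p, anova_q = anova_q,
    max_fold = max_fold, max_cv = worst_cv,
    pass_presence = pass_presence, pass_anova = pass_anova,
    pass_fold = pass_fold, pass_cv = pass_cv,
    pass = pass_presence & pass_anova & pass_fold & pass_cv,
    row.names = NULL
  )
  class(out) <- c("FilteredGeneSet", class(out))
  out
}

#' Fold changes of condition means relative to a reference condition
#'
#' @param means Genes x populations (here: conditions) mean matrix.
#' @param conditions Activated condition columns (e.g. SF, TG, UA).
#' @param reference Reference column (e.g. BL).
#' @return Genes x conditions matrix of mean ratios (> 0).
#' @export
fold_vs_reference <- function(means, conditions, reference) {
  miss <- setdiff(c(conditions, reference), colnames(means))
  if (length(miss)) stop("unknown condition(s): ", paste(miss, collapse = ", "))
  ref <- means[, reference]
  if (any(ref <= 0)) stop("reference means must be > 0")
  means[, conditions, drop = FALSE] / ref
}

#' Correlation and slope between two conditions' fold-change vectors
#'
#' Pearson correlation of the log2 fold changes and the ordinary
#' least-squares slope (with 95% confidence interval) of `log2(fc_b)` on
#' `log2(fc_a)`.
#'
#' @param fc_a,fc_b Equal-length positive fold-change vectors, n >= 3.
#' @return List with `r`, `slope`, `slope_ci` (length-2 vector), `n`.
#' @export
condition_correlation <- function(fc_a, fc_b) {
  stopifnot(length(fc_a) == length(fc_b))
  if (length(fc_a) < 3) stop("need n >= 3")
  if (any(fc_a <= 0) || any(fc_b <= 0)) stop("fold changes must be > 0")
  la <- log2(fc_a); lb <- log2(fc_b)
  if (stats::sd(la) == 0 || stats::sd(lb) == 0)
    stop("zero variance in a fold-change vector")
  fit <- stats::lm(lb ~ la)
  ci <- stats::confint(fit, "la", level = 0.95)
  list(r = stats::cor(la, lb), slope = unname(stats::coef(fit)["la"]),
       slope_ci = c(ci[1], ci[2]), n = length(fc_a))
}

# region labels for a 3-set Venn, in fixed order
venn_region_names <- function(conds) {
  c(conds,
    paste(conds[1], conds[2], sep = "&"),
    paste(conds[1], conds[3], sep = "&"),
    paste(conds[2], conds[3], sep = "&"),
    paste(conds, collapse = "&"))
}

#' Three-condition Venn region counts at strict and relaxed fold cutoffs
#'
#' Strict mode assigns each gene to the region given by the set of
#' conditions where its fold passes the strict cutoff. Relaxed mode counts a
#' gene as shared between two conditions when one passes the strict cutoff
#' and the other the relaxed one; a triple-shared gene needs one strict and
#' the other two relaxed. In both modes a gene contributes only if it passes
#' the strict cutoff in at least one condition.
#'
#' @param fc Genes x 3-conditions fold-change matrix (vs the reference).
#' @param strict Strict fold cutoff (default 2; the comparison is `>`).
#' @param relaxed Relaxed cutoff used for shared regions (default 1.5).
#' @param direction `"up"` (fold above cutoff) or `"down"` (fold below the
#'   reciprocal cutoff).
#' @param mode `"strict"` or `"relaxed"`.
#' @return Named integer vector over the seven Venn regions.
#' @export
venn_counts <- function(fc, strict = 2, relaxed = 1.5,
                        direction = c("up", "down"),
                        mode = c("strict", "relaxed")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  if (ncol(fc) != 3) stop("exactly 3 conditions are required")
  conds <- colnames(fc)
  pass <- function(x, cut) if (direction == "up") x > cut else x < 1 / cut
  s <- pass(fc, strict)
  r <- pass(fc, relaxed)
  regions <- venn_region_names(conds)
  counts <- stats::setNames(integer(7), regions)
  for (i in seq_len(nrow(fc))) {
    si <- s[i, ]; ri <- r[i, ]
    if (!any(si)) next
    member <- if (mode == "strict") si else ri
    lab <- paste(conds[member], collapse = "&")
    counts[lab] <- counts[lab] + 1L
  }
  counts
}

#' Genes specific to one activated condition
#'
#' Genes whose mean in `condition` is at least `min_fold` times the mean in
#' every other activated condition and in the reference.
#'
#' @param means Genes x conditions mean matrix.
#' @param condition Target condition.
#' @param other_conditions The remaining activated conditions.
#' @param reference Reference condition (e.g. BL).
#' @param min_fold Fold multiple (default 2, comparison `>=`).
#' @return Character vector of gene identifiers.
#' @export
condition_specific_genes <- function(means, condition, other_conditions,
                                     reference, min_fold = 2) {
  if (condition %in% other_conditions)
    stop("`condition` must not appear in `other_conditions`")
  comp <- c(other_conditions, reference)
  target <- means[, condition]
  ok <- rep(TRUE, nrow(means))
  for (cc in comp) ok <- ok & target >= min_fold * means[, cc]
  rownames(means)[ok]
}

#' Pairwise comparison of category counts between two gene lists
#'
#' Two-sided test of whether the proportion `k1/n1` differs from `k2/n2`,
#' on the 2x2 table `[[k1, n1-k1], [k2, n2-k2]]`. Fisher's exact test by
#' default; the chi-square variant (no continuity correction) is offered
#' when all expected counts are at least 5.
#'
#' @param k1,n1,k2,n2 Category count and list size for each list.
#' @param method `"fisher"` (default), `"chisq"`, or `"auto"` (chi-square
#'   when all expected counts >= 5, otherwise Fisher).
#' @return List with `p`, `method`, and the 2x2 `table`.
#' @export
category_count_compare <- function(k1, n1, k2, n2,
                                   method = c("fisher", "chisq", "auto")) {
  method <- match.arg(method)
  if (k1 > n1 || k2 > n2) stop("k must not exceed n")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto")
    method <- if (all(expected >= 5)) "chisq" else "fisher"
  if (method == "chisq") {
    if (any(expected < 5))
      warning("expected count < 5; chi-square approximation is poor")
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
  } else {
    p <- stats::fisher.test(tab)$p.value
  }
  list(p = p, method = method, table = tab)
}
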