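#' Normalize experimental channels to the bait
#'
#' Divides every protein's abundance in each bait-expressing channel by the
#' bait protein's abundance in that channel, yielding dimensionless
#' bait-normalized abundances that cancel pull-down efficiency and loading
#' differences between channels.  Negative-control channels carry no bait
#' and are excluded.  Missing abundances propagate as missing.
#'
#' @param matrix An [abundance_matrix()] of raw abundances; the bait must
#'   have strictly positive abundance in every experimental channel.
#' @param layout A [plex_layout()].
#' @return A `normalized_matrix`: list with `values` (proteins x
#'   experimental channels, bait row identically 1), `bait_id`, `gene`.
#' @export
bait_normalize <- function(matrix, layout) {
  stopifnot(inherits(matrix, "abundance_matrix"), inherits(layout, "plex_layout"))
  expch <- experimental_channels(layout)
  .assert(length(expch) >= 2L, "apms_config_error",
          "layout has no experimental channels")
  .assert(all(expch %in% colnames(matrix$values)), "apms_layout_mismatch",
          "abundance matrix lacks experimental channel(s): %s",
          paste(setdiff(expch, colnames(matrix$values)), collapse = ", "))
  bait <- matrix$values[matrix$bait_id, expch]
  bad <- expch[is.na(bait) | bait <= 0]
  if (length(bad) > 0L) {
    .stop2("apms_normalization_error",
           "bait abundance missing or zero in channel(s): %s",
           paste(bad, collapse = ", "))
  }
  vals <- sweep(matrix$values[, expch, drop = FALSE], 2L, bait, "/")
  structure(list(values = vals, bait_id = matrix$bait_id, gene = matrix$gene),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d proteins x %d experimental channels (bait: %s)\n",
              nrow(x$values), ncol(x$values), x$bait_id))
  invisible(x)
}

#' Per-protein fold enrichment between bait variants
#'
#' Fold enrichment compares how strongly each prey engages the variant
#' bait relative to the wild-type bait:
#' the mean bait-normalized abundance over the variant channels divided by
#' the mean over the wild-type channels.  With equal replicate counts this
#' equals the ratio of summed abundances.  Missing values are excluded from
#' each mean; a protein with no usable value in a condition, or a wild-type
#' mean of zero, gets an undefined fold enrichment (`NA`, `defined =
#' FALSE`) and is retained with a warning rather than dropped.
#'
#' @param norm A normalized matrix from [bait_normalize()].
#' @param layout A [plex_layout()].
#' @return Data frame with one row per protein: `protein`,
#'   `fold_enrichment`, `n_variant`, `n_wt` (non-missing values used per
#'   condition), `defined`.
#' @export
fold_enrichment <- function(norm, layout) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(layout, "plex_layout"))
  wt <- channels_for_role(layout, "WT_BAIT")
  var <- channels_for_role(layout, "VARIANT_BAIT")
  .assert(length(wt) >= 1L && length(var) >= 1L, "apms_config_error",
          "layout needs WT_BAIT and VARIANT_BAIT channels")
  vw <- norm$values[, wt, drop = FALSE]
  vv <- norm$values[, var, drop = FALSE]
  n_wt <- rowSums(!is.na(vw))
  n_var <- rowSums(!is.na(vv))
  mean_wt <- rowMeans(vw, na.rm = TRUE)
  mean_var <- rowMeans(vv, na.rm = TRUE)
  defined <- n_wt >= 1L & n_var >= 1L & !is.na(mean_wt) & mean_wt > 0
  fe <- ifelse(defined, mean_var / mean_wt, NA_real_)
  if (any(!defined)) {
    warning(sprintf("fold enrichment undefined for %d protein(s): %s",
                    sum(!defined),
                    paste(utils::head(rownames(norm$values)[!defined], 5L),
                          collapse = ", ")),
            call. = FALSE)
  }
  data.frame(protein = rownames(norm$values),
             fold_enrichment = fe,
             n_variant = as.integer(n_var),
             n_wt = as.integer(n_wt),
             defined = defined,
             stringsAsFactors = FALSE)
}

# Shared two-sample t-test wrapper with an explicit zero-variance policy:
# statistics delegate to stats::t.test, which cannot handle constant data,
# so the degenerate case is resolved first (p = 1 for equal means, p = 0
# for unequal means).
.two_sample_t <- function(group_a, group_b, pooled) {
  .assert(is.numeric(group_a) && is.numeric(group_b), "apms_validation_error",
          "groups must be numeric vectors")
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2L || n2 < 2L) {
    .stop2("apms_insufficient_replicates",
           "each group needs at least 2 non-missing values (got %d and %d)",
           n1, n2)
  }
  method <- if (pooled) "homoscedastic" else "welch"
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    d <- mean(group_a) - mean(group_b)
    p <- if (d == 0) 1 else 0
    message(sprintf("zero variance in both groups with %s means: p = %g",
                    if (d == 0) "equal" else "unequal", p))
    return(structure(list(t_statistic = if (d == 0) 0 else sign(d) * Inf,
                          df = n1 + n2 - 2,
                          p_value = p, n = c(n1, n2), method = method),
                     class = "t_test_result"))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = pooled)
  structure(list(t_statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = fit$p.value,
                 n = c(n1, n2),
                 method = method),
            class = "t_test_result")
}

#' Two-sided pooled-variance (homoscedastic) t-test
#'
#' The significance test applied per protein to its bait-normalized
#' abundances, wild-type versus variant replicates, assuming equal group
#' variances (degrees of freedom `n1 + n2 - 2`).  With
#' `log_transform = TRUE` the test is applied to `log2` of the inputs,
#' appropriate when noise is multiplicative.  Zero pooled variance is
#' resolved deterministically rather than erroring: `p = 1` when the group
#' means are equal, `p = 0` when they differ (both reported via
#' `message()`), so pipelines never silently drop proteins.
#'
#' @param group_a,group_b Numeric vectors with at least 2 non-missing
#'   values each; strictly positive when `log_transform = TRUE`.
#' @param log_transform Test `log2`-transformed values (default `FALSE`).
#' @return A `t_test_result`: list with `t_statistic`, `df`, `p_value`,
#'   `n` (group sizes) and `method`.
#' @seealso [welch_t_test()]
#' @export
#' @examples
#' homoscedastic_t_test(c(2, 4, 6), c(1, 2, 3))
homoscedastic_t_test <- function(group_a, group_b, log_transform = FALSE) {
  if (isTRUE(log_transform)) {
    .assert(all(group_a > 0, na.rm = TRUE) && all(group_b > 0, na.rm = TRUE),
            "apms_validation_error",
            "log_transform requires strictly positive values")
    group_a <- log2(group_a)
    group_b <- log2(group_b)
  }
  .two_sample_t(group_a, group_b, pooled = TRUE)
}

#' Two-sided unequal-variance (Welch) t-test
#'
#' Welch's t-test with Satterthwaite degrees of freedom, used where the
#' equal-variance assumption is untenable (for example comparing per-image
#' retention proportions between genotypes).  Degenerate inputs follow the
#' same policy as [homoscedastic_t_test()].
#'
#' @inheritParams homoscedastic_t_test
#' @return A `t_test_result`.
#' @export
welch_t_test <- function(group_a, group_b) {
  .two_sample_t(group_a, group_b, pooled = FALSE)
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4g, df = %.4g, p = %.4g (n = %d, %d)\n",
              x$method, x$t_statistic, x$df, x$p_value, x$n[1L], x$n[2L]))
  invisible(x)
}
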