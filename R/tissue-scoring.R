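#' Blinded multi-rater cell count table
#'
#' Holds per-image cell counts from a blinded scoring exercise: several
#' independent participants each count, for every image, the total number
#' of cells and the number of cells positive for the phenotype (for
#' example intracellular procollagen retention), across genotypes.
#'
#' @param participant Character or factor: rater identifier per record.
#' @param image Character: image identifier per record.
#' @param genotype Character: genotype label per record (for example
#'   `"WT"`, `"HET"`, `"HOM"`).
#' @param positive Non-negative integer count of positive cells.
#' @param total Positive integer count of all cells; `positive <= total`.
#' @return A `rater_counts` data frame.
#' @seealso [retention_summary()], [retention_significance()],
#'   [read_rater_counts()]
#' @export
rater_counts <- function(participant, image, genotype, positive, total) {
  n <- length(participant)
  .assert(n >= 1L, "apms_validation_error", "rater counts must be non-empty")
  .assert(all(lengths(list(image, genotype, positive, total)) == n),
          "apms_validation_error", "all rater-count columns must have equal length")
  positive <- as.integer(positive)
  total <- as.integer(total)
  .assert(!anyNA(positive) && !anyNA(total) && all(positive >= 0L) &&
            all(total >= 1L), "apms_validation_error",
          "counts must be non-negative integers with total >= 1")
  bad <- which(positive > total)
  .assert(length(bad) == 0L, "apms_validation_error",
          "positive cells exceed total cells in record %s",
          paste(utils::head(bad, 3L), collapse = ", "))
  structure(
    data.frame(participant = as.character(participant),
               image = as.character(image),
               genotype = as.character(genotype),
               positive = positive, total = total,
               stringsAsFactors = FALSE),
    class = c("rater_counts", "data.frame")
  )
}

#' Read a rater-count table from a delimited file
#'
#' Expects columns `participant`, `image`, `genotype`, `positive`, `total`
#' (tab- or comma-separated, auto-detected).
#'
#' @param path Path to the counts file.
#' @return A [rater_counts()] table.
#' @export
read_rater_counts <- function(path) {
  .assert(file.exists(path), "apms_io_error", "counts file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                           stringsAsFactors = FALSE)
  need <- c("participant", "image", "genotype", "positive", "total")
  .assert(all(need %in% names(tab)), "apms_validation_error",
          "counts file must have columns: %s", paste(need, collapse = ", "))
  rater_counts(tab$participant, tab$image, tab$genotype, tab$positive, tab$total)
}

#' Retention proportions by genotype with between-participant SEM
#'
#' For each (participant, genotype) the pooled proportion of positive
#' cells is the summed positives over the summed totals of that
#' participant's images.  The genotype point estimate is the mean of the
#' participant proportions and the error bar is the standard error of the
#' mean across participants (sample SD / sqrt(number of participants)).
#' Pooled counts are used for the point estimate (each cell weighs
#' equally); significance testing instead uses per-image proportions as
#' the replication unit -- see [retention_significance()].
#'
#' @param counts A [rater_counts()] table in which every participant has
#'   at least one image for every genotype present.
#' @return A `retention_summary`: list with `participant` (data frame
#'   `genotype`, `participant`, `positive`, `total`, `proportion`) and
#'   `genotype` (data frame `genotype`, `mean_proportion`, `sem`,
#'   `n_participants`).
#' @export
retention_summary <- function(counts) {
  stopifnot(inherits(counts, "rater_counts"))
  .check_coverage(counts)
  agg <- stats::aggregate(cbind(positive, total) ~ genotype + participant,
                          data = counts, FUN = sum)
  agg$proportion <- agg$positive / agg$total
  agg <- agg[order(agg$genotype, agg$participant), , drop = FALSE]
  rownames(agg) <- NULL
  by_geno <- stats::aggregate(proportion ~ genotype, data = agg,
                              FUN = function(p) {
                                c(mean = mean(p),
                                  sem = if (length(p) > 1L)
                                    stats::sd(p) / sqrt(length(p)) else 0,
                                  n = length(p))
                              })
  geno <- data.frame(genotype = by_geno$genotype,
                     mean_proportion = by_geno$proportion[, "mean"],
                     sem = by_geno$proportion[, "sem"],
                     n_participants = as.integer(by_geno$proportion[, "n"]),
                     stringsAsFactors = FALSE)
  structure(list(participant = agg, genotype = geno),
            class = "retention_summary")
}

#' @export
print.retention_summary <- function(x, ...) {
  cat("retention summary (mean of per-participant pooled proportions +/- SEM):\n")
  print(x$genotype, row.names = FALSE)
  invisible(x)
}

# every participant observed in the table must cover every genotype
.check_coverage <- function(counts) {
  tab <- table(counts$participant, counts$genotype)
  miss <- which(tab == 0L, arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    .stop2("apms_coverage_error",
           "participant '%s' has no images for genotype '%s'",
           rownames(tab)[miss[1L, 1L]], colnames(tab)[miss[1L, 2L]])
  }
  invisible(TRUE)
}

#' Max-p significance rule for blinded retention scoring
#'
#' For each participant, compares the per-image positive-cell proportions
#' of two genotypes with a Welch (heteroscedastic) t-test, and reports the
#' largest of the participant p-values.  Taking the maximum across
#' independent raters is conservative by construction: the reported p is
#' at least as large as every individual one, so a significant reported p
#' means every blinded rater independently saw a significant difference.
#'
#' @param counts A [rater_counts()] table.
#' @param genotype_a,genotype_b Genotype labels to compare.
#' @return List with `participant` (data frame `participant`,
#'   `t_statistic`, `df`, `p_value`), and `p_reported` (the maximum
#'   p-value).
#' @export
retention_significance <- function(counts, genotype_a, genotype_b) {
  stopifnot(inherits(counts, "rater_counts"))
  .assert(all(c(genotype_a, genotype_b) %in% counts$genotype),
          "apms_validation_error", "both genotypes must be present in counts")
  participants <- sort(unique(counts$participant))
  res <- lapply(participants, function(pp) {
    sub <- counts[counts$participant == pp, , drop = FALSE]
    pa <- sub[sub$genotype == genotype_a, , drop = FALSE]
    pb <- sub[sub$genotype == genotype_b, , drop = FALSE]
    if (nrow(pa) < 2L || nrow(pb) < 2L) {
      .stop2("apms_insufficient_data",
             "participant '%s' has fewer than 2 images for a genotype", pp)
    }
    fit <- welch_t_test(pa$positive / pa$total, pb$positive / pb$total)
    data.frame(participant = pp, t_statistic = fit$t_statistic, df = fit$df,
               p_value = fit$p_value, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, res)
  list(participant = per, p_reported = max(per$p_value))
}

#' Two-group comparison of tissue-level measurements
#'
#' Compares two sets of scalar measurements (for example TUNEL pixel
#' intensity per area across sections, or organoid diameters) with a
#' two-sided t-test.  `variance_mode = "welch"` (default) makes no
#' equal-variance assumption; `"pooled"` is the homoscedastic test.
#'
#' @param a,b Numeric measurement vectors with at least 2 values each.
#' @param variance_mode `"welch"` (default) or `"pooled"`.
#' @return A `t_test_result` (see [homoscedastic_t_test()]).
#' @export
compare_measurements <- function(a, b, variance_mode = c("welch", "pooled")) {
  variance_mode <- match.arg(variance_mode)
  if (variance_mode == "pooled") homoscedastic_t_test(a, b) else welch_t_test(a, b)
}

#' Read a two-column measurement table
#'
#' Expects columns `group` and `value` (tab- or comma-separated).
#'
#' @param path Path to the measurements file.
#' @return Data frame with character `group` and numeric `value`.
#' @export
read_measurements <- function(path) {
  .assert(file.exists(path), "apms_io_error", "measurements file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                           stringsAsFactors = FALSE)
  .assert(all(c("group", "value") %in% names(tab)), "apms_validation_error",
          "measurements file must have columns group and value")
  .assert(is.numeric(tab$value) && all(is.finite(tab$value)),
          "apms_validation_error", "measurement values must be finite numbers")
  data.frame(group = as.character(tab$group), value = tab$value,
             stringsAsFactors = FALSE)
}
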