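#' High-confidence interactor filter rule
#'
#' Parameters of the negative-control filter that separates genuine bait
#' interactors from nonspecific background.  The default rule retains a
#' protein whose raw abundance exceeds `ratio_threshold` times its averaged
#' negative-control baseline (strictly, by default) in at least
#' `min_passing_channels` of the `total_experimental_channels`
#' bait-expressing channels -- the "> 2-fold over control in at least 4 of
#' the 6 experimental samples" rule.  `mode = "all_replicates"` instead
#' requires the criterion in every experimental channel, the stricter
#' reading in which at least 2-fold enrichment must hold across all
#' replicates.
#'
#' @param ratio_threshold Positive fold-over-baseline threshold (default 2).
#' @param min_passing_channels Minimum number of experimental channels that
#'   must pass in `"k_of_n"` mode (default 4).
#' @param total_experimental_channels Expected number of experimental
#'   (bait-expressing) channels (default 6 = 3 wild-type + 3 variant); a
#'   mismatch with the layout is a configuration error.
#' @param strict_inequality Use `>` (default) rather than `>=` when
#'   comparing abundance against `ratio_threshold * baseline`.
#' @param mode `"k_of_n"` (default) or `"all_replicates"`.
#' @return A `filter_rule` object.
#' @seealso [high_confidence_filter()]
#' @export
filter_rule <- function(ratio_threshold = 2,
                        min_passing_channels = 4L,
                        total_experimental_channels = 6L,
                        strict_inequality = TRUE,
                        mode = c("k_of_n", "all_replicates")) {
  mode <- match.arg(mode)
  .assert(is.numeric(ratio_threshold) && ratio_threshold > 0,
          "apms_validation_error", "ratio_threshold must be > 0")
  min_passing_channels <- as.integer(min_passing_channels)
  total_experimental_channels <- as.integer(total_experimental_channels)
  .assert(min_passing_channels >= 1L, "apms_validation_error",
          "min_passing_channels must be a positive integer")
  .assert(min_passing_channels <= total_experimental_channels,
          "apms_validation_error",
          "min_passing_channels cannot exceed total_experimental_channels")
  structure(list(ratio_threshold = ratio_threshold,
                 min_passing_channels = min_passing_channels,
                 total_experimental_channels = total_experimental_channels,
                 strict_inequality = isTRUE(strict_inequality),
                 mode = mode),
            class = "filter_rule")
}

#' Per-protein negative-control baseline
#'
#' The nonspecific-binding baseline of each protein is the arithmetic mean
#' of its raw abundances over the no-transfection negative-control
#' channels, with missing values treated as 0 (a protein undetected in a
#' control channel contributes no signal there).
#'
#' @param matrix An [abundance_matrix()] of raw abundances.
#' @param layout A [plex_layout()] with at least one `NEGATIVE_CONTROL`
#'   channel.
#' @return Named numeric vector: baseline abundance per protein.
#' @export
negative_control_baseline <- function(matrix, layout) {
  stopifnot(inherits(matrix, "abundance_matrix"), inherits(layout, "plex_layout"))
  ctrl <- control_channels(layout)
  .assert(length(ctrl) >= 1L, "apms_config_error",
          "layout has no NEGATIVE_CONTROL channels")
  .assert(all(ctrl %in% colnames(matrix$values)), "apms_layout_mismatch",
          "abundance matrix lacks negative-control channel(s): %s",
          paste(setdiff(ctrl, colnames(matrix$values)), collapse = ", "))
  v <- matrix$values[, ctrl, drop = FALSE]
  v[is.na(v)] <- 0
  rowMeans(v)
}

#' Identify high-confidence interactors against the negative control
#'
#' Compares each protein's raw abundance in the bait-expressing
#' (experimental) channels against `ratio_threshold` times its averaged
#' negative-control baseline, and retains proteins passing in enough
#' channels per the [filter_rule()].  Two deliberate edge policies: a zero
#' baseline (protein absent from every control channel) counts as passed in
#' any channel with positive abundance, since absence in the control is the
#' strongest enrichment evidence; a missing experimental abundance counts
#' as a failed channel.  Filtering operates on raw abundances, before bait
#' normalization, because the negative-control channels contain no bait.
#'
#' The bait protein itself is always reported, flagged by `is_bait`.
#'
#' @param matrix An [abundance_matrix()] of raw abundances.
#' @param layout A [plex_layout()].
#' @param rule A [filter_rule()]; its `total_experimental_channels` must
#'   equal the layout's actual experimental channel count.
#' @return Data frame with one row per protein: `protein`, `pass_count`
#'   (number of experimental channels passing), `n_channels`, `retained`,
#'   `is_bait`.  Row order follows the input matrix.
#' @export
high_confidence_filter <- function(matrix, layout, rule = filter_rule()) {
  stopifnot(inherits(rule, "filter_rule"))
  expch <- experimental_channels(layout)
  .assert(length(expch) == rule$total_experimental_channels,
          "apms_config_error",
          "rule expects %d experimental channels but layout has %d",
          rule$total_experimental_channels, length(expch))
  .assert(all(expch %in% colnames(matrix$values)), "apms_layout_mismatch",
          "abundance matrix lacks experimental channel(s): %s",
          paste(setdiff(expch, colnames(matrix$values)), collapse = ", "))
  baseline <- negative_control_baseline(matrix, layout)
  x <- matrix$values[, expch, drop = FALSE]
  thr <- rule$ratio_threshold * baseline
  pass <- if (rule$strict_inequality) x > thr else x >= thr
  # zero baseline: any positive signal passes regardless of the inequality
  zb <- baseline == 0
  pass[zb, ] <- !is.na(x[zb, , drop = FALSE]) & x[zb, , drop = FALSE] > 0
  pass[is.na(pass)] <- FALSE   # missing experimental value fails that channel
  counts <- rowSums(pass)
  need <- if (rule$mode == "all_replicates") length(expch) else rule$min_passing_channels
  data.frame(protein = rownames(matrix$values),
             pass_count = as.integer(counts),
             n_channels = length(expch),
             retained = counts >= need,
             is_bait = rownames(matrix$values) == matrix$bait_id,
             stringsAsFactors = FALSE)
}
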