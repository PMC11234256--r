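#' Pipeline configuration
#'
#' Bundles the tunable parameters of the comparative interactome pipeline.
#'
#' @param rule A [filter_rule()] for the negative-control filter.
#' @param log_transform Run the per-protein homoscedastic t-test on
#'   log2-transformed bait-normalized abundances (default `FALSE`: the
#'   test is applied on the normalized scale directly; the simulation
#'   harness uses `TRUE`, where multiplicative noise makes the log-scale
#'   test exactly calibrated).
#' @param q_target Desired FDR level for the two-stage step-up procedure
#'   (default 0.10).
#' @param family FDR family: `"filtered"` (default) adjusts over the
#'   high-confidence proteins only, the family the published table
#'   reports; `"all"` adjusts over every detected non-bait protein.
#' @param q_grid Grid step for search-based q-values (default `1e-4`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rule = filter_rule(), log_transform = FALSE,
                            q_target = 0.10, family = c("filtered", "all"),
                            q_grid = 1e-4) {
  family <- match.arg(family)
  stopifnot(inherits(rule, "filter_rule"))
  .assert(q_target > 0 && q_target < 1, "apms_validation_error",
          "q_target must lie in (0, 1)")
  structure(list(rule = rule, log_transform = isTRUE(log_transform),
                 q_target = q_target, family = family, q_grid = q_grid),
            class = "pipeline_config")
}

#' Run the comparative interactome discovery pipeline
#'
#' Composes the analysis stages end to end: [high_confidence_filter()]
#' against the negative control, [bait_normalize()],
#' [fold_enrichment()] (variant over wild-type), a per-protein
#' [homoscedastic_t_test()] of variant versus wild-type bait-normalized
#' abundances, and [bky_two_stage()] FDR adjustment at
#' `config$q_target`.  The bait row is excluded from the result (its fold
#' enrichment is identically 1 by construction).  Proteins whose t-test is
#' not computable (fewer than 2 usable values in a group, or non-positive
#' values under `log_transform`) get `NA` p- and q-values and are excluded
#' from the FDR family.
#'
#' @param matrix An [abundance_matrix()] of raw abundances.
#' @param layout A [plex_layout()] with at least 2 channels in each of the
#'   wild-type, variant and negative-control roles.
#' @param config A [pipeline_config()].
#' @return An `enrichment_table`: data frame sorted by fold enrichment
#'   descending (ties by p-value ascending, then protein id) with columns
#'   `protein`, `gene`, `fold_enrichment`, `p_value`, `q_value`,
#'   `significant`, `high_confidence`, `pass_count`.  Attribute
#'   `"fdr"` holds the full `fdr_result`; attribute `"params"` echoes the
#'   configuration and per-stage counts.
#' @export
run_pipeline <- function(matrix, layout, config = pipeline_config()) {
  stopifnot(inherits(matrix, "abundance_matrix"),
            inherits(layout, "plex_layout"),
            inherits(config, "pipeline_config"))
  .check_runnable(layout)
  filt <- high_confidence_filter(matrix, layout, config$rule)
  keep <- if (config$family == "filtered") filt$retained & !filt$is_bait
          else !filt$is_bait
  proteins <- filt$protein[keep]
  counts <- list(n_input = nrow(filt), n_high_confidence = sum(filt$retained),
                 n_tested = length(proteins))
  if (length(proteins) == 0L) {
    out <- data.frame(protein = character(), gene = character(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      high_confidence = logical(), pass_count = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "params") <- c(unclass(config), counts)
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  norm <- bait_normalize(matrix, layout)
  fe <- fold_enrichment(norm, layout)
  fe <- fe[match(proteins, fe$protein), , drop = FALSE]
  wt <- channels_for_role(layout, "WT_BAIT")
  var <- channels_for_role(layout, "VARIANT_BAIT")
  pvals <- vapply(proteins, function(pr) {
    a <- norm$values[pr, var]
    b <- norm$values[pr, wt]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    if (config$log_transform && (any(a <= 0) || any(b <= 0))) return(NA_real_)
    homoscedastic_t_test(a, b, log_transform = config$log_transform)$p_value
  }, numeric(1L))
  testable <- !is.na(pvals)
  qvals <- rep(NA_real_, length(proteins))
  rejected <- rep(FALSE, length(proteins))
  fdr <- NULL
  if (any(testable)) {
    fdr <- bky_two_stage(pvals[testable], q_target = config$q_target,
                         q_grid = config$q_grid)
    qvals[testable] <- fdr$q_values
    rejected[testable] <- fdr$rejected
  }
  gene <- if (!is.null(matrix$gene)) unname(matrix$gene[proteins])
          else rep(NA_character_, length(proteins))
  out <- data.frame(protein = proteins,
                    gene = gene,
                    fold_enrichment = fe$fold_enrichment,
                    p_value = unname(pvals),
                    q_value = qvals,
                    significant = rejected,
                    high_confidence = filt$retained[keep],
                    pass_count = filt$pass_count[keep],
                    stringsAsFactors = FALSE)
  ord <- order(-out$fold_enrichment, out$p_value, out$protein,
               na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fdr") <- fdr
  attr(out, "params") <- c(unclass(config), counts)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("enrichment_table: %d proteins (of %d input, %d high-confidence)\n",
              nrow(x), p$n_input %||% NA, p$n_high_confidence %||% NA))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an enrichment table
#'
#' Serializes an enrichment table as tab-separated text mirroring the
#' published interactor-table layout (protein, gene symbol, fold
#' enrichment, p-value, q-value, confidence flag), with numbers written to
#' 8 significant digits.  `read_enrichment_table()` is the inverse.
#'
#' @param table An `enrichment_table` from [run_pipeline()], or any data
#'   frame with compatible columns.
#' @param path File path.
#' @return `write_enrichment_table()` returns `path` invisibly;
#'   `read_enrichment_table()` returns an `enrichment_table` data frame.
#' @export
write_enrichment_table <- function(table, path) {
  .assert(is.data.frame(table), "apms_validation_error",
          "table must be a data frame")
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1L))
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(out[[j]]), NA, sprintf("%.8g", out[[j]]))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  .assert(ok, "apms_io_error", "cannot write enrichment table to %s", path)
  invisible(path)
}

#' @rdname write_enrichment_table
#' @export
read_enrichment_table <- function(path) {
  .assert(file.exists(path), "apms_io_error", "file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "\"",
                           na.strings = "NA", comment.char = "")
  for (col in c("significant", "high_confidence")) {
    if (col %in% names(tab)) tab[[col]] <- as.logical(tab[[col]])
  }
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Star-annotate a differential expression panel
#'
#' Maps adjusted p-values of selected genes to the conventional
#' significance stars used in heatmap panels: `"*"` for adjusted p < 0.05,
#' `"**"` for < 0.01, `"***"` for < 0.001 (strict inequalities), empty
#' otherwise.  One entry is produced per (gene set, gene) pair; genes
#' absent from the table are flagged `missing` with `NA` statistics.
#'
#' @param de_table Data frame with columns `gene`, `log2_fc`, `p_adj`
#'   (adjusted p-values in `[0, 1]`).
#' @param gene_sets Named list of character vectors of gene symbols.
#' @return Data frame with columns `gene_set`, `gene`, `log2_fc`, `p_adj`,
#'   `stars`, `missing`.
#' @export
annotate_panel <- function(de_table, gene_sets) {
  .assert(is.data.frame(de_table) &&
            all(c("gene", "log2_fc", "p_adj") %in% names(de_table)),
          "apms_validation_error",
          "de_table must have columns gene, log2_fc and p_adj")
  .assert(all(is.na(de_table$p_adj) |
                (de_table$p_adj >= 0 & de_table$p_adj <= 1)),
          "apms_validation_error", "adjusted p-values must lie in [0, 1]")
  .assert(is.list(gene_sets) && !is.null(names(gene_sets)),
          "apms_validation_error", "gene_sets must be a named list")
  rows <- lapply(names(gene_sets), function(set) {
    genes <- gene_sets[[set]]
    if (length(genes) == 0L) return(NULL)
    idx <- match(genes, de_table$gene)
    data.frame(gene_set = set, gene = genes,
               log2_fc = de_table$log2_fc[idx],
               p_adj = de_table$p_adj[idx],
               stars = vapply(de_table$p_adj[idx], .stars, character(1L)),
               missing = is.na(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_set = character(), gene = character(),
                      log2_fc = numeric(), p_adj = numeric(),
                      stars = character(), missing = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

.stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
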