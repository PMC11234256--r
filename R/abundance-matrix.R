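#' Construct a protein-by-channel abundance matrix
#'
#' Holds raw (unnormalized) reporter-ion protein abundances for one
#' multiplexed AP-MS run, with the bait protein designated by identifier.
#' Abundances must be non-negative; undetected cells are kept as `NA` --
#' each downstream stage declares its own missing-value policy (the
#' negative-control baseline treats missing as 0, the high-confidence
#' filter counts a missing experimental value as a failed channel, bait
#' normalization propagates missingness).
#'
#' @param values Numeric matrix, proteins as rows (rownames = protein
#'   accessions), channels as columns (colnames = channel identifiers).
#'   Values must be `>= 0` or `NA`.
#' @param bait_id Protein identifier of the bait; must be a rowname of
#'   `values`.
#' @param gene Optional character vector of gene symbols, named by protein
#'   accession (or unnamed, parallel to the rows of `values`).
#'
#' @return An `abundance_matrix` object (list with elements `values`,
#'   `bait_id`, `gene`).
#' @seealso [read_abundance_table()]
#' @export
abundance_matrix <- function(values, bait_id, gene = NULL) {
  .assert(is.matrix(values) && is.numeric(values), "apms_validation_error",
          "values must be a numeric matrix")
  .assert(!is.null(rownames(values)) && !is.null(colnames(values)),
          "apms_validation_error",
          "values must have protein rownames and channel colnames")
  .assert(!anyDuplicated(rownames(values)), "apms_validation_error",
          "duplicate protein identifiers in abundance matrix")
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    .stop2("apms_validation_error",
           "negative abundance at protein '%s', channel '%s'",
           rownames(values)[neg[1L, 1L]], colnames(values)[neg[1L, 2L]])
  }
  .assert(is.character(bait_id) && length(bait_id) == 1L,
          "apms_validation_error", "bait_id must be a single string")
  .assert(bait_id %in% rownames(values), "apms_bait_not_found",
          "bait protein '%s' not found among protein identifiers", bait_id)
  if (!is.null(gene)) {
    gene <- as.character(gene)
    if (is.null(names(gene))) {
      .assert(length(gene) == nrow(values), "apms_validation_error",
              "unnamed gene vector must match the number of proteins")
      names(gene) <- rownames(values)
    }
  }
  structure(list(values = values, bait_id = bait_id, gene = gene),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d channels (bait: %s, %d missing)\n",
              nrow(x$values), ncol(x$values), x$bait_id, sum(is.na(x$values))))
  invisible(x)
}

#' Number of proteins / channels of an abundance matrix
#'
#' @param x An [abundance_matrix()].
#' @return `dim()` of the underlying matrix.
#' @export
dim.abundance_matrix <- function(x) dim(x$values)

# Detect the field separator of a delimited text file from its header line:
# tab wins if present, otherwise comma.
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a protein-by-channel abundance table
#'
#' Reads a delimited text export (tab- or comma-separated, auto-detected
#' from the header line) with one row per protein and one column per
#' reporter channel, validates it against a plex layout, and returns an
#' [abundance_matrix()].  Empty fields and the sentinel `"NA"` are recorded
#' as missing.  Channels marked `UNUSED` in the layout are dropped on load.
#'
#' @param path Path to the delimited abundance table.
#' @param layout A [plex_layout()]; every active channel must be a column
#'   of the table.
#' @param bait_id Protein identifier of the bait.
#' @param id_column Header name of the protein-identifier column
#'   (default `"Accession"`).
#' @param gene_column Optional header name of a gene-symbol column; used
#'   when present, ignored otherwise.
#' @param contaminants Optional character vector of accessions to exclude
#'   at load (a contaminant list), or the path of a plain-text file with
#'   one accession per line.
#'
#' @return An [abundance_matrix()] whose channel set equals the layout's
#'   active channels.
#' @export
read_abundance_table <- function(path, layout, bait_id,
                                 id_column = "Accession",
                                 gene_column = "Gene",
                                 contaminants = NULL) {
  stopifnot(inherits(layout, "plex_layout"))
  .assert(file.exists(path), "apms_io_error", "abundance file not found: %s", path)
  sep <- .detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("", "NA"), check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  .assert(id_column %in% names(tab), "apms_validation_error",
          "protein-id column '%s' not found in %s", id_column, path)
  active <- .active_channels(layout)
  missing_ch <- setdiff(active, names(tab))
  if (length(missing_ch) > 0L) {
    .stop2("apms_layout_mismatch",
           "abundance table lacks channel column(s): %s",
           paste(missing_ch, collapse = ", "))
  }
  ids <- as.character(tab[[id_column]])
  .assert(!anyNA(ids), "apms_validation_error", "missing protein identifier")
  if (is.character(contaminants) && length(contaminants) == 1L &&
      file.exists(contaminants)) {
    contaminants <- readLines(contaminants)
    contaminants <- trimws(contaminants[nzchar(trimws(contaminants))])
  }
  keep <- !(ids %in% contaminants)
  tab <- tab[keep, , drop = FALSE]
  ids <- ids[keep]
  vals <- as.matrix(tab[, active, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  gene <- NULL
  if (!is.null(gene_column) && gene_column %in% names(tab)) {
    gene <- as.character(tab[[gene_column]])
    names(gene) <- ids
  }
  abundance_matrix(vals, bait_id = bait_id, gene = gene)
}

#' Write an abundance matrix to a tab-separated file
#'
#' Inverse of [read_abundance_table()]: writes the protein-id column, an
#' optional gene column, and one column per channel; missing values are
#' written as empty fields.
#'
#' @param matrix An [abundance_matrix()].
#' @param path Output file path.
#' @param id_column Header used for the protein-identifier column.
#' @param gene_column Header used for the gene column when gene symbols are
#'   present.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(matrix, path, id_column = "Accession",
                                  gene_column = "Gene") {
  stopifnot(inherits(matrix, "abundance_matrix"))
  out <- data.frame(id = rownames(matrix$values), stringsAsFactors = FALSE)
  names(out) <- id_column
  if (!is.null(matrix$gene)) {
    out[[gene_column]] <- unname(matrix$gene[rownames(matrix$values)])
  }
  out <- cbind(out, as.data.frame(matrix$values, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
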