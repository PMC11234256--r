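#' Published high-confidence interactor table (packaged fixture)
#'
#' The 26 high-confidence procollagen-II interactors of the published
#' comparative interactome, with their printed fold enrichments, p-values
#' (homoscedastic t-test across three biological replicates) and q-values
#' (two-stage step-up procedure at a desired FDR of 10%).  Shipped as a
#' plain-text fixture in `inst/extdata/table1_interactors.tsv`; used as
#' the worked example for the multiple-testing module -- re-running the
#' two-stage procedure on these 26 p-values at the 10% level rejects
#' exactly the two proteins whose printed q-values fall below 0.10
#' (P4HB and PLOD2).
#'
#' @return Data frame with 26 rows and columns `protein` (full protein
#'   name), `gene`, `fold_enrichment`, `p_value`, `q_value`, in the
#'   printed (fold-enrichment descending) order.
#' @export
#' @examples
#' tab <- table1_fixture()
#' res <- bky_two_stage(tab$p_value, q_target = 0.10)
#' tab$gene[res$rejected]
table1_fixture <- function() {
  path <- system.file("extdata", "table1_interactors.tsv",
                      package = "apmsenrich", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  tab
}
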