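#' The published HNSC88 signature
#'
#' The 88-gene head-and-neck squamous cell carcinoma signature, as
#' published: 11 functional cluster groups (G1-G11, spanning tumor immune
#' response, survival, metastasis, growth and metabolism) with 5 to 15
#' genes each. Shipped as a plain-text fixture so real-data group
#' structure is available without any download; useful as a reference
#' input for [cluster_samples()] on matching expression data.
#'
#' @return A tibble with columns `group` (factor G1-G11) and `gene`
#'   (HGNC-style symbols), 88 rows.
#' @examples
#' sig <- hnsc88_signature()
#' table(sig$group)
#' @export
hnsc88_signature <- function() {
  path <- system.file("extdata", "hnsc88_groups.tsv", package = "sigforge",
                      mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  tibble::tibble(
    group = factor(df$group, levels = paste0("G", 1:11)),
    gene = df$gene)
}
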