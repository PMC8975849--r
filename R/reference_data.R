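#' Reported structural properties of reference networks
#'
#' Structural properties reported for nine published semantic and
#' free-association networks (`which = "semantic"`: SWOW-EN, South
#' Florida, Edinburgh, WordNet-derived taxonomic/synonym/phonological
#' layers and their multiplex, a Russian thesaurus, Dutch association
#' data) and for triangle preferential-attachment simulations at four
#' sizes (`which = "simulated"`). Columns: `nodes`, `edges`, `density`,
#' `transitivity`, `clustering`, and the reported random-graph thresholds
#' `pc2`, `pc3`. These serve as inputs for threshold and density
#' cross-checks; the underlying datasets themselves are not shipped.
#'
#' @param which `"semantic"` (default) or `"simulated"`.
#' @return A `data.frame`, one row per network.
#' @export
reference_networks <- function(which = c("semantic", "simulated")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0(which, "_networks.tsv"),
                   package = "kcliquenet", mustWork = TRUE)
  read.table(f, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = TRUE)
}
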