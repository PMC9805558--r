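#' Default universal single-copy marker-gene panel
#'
#' The species screen estimates per-species sequencing depth from the read
#' coverage of universal single-copy gene families. The default panel is a
#' fixed set of 15 family labels in the PhyEco "B" naming convention used
#' across the MIDAS lineage of tools. Database construction looks for these
#' labels in the `marker_family=` tag of gene description lines; the
#' simulator plants all 15 in every genome it generates.
#'
#' @return character vector of 15 marker family labels.
#' @export
#' @examples
#' marker_panel()
marker_panel <- function() {
  c("B000032", "B000039", "B000041", "B000062", "B000063",
    "B000065", "B000071", "B000079", "B000080", "B000081",
    "B000082", "B000086", "B000096", "B000103", "B000114")
}
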