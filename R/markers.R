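#' Single-copy marker gene sets
#'
#' Universal single-copy gene inventories used to score genome-bin
#' completeness and duplication: 51 markers for bacteria and 38 for archaea.
#' Because a single-copy gene occurs exactly once per genome, the fraction of
#' the set recovered in a bin estimates completeness, and multi-copy markers
#' indicate contamination (or scaffolding artifacts).
#'
#' The identifiers shipped here are synthetic placeholder ids, dominated by
#' ribosomal proteins and core information-processing genes as is conventional
#' for such sets; only the cardinalities (51 and 38) are contractual. Supply
#' your own character vector to any function accepting a marker set to use a
#' different inventory.
#'
#' @param domain `"bacteria"` or `"archaea"`.
#' @return Character vector of marker ids (length 51 for bacteria, 38 for
#'   archaea).
#' @examples
#' length(marker_set("bacteria"))
#' length(marker_set("archaea"))
#' @export
marker_set <- function(domain = c("bacteria", "archaea")) {
  domain <- match.arg(domain)
  if (domain == "bacteria") bacterial_markers else archaeal_markers
}

# 51 bacterial single-copy markers (synthetic placeholder ids)
bacterial_markers <- c(
  "rpL1_b", "rpL2_b", "rpL3_b", "rpL4_b", "rpL5_b", "rpL6_b", "rpL9_b",
  "rpL10_b", "rpL11_b", "rpL13_b", "rpL14_b", "rpL15_b", "rpL16_b",
  "rpL17_b", "rpL18_b", "rpL19_b", "rpL20_b", "rpL21_b", "rpL22_b",
  "rpL23_b", "rpL24_b", "rpL27_b", "rpL28_b", "rpL29_b",
  "rpS2_b", "rpS3_b", "rpS4_b", "rpS5_b", "rpS6_b", "rpS7_b", "rpS8_b",
  "rpS9_b", "rpS10_b", "rpS11_b", "rpS12_b", "rpS13_b", "rpS15_b",
  "rpS16_b", "rpS17_b", "rpS18_b", "rpS19_b", "rpS20_b",
  "rpoA_b", "rpoB_b", "rpoC_b", "secY_b", "ffh_b", "infB_b", "infC_b",
  "gyrA_b", "recA_b"
)

# 38 archaeal single-copy markers (synthetic placeholder ids)
archaeal_markers <- c(
  "rpL2_a", "rpL3_a", "rpL4_a", "rpL5_a", "rpL6_a", "rpL10_a", "rpL11_a",
  "rpL13_a", "rpL14_a", "rpL15_a", "rpL18_a", "rpL22_a", "rpL24_a",
  "rpL30_a", "rpL37ae_a", "rpL44e_a",
  "rpS2_a", "rpS3_a", "rpS4_a", "rpS5_a", "rpS7_a", "rpS8_a", "rpS9_a",
  "rpS11_a", "rpS13_a", "rpS15_a", "rpS17_a", "rpS19_a", "rpS19e_a",
  "rpS28e_a",
  "rpoA1_a", "rpoB_a", "secY_a", "infB_a", "eif2a_a", "prf1_a", "pcna_a",
  "cdc48_a"
)
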