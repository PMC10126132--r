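#' The 24-microRNA EBC analysis panel
#'
#' Canonical identifiers of the 24 microRNAs interrogated qualitatively in
#' exhaled breath condensate for case-control discrimination. The housekeeper
#' (miR-423-3p / miR-423-5p) is handled separately by the scoring
#' configuration and is never part of the analysis panel.
#'
#' @return Character vector of 24 canonical microRNA ids.
#' @export
#' @examples
#' ebc_mir_panel()
ebc_mir_panel <- function() {
  c("miR-324-5p", "miR-9", "miR-21", "miR-31", "miR-33b", "miR-96",
    "miR-105", "miR-146a-5p", "miR-182-5p", "miR-196b", "miR-199b-5p",
    "miR-200a", "miR-200b", "miR-205", "miR-212", "miR-221", "miR-345",
    "miR-429", "miR-767", "miR-944", "miR-1269a", "miR-1293", "miR-1910",
    "miR-3662")
}

#' Normalise microRNA identifiers
#'
#' Accepts the dot-separated form that spreadsheets produce
#' (`"miR.146a.5p"`) and the canonical dash form (`"miR-146a-5p"`), with or
#' without an `"hsa-"` species prefix, and returns the canonical dash form.
#'
#' @param x character vector of microRNA ids.
#' @return Character vector of canonical ids.
#' @export
#' @examples
#' normalize_mir_id(c("miR.146a.5p", "hsa-miR-21", "miR.3662"))
normalize_mir_id <- function(x) {
  x <- as.character(x)
  x <- sub("^hsa[-.]", "", x)
  x <- gsub(".", "-", x, fixed = TRUE)
  # tolerate the dash-less spelling "miR423-5p"
  sub("^(miR|let)([0-9])", "\\1-\\2", x)
}

#' @keywords internal
is_housekeeper_id <- function(x, housekeeper_id = "miR-423-3p") {
  nx <- normalize_mir_id(x)
  # either arm of miR-423 is accepted as the housekeeper label
  nx %in% unique(c(normalize_mir_id(housekeeper_id), "miR-423-3p", "miR-423-5p"))
}
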