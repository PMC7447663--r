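#' Immune checkpoint inhibitor drug classes
#'
#' The default mapping from ICI drug names to target classes:
#' ipilimumab (anti-CTLA-4), nivolumab and pembrolizumab (anti-PD-1),
#' atezolizumab and durvalumab (anti-PD-L1). Names are lower-cased
#' canonical forms; matching is exact after lower-casing and trimming.
#'
#' @return Named character vector mapping drug name to one of
#'   `"CTLA4"`, `"PD1"`, `"PDL1"`.
#' @export
ici_drug_classes <- function() {
  c(ipilimumab = "CTLA4",
    nivolumab = "PD1",
    pembrolizumab = "PD1",
    atezolizumab = "PDL1",
    durvalumab = "PDL1")
}

#' Exposure class labels
#'
#' @param ici_catalog Named character vector mapping ICI drug names to
#'   classes; see [ici_drug_classes()].
#' @return Character vector of the exposure labels assigned by
#'   [classify_exposure()]: one monotherapy label per ICI drug,
#'   `combination` (anti-CTLA-4 plus anti-PD-1/PD-L1), `other_multi_ici`
#'   (several ICIs without the CTLA-4 backbone) and `non_ici`.
#' @export
exposure_levels <- function(ici_catalog = ici_drug_classes()) {
  c(paste0(names(ici_catalog), "_mono"),
    "combination", "other_multi_ici", "non_ici")
}

#' Classify therapy exposure of each report
#'
#' Assigns exactly one exposure label per report from its suspected drug
#' list, ignoring any drug not present in `ici_catalog` (non-ICI
#' co-medication never changes the label):
#'
#' * no ICI drug — `non_ici`;
#' * exactly one ICI drug — `<drug>_mono`;
#' * an anti-CTLA-4 drug together with at least one anti-PD-1 or anti-PD-L1
#'   drug — `combination`;
#' * several ICI drugs without that combination pattern (e.g. nivolumab
#'   plus pembrolizumab) — `other_multi_ici`.
#'
#' @param reports An [icsr_set()].
#' @param ici_catalog Named character vector mapping ICI drug names to
#'   classes `CTLA4`, `PD1` or `PDL1`; see [ici_drug_classes()].
#' @return Factor of exposure labels with levels [exposure_levels()], one
#'   per report.
#' @examples
#' x <- icsr_set(c("R1", "R2", "R3"),
#'               drugs = list("ipilimumab",
#'                            c("ipilimumab", "nivolumab", "aspirin"),
#'                            c("nivolumab", "pembrolizumab")),
#'               events = "hypophysitis")
#' classify_exposure(x)
#' @export
classify_exposure <- function(reports, ici_catalog = ici_drug_classes()) {
  stopifnot(is_icsr_set(reports))
  if (!all(ici_catalog %in% c("CTLA4", "PD1", "PDL1"))) {
    stop("ici_catalog classes must be CTLA4, PD1 or PDL1", call. = FALSE)
  }
  names(ici_catalog) <- canonical_drug(names(ici_catalog))
  labels <- vapply(reports$drugs, function(d) {
    ici <- intersect(d, names(ici_catalog))
    if (length(ici) == 0L) return("non_ici")
    if (length(ici) == 1L) return(paste0(ici, "_mono"))
    cls <- ici_catalog[ici]
    if (any(cls == "CTLA4") && any(cls %in% c("PD1", "PDL1"))) "combination"
    else "other_multi_ici"
  }, character(1))
  factor(labels, levels = exposure_levels(ici_catalog))
}

#' Standard exposure selectors for spectrum screening
#'
#' Builds the named list of report selectors used by [screen_spectrum()]
#' and [compare_subgroups()]: any ICI, each monotherapy, pooled
#' anti-CTLA-4 / anti-PD-1 / anti-PD-L1 monotherapy, anti-PD-1/PD-L1
#' monotherapy pooled, and combination therapy. Each selector is a function
#' taking an `icsr_set` and returning one logical per report.
#'
#' @inheritParams classify_exposure
#' @return Named list of selector functions.
#' @export
exposure_selectors <- function(ici_catalog = ici_drug_classes()) {
  by_class <- function(keep) {
    force(keep)
    function(reports) classify_exposure(reports, ici_catalog) %in% keep
  }
  mono <- paste0(names(ici_catalog), "_mono")
  names(mono) <- mono
  pooled <- function(classes) mono[ici_catalog[names(ici_catalog)] %in% classes]
  sel <- c(
    list(any_ici = by_class(c(mono, "combination", "other_multi_ici")),
         combination = by_class("combination"),
         ctla4_mono = by_class(pooled("CTLA4")),
         pd1_mono = by_class(pooled("PD1")),
         pdl1_mono = by_class(pooled("PDL1")),
         pd1_pdl1_mono = by_class(pooled(c("PD1", "PDL1")))),
    lapply(mono, by_class)
  )
  sel
}
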