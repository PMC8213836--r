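#' Describe a crosslinker (binder) architecture
#'
#' A crosslinker is characterised for the surface simulation only by the
#' maximal anchor-to-anchor distance it can bridge: the lengths of the two
#' DNA levers it connects, the receptor extracellular domains carried at
#' their tips, and the span between the molecule's paratope pairs.
#'
#' @param name Label for the architecture.
#' @param span_nm Paratope-to-paratope span of the molecule in nm
#'   (non-negative).
#' @param lever_length_nm Length of one DNA lever in nm (default 32).
#' @param her2_length_nm Height of the HER2 extracellular domain in nm
#'   (default 8).
#' @param her2_terms Number of receptor lengths added to the reach
#'   (default 2, one per bridged lever; set to 1 for sensitivity analysis
#'   if the receptor is counted once).
#' @return An object of class `crosslinker_spec`.
#' @seealso [crosslinker_preset()] for the built-in architectures,
#'   [max_reach()] for the derived reach.
#' @examples
#' crosslinker_spec("custom", span_nm = 10)
#' @export
crosslinker_spec <- function(name, span_nm, lever_length_nm = 32,
                             her2_length_nm = 8, her2_terms = 2) {
  if (!is.finite(span_nm) || span_nm < 0) {
    stop_invalid("span_nm must be non-negative")
  }
  if (!is.finite(lever_length_nm) || lever_length_nm < 0 ||
      !is.finite(her2_length_nm) || her2_length_nm < 0 ||
      !is.finite(her2_terms) || her2_terms < 0) {
    stop_invalid("lengths and her2_terms must be non-negative")
  }
  spec <- structure(
    list(name = as.character(name), span_nm = span_nm,
         lever_length_nm = lever_length_nm,
         her2_length_nm = her2_length_nm,
         her2_terms = as.integer(her2_terms)),
    class = "crosslinker_spec"
  )
  if (max_reach(spec) <= 0) stop_invalid("crosslinker reach must be positive")
  spec
}

#' Built-in binder architectures
#'
#' Three preset architectures that differ only in paratope-pair span:
#' `"441"` — tetravalent scFv-IgG fusion, span ~20 nm; `"841"` — bivalent
#' scFv-Fab fusion, span ~2 nm; `"mAb_combo"` — a combination of two
#' monoclonal IgGs, span ~14 nm.
#'
#' @param name One of `"441"`, `"841"`, `"mAb_combo"`.
#' @return A `crosslinker_spec`.
#' @examples
#' max_reach(crosslinker_preset("441")) # 100 nm
#' @export
crosslinker_preset <- function(name = c("441", "841", "mAb_combo")) {
  name <- match.arg(name)
  span <- c("441" = 20, "841" = 2, "mAb_combo" = 14)[[name]]
  crosslinker_spec(name, span_nm = span)
}

#' Maximal anchor-to-anchor crosslinking reach
#'
#' The largest in-plane distance between two lever anchor points that a
#' molecule can bridge: both DNA levers, the receptor domain(s) at their
#' tips, and the molecule's paratope span, all assumed freely pivoting and
#' maximally extended.
#'
#' @param spec A `crosslinker_spec`.
#' @return Reach in nm: `2 * lever_length + her2_terms * her2_length + span`.
#' @examples
#' max_reach(crosslinker_preset("841")) # 82 nm
#' @export
max_reach <- function(spec) {
  stopifnot(inherits(spec, "crosslinker_spec"))
  if (spec$span_nm < 0) stop_invalid("span_nm must be non-negative")
  2 * spec$lever_length_nm + spec$her2_terms * spec$her2_length_nm +
    spec$span_nm
}

#' @export
print.crosslinker_spec <- function(x, ...) {
  cat(sprintf(
    "<crosslinker_spec> %s: span %g nm, lever %g nm, receptor %g nm x%d -> reach %g nm\n",
    x$name, x$span_nm, x$lever_length_nm, x$her2_length_nm, x$her2_terms,
    max_reach(x)))
  invisible(x)
}
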