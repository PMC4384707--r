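# joules per MeV (CODATA)
MEV_TO_J <- 1.602176634e-13

#' Label an exposure condition
#'
#' Conditions are (injected activity, time after injection) pairs. A compact
#' label such as `"1.7kBq_6h"` keys per-condition results throughout the
#' pipeline.
#'
#' @param activity_kbq Injected activity in kBq.
#' @param time_h Time after injection in hours.
#' @return Character vector of condition labels.
#' @examples
#' condition_label(c(1.7, 105), c(6, 1))
#' @export
condition_label <- function(activity_kbq, time_h) {
  sprintf("%gkBq_%gh", activity_kbq, time_h)
}

#' Round to significant figures for report tables
#'
#' Report tables carry doses rounded to a stated number of significant
#' figures (default 2); raw values are always retained alongside. Uses
#' [base::signif()], i.e. round-half-even at the binary representation.
#'
#' @param x Numeric vector.
#' @param digits Significant figures (default 2).
#' @return Numeric vector rounded to `digits` significant figures.
#' @export
signif_report <- function(x, digits = 2) signif(x, digits)

# stop() with a consistent prefix, classed for testthat
stop_atdose <- function(msg, ..., class = "atdose_error") {
  abort(sprintf(msg, ...), class = class)
}
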