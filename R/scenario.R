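#' CTM smoke contribution on the fine grid
#'
#' Difference of the paired runs, `ctm_on - ctm_off`, mapped from coarse
#' to fine cells by nearest-coarse-cell assignment (each fine cell takes
#' the value of the coarse cell containing it; no interpolation).  The
#' difference may be negative under simulation noise and is deliberately
#' not floored here -- flooring would bias the classification threshold.
#'
#' @param pair a `ctm_pair` from [simulate_ctm()].
#' @param species `"OC"`, `"EC"`, or `"both"` (OC + EC summed, the
#'   default used for classification).
#' @return fine-cell-by-day matrix of the smoke contribution in ug/m3.
#' @export
smoke_contribution <- function(pair, species = c("both", "OC", "EC")) {
  species <- match.arg(species)
  one <- function(sp) {
    on <- pair[[sp]]$ctm_on; off <- pair[[sp]]$ctm_off
    if (!identical(dim(on), dim(off))) stop("ctm_on / ctm_off shape mismatch")
    (on - off)[pair$map, , drop = FALSE]
  }
  if (species == "both") one("OC") + one("EC") else one(species)
}

#' Classify cell-days into smoke scenarios
#'
#' A cell-day is `SMOKE_ON` iff the CTM smoke contribution strictly
#' exceeds the threshold `delta`; ties and everything below are
#' `SMOKE_OFF`.  With `delta = 0` exactly the cell-days with positive
#' contribution are flagged.
#'
#' @param contribution fine-grid cell-by-day contribution matrix from
#'   [smoke_contribution()].
#' @param delta threshold in ug/m3 (>= 0); default 0.1.
#' @return object of class `scenario_mask`: a logical cell-by-day matrix
#'   (`TRUE` = SMOKE_ON) with the threshold and the unfloored
#'   contribution attached as attributes.
#' @export
classify_scenario <- function(contribution, delta = 0.1) {
  stopifnot(delta >= 0)
  m <- contribution > delta
  attr(m, "delta") <- delta
  attr(m, "contribution") <- contribution
  class(m) <- c("scenario_mask", class(m))
  m
}
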