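# Closed-form estimator of the total number of coding transcripts.
#
# Let I + II be the predictions consistent with the known annotation
# (II of them RNA-seq validated), III the expected number of true novel
# validated transcripts, IV the novel unvalidated true transcripts, and
# K the size of the known set.  Assuming the predictor's sensitivity on
# known transcripts, Sn = (I + II) / K, carries over to undiscovered
# ones, the total satisfies Sn = (I + II + III + IV) / total, i.e.
#
#   total = (I + II + III + IV) / Sn
#
# With III = 0 and IV = 0 the estimate collapses to K exactly.

#' Assemble the census estimator inputs
#'
#' @param I_plus_II predictions consistent with the known set.
#' @param III expected true novel validated transcripts (see
#'   [precision_adjust()]).
#' @param IV novel unvalidated true transcripts (default 0: lower-bound
#'   mode, since validation saturation suggests IV is small).
#' @param known_total size of the known transcript set.
#' @return object of class `"census_inputs"`.
#' @export
census_inputs <- function(I_plus_II, III, IV = 0, known_total) {
  stopifnot(I_plus_II >= 0, III >= 0, IV >= 0, known_total >= 0)
  if (I_plus_II > known_total)
    stop("I_plus_II cannot exceed known_total", call. = FALSE)
  structure(list(I_plus_II = I_plus_II, III = III, IV = IV,
                 known_total = known_total), class = "census_inputs")
}

#' Predictor sensitivity on the known transcript set
#'
#' @param inputs a [census_inputs()].
#' @return fraction `I_plus_II / known_total`.
#' @export
sensitivity_known <- function(inputs) {
  if (inputs$known_total <= 0) stop("known_total must be > 0", call. = FALSE)
  inputs$I_plus_II / inputs$known_total
}

#' Estimate the total number of transcripts with coding potential
#'
#' @param inputs a [census_inputs()].
#' @return estimated count, rounded to the nearest integer.
#' @export
estimate_total <- function(inputs) {
  sn <- sensitivity_known(inputs)
  if (sn <= 0) stop("sensitivity is zero; estimate undefined", call. = FALSE)
  round((inputs$I_plus_II + inputs$III + inputs$IV) / sn)
}

#' Expected true novel validated transcripts (III)
#'
#' The medium-confidence (VMC) count discounted by the precision
#' estimated from the PCR panel.
#'
#' @param vmc_count number of VMC transcripts.
#' @param pcr_validated,pcr_assayed PCR panel outcome counts.
#' @param use_rounded_percent multiply by the percentage rounded to one
#'   decimal (e.g. 84.1%) rather than the exact ratio; `TRUE` by
#'   default, reproducing the published worked value exactly.
#' @return `III`, rounded to the nearest integer.
#' @export
precision_adjust <- function(vmc_count, pcr_validated, pcr_assayed,
                             use_rounded_percent = TRUE) {
  if (pcr_assayed <= 0) stop("pcr_assayed must be > 0", call. = FALSE)
  prec <- if (use_rounded_percent)
    round(100 * pcr_validated / pcr_assayed, 1) / 100
  else pcr_validated / pcr_assayed
  round(vmc_count * prec)
}

#' Recover a set size from a printed (count, percentage) pair
#'
#' Helper for inputs reported only as "n items = p% of the set".
#'
#' @param count the printed subset count.
#' @param percent the printed percentage (e.g. 73.94).
#' @return the implied total, rounded to the nearest integer.
#' @export
total_from_fraction <- function(count, percent) {
  stopifnot(percent > 0)
  round(count / (percent / 100))
}
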