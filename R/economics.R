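#' Screening-economics arithmetic
#'
#' Simple composition rules for the cost of saving a life from melanoma by
#' secondary prevention. The number needed to screen (NNS) is the product
#' of three factors: consultations per excision, benign excisions per
#' melanoma (the NNT), and melanomas excised per life saved (the scenario
#' engine's excisions-per-death-averted ratio). Currency values are labels;
#' no exchange-rate handling.
#'
#' @param consultations_per_excision average screening consultations per
#'   lesion excised (1 for extreme-risk screening, ~25 for the general
#'   public).
#' @param nnt benign pigmented lesions excised per melanoma excised.
#' @param excisions_per_life melanomas excised per life saved (scalar or a
#'   length-2 range).
#' @return `nns()`: the number of screening assessments per life saved.
#' @examples
#' nns(25, 10, 100)   # 25000
#' @export
nns <- function(consultations_per_excision, nnt, excisions_per_life) {
  stopifnot(consultations_per_excision > 0, nnt > 0,
            all(excisions_per_life > 0))
  consultations_per_excision * nnt * excisions_per_life
}

#' Total cost per excision event
#'
#' The excision event itself (consultation + excision + pathology) plus the
#' additional screening consultations that did not lead to an excision:
#' `cost_excision_event + (consultations_per_excision - 1) * cost_consultation`.
#'
#' @inheritParams nns
#' @param cost_excision_event cost of a consultation-plus-excision-plus-
#'   pathology event (default $300).
#' @param cost_consultation cost of a screening consultation (default $50).
#' @return Cost per excision (currency units).
#' @examples
#' cost_per_excision(25)   # 300 + 24 * 50 = 1500
#' @export
cost_per_excision <- function(consultations_per_excision,
                              cost_excision_event = 300,
                              cost_consultation = 50) {
  stopifnot(consultations_per_excision >= 1,
            cost_excision_event >= 0, cost_consultation >= 0)
  cost_excision_event + (consultations_per_excision - 1) * cost_consultation
}

#' Cost per life saved by secondary prevention
#'
#' Cost per excision times the NNT times the number of melanoma excisions
#' per life saved, applied elementwise when `excisions_per_life` is a
#' range. With one consultation per excision and an NNT of 10, the
#' interpolated 50-120 excisions-per-life range gives $150,000-$360,000;
#' with 25 consultations per excision, $750,000-$1.8M.
#'
#' @inheritParams cost_per_excision
#' @param excisions_per_life scalar or length-2 range (low, high).
#' @return Numeric of the same length as `excisions_per_life`.
#' @export
cost_per_life_saved <- function(consultations_per_excision, nnt,
                                excisions_per_life,
                                cost_excision_event = 300,
                                cost_consultation = 50) {
  stopifnot(all(excisions_per_life > 0), nnt > 0)
  if (length(excisions_per_life) == 2L &&
      excisions_per_life[1] > excisions_per_life[2])
    stop("excisions_per_life range must be (low, high)")
  cost_per_excision(consultations_per_excision, cost_excision_event,
                    cost_consultation) * nnt * excisions_per_life
}

#' Cost per life saved by primary prevention
#'
#' Campaign expenditure per capita times the population, divided by the
#' number of melanoma deaths averted.
#'
#' @param per_capita_spend campaign cost per capita over the period.
#' @param population average population covered.
#' @param lives_saved melanoma deaths averted (must be positive).
#' @return Cost per life saved (currency units).
#' @examples
#' primary_prevention_cost(3.44, 4.5e6, 900)   # 17200
#' @export
primary_prevention_cost <- function(per_capita_spend, population,
                                    lives_saved) {
  stopifnot(per_capita_spend > 0, population > 0)
  if (length(lives_saved) != 1L || lives_saved <= 0)
    stop("lives_saved must be a positive scalar")
  per_capita_spend * population / lives_saved
}

#' Inflation adjustment by compound growth
#'
#' @param amount currency amount.
#' @param annual_rate average annual inflation rate (e.g. 0.025).
#' @param years number of years of compounding.
#' @return `amount * (1 + annual_rate)^years`.
#' @examples
#' inflation_adjust(17200, 0.025, 14)   # ~24304
#' @export
inflation_adjust <- function(amount, annual_rate, years) {
  stopifnot(annual_rate >= 0, years >= 0)
  amount * (1 + annual_rate)^years
}
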