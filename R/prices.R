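# Unit prices for resource-use valuation (German guideline prices, 2013 euro).

#' Unit-price table for costing resource use
#'
#' Prices per unit of health-care contact, hospital day, kilometre travelled
#' and hour of unpaid work, plus the intervention program costs, the
#' statutory-insurance population share used in medication weighting, the
#' consumer-price-index factor to the 2013 reference year and the euro to
#' pound-sterling purchasing-power conversion rate.
#'
#' Contacts: GP EUR 20.92, internal-medicine consult EUR 68.06, psychiatrist
#' session EUR 46.55, psychotherapist session EUR 81.44. Hospital days:
#' mental hospital EUR 335.52, psychosomatic medicine EUR 306.41. Travel
#' EUR 0.30/km; informal care and domestic help EUR 18.33/h (shadow price);
#' participant time EUR 23.10/h. The guided web-based program costs EUR 299
#' per participant, the psycho-educational control program EUR 10. Prices
#' for other medical specialists and psychiatric day care are not fixed by
#' the published price list and are configurable here.
#'
#' @param ... named overrides of any default entry.
#' @return an object of class `unit_price_table` (named list).
#' @export
#' @examples
#' p <- unit_price_table()
#' p$gp # 20.92
unit_price_table <- function(...) {
  p <- list(
    gp                    = 20.92,  # EUR per GP visit
    internist             = 68.06,  # EUR per internal-medicine consult
    psychiatrist          = 46.55,  # EUR per session
    psychotherapist       = 81.44,  # EUR per session
    other_specialist      = 40.00,  # EUR per contact (configurable default)
    inpatient_mental      = 335.52, # EUR per day
    inpatient_psychosomatic = 306.41, # EUR per day
    daycare               = 150.00, # EUR per day (configurable default)
    travel                = 0.30,   # EUR per km
    informal_care         = 18.33,  # EUR per hour (shadow price)
    domestic_help         = 18.33,  # EUR per hour (shadow price)
    opportunity_cost      = 23.10,  # EUR per participant hour
    intervention_cost     = 299,    # EUR per intervention participant
    control_program_cost  = 10,     # EUR per control participant
    statutory_share       = 0.89,   # statutorily insured population share
    cpi_index_factor      = 1.04,   # indexing to the 2013 reference year
    euro_to_gbp           = 0.85,   # purchasing-power parity GBP per EUR
    antidepressant_packages = data.frame(
      # three largest packages of the same agent: pharmacy retail prices for
      # statutory vs private insurance and defined daily doses per package
      price_statutory = c(16.50, 28.90, 46.80),
      price_private   = c(19.80, 33.50, 53.90),
      ddd             = c(50, 100, 100)
    )
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown price entries: ", paste(unknown, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  validate_price_table(p)
  structure(p, class = "unit_price_table")
}

validate_price_table <- function(p) {
  scalars <- setdiff(names(p), "antidepressant_packages")
  vals <- unlist(p[scalars])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("unit prices must be finite and non-negative")
  }
  for (nm in c("statutory_share", "euro_to_gbp")) {
    if (p[[nm]] <= 0 || p[[nm]] > 1) stop(nm, " must lie in (0, 1]")
  }
  pk <- p$antidepressant_packages
  if (any(pk$ddd <= 0)) stop("package defined daily doses must be positive")
  invisible(p)
}

#' Read or write a unit-price table as YAML
#'
#' @param path file path.
#' @return `read_price_table()` returns a `unit_price_table`;
#'   `write_price_table()` invisibly returns `path`.
#' @export
read_price_table <- function(path) {
  raw <- yaml::read_yaml(path)
  pk <- raw$antidepressant_packages
  if (!is.null(pk)) raw$antidepressant_packages <- as.data.frame(pk)
  do.call(unit_price_table, raw)
}

#' @rdname read_price_table
#' @param prices a `unit_price_table`.
#' @export
write_price_table <- function(prices, path) {
  out <- unclass(prices)
  out$antidepressant_packages <- as.list(out$antidepressant_packages)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Index a euro amount to the reference year and convert to pounds
#'
#' @param amount euro amount (vectorised).
#' @param index_factor consumer-price-index factor (default 1.04).
#' @param rate pounds per euro (default 0.85).
#' @return a data.frame with columns `eur` (indexed euro) and `gbp`.
#' @export
#' @examples
#' index_and_convert(299, index_factor = 1)$gbp # 254.15 -> GBP 254 displayed
index_and_convert <- function(amount, index_factor = 1.04, rate = 0.85) {
  stopifnot(all(amount >= 0), index_factor > 0, rate > 0)
  eur <- amount * index_factor
  data.frame(eur = eur, gbp = eur * rate)
}
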