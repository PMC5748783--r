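## Sample screening: age limits and energy-misreporter exclusion.
##
## Energy misreporting is judged on total reported energy (including alcohol)
## against predicted basal metabolic rate; substitution accounting elsewhere
## in the package uses non-alcohol energy only.

## Henry (2005) BMR coefficient tables, MJ/day; height in metres.
## Bands: [18, 30), [30, 60), [60, Inf).
HENRY_WEIGHT <- list(
  male   = rbind(c(0.0669, 2.28), c(0.0592, 2.48), c(0.0563, 2.15)),
  female = rbind(c(0.0546, 2.33), c(0.0407, 2.90), c(0.0424, 2.38)))
HENRY_WEIGHT_HEIGHT <- list(
  male   = rbind(c(0.0600, 1.31, 0.473),
                 c(0.0476, 2.26, -0.574),
                 c(0.0478, 2.26, -1.070)),
  female = rbind(c(0.0433, 2.57, -1.180),
                 c(0.0342, 2.10, -0.0486),
                 c(0.0356, 1.76, 0.0448)))

#' Basal metabolic rate from the Henry predictive equations
#'
#' Evaluates the published Henry (2005) coefficient tables by sex and age
#' band (18-30, 30-60, 60+ years), either the weight-only or the
#' weight-and-height variant, and converts megajoules to kilocalories
#' (x 239.005736). Vectorised over individuals.
#'
#' @param sex \code{"male"} or \code{"female"} (recycled).
#' @param age_y Age in years; must be at least 18 (below the supported bands
#'   otherwise).
#' @param weight_kg Body weight, kg.
#' @param height_cm Body height, cm (required for the weight-height variant).
#' @param equation \code{"weight_height"} (default) or \code{"weight"}.
#' @return Basal metabolic rate, kcal/day.
#' @export
henry_bmr <- function(sex, age_y, weight_kg, height_cm = NULL,
                      equation = c("weight_height", "weight")) {
  equation <- match.arg(equation)
  n <- max(length(sex), length(age_y), length(weight_kg))
  sex <- rep_len(as.character(sex), n)
  age_y <- rep_len(age_y, n)
  weight_kg <- rep_len(weight_kg, n)
  if (any(age_y < 18))
    stop("age below the supported Henry age bands (18+)", call. = FALSE)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  band <- findInterval(age_y, c(18, 30, 60))
  mj <- numeric(n)
  if (equation == "weight") {
    for (i in seq_len(n)) {
      cf <- HENRY_WEIGHT[[sex[i]]][band[i], ]
      mj[i] <- cf[1] * weight_kg[i] + cf[2]
    }
  } else {
    if (is.null(height_cm))
      stop("height_cm required for the weight-height Henry equations",
           call. = FALSE)
    height_m <- rep_len(height_cm, n) / 100
    for (i in seq_len(n)) {
      cf <- HENRY_WEIGHT_HEIGHT[[sex[i]]][band[i], ]
      mj[i] <- cf[1] * weight_kg[i] + cf[2] * height_m[i] + cf[3]
    }
  }
  mj * MJ_TO_KCAL
}

#' Goldberg/Black cut-offs for the EI:BMR ratio
#'
#' Confidence-limit form of the Goldberg cut-off: the plausible range of the
#' ratio of mean reported energy intake to basal metabolic rate for a given
#' physical activity level (PAL) is
#' \code{PAL * exp(-+ 1.96 * s / 100)} with
#' \code{s = sqrt(cv_ei^2 / n_days + cv_bmr^2 + cv_pal^2)}.
#' Default coefficients of variation are the standard 23% (within-person
#' energy intake), 8.5% (BMR prediction) and 15% (PAL).
#'
#' @param pal Physical activity level (1.4, 1.6 or 1.8 for little active,
#'   moderately active and active lifestyles).
#' @param n_days Number of recorded days (at least 1).
#' @param cv_ei,cv_bmr,cv_pal Percent coefficients of variation.
#' @param z Normal quantile of the confidence limits (default 1.96).
#' @return Named vector \code{c(lower=, upper=)} of EI:BMR cut-offs.
#' @export
goldberg_bounds <- function(pal, n_days, cv_ei = 23, cv_bmr = 8.5,
                            cv_pal = 15, z = 1.96) {
  if (n_days < 1) stop("n_days must be at least 1", call. = FALSE)
  s <- sqrt(cv_ei^2 / n_days + cv_bmr^2 + cv_pal^2)
  c(lower = pal * exp(-z * s / 100), upper = pal * exp(z * s / 100))
}

#' Screening configuration
#'
#' @param age_min,age_max Retained age range; the upper bound is exclusive in
#'   the sense that ages strictly above \code{age_max} are excluded (a
#'   65.0-year-old is retained).
#' @param pal_by_activity Named PAL per activity level.
#' @param cv_ei,cv_bmr,cv_pal Goldberg coefficients of variation (percent).
#' @param equation Henry equation variant, see \code{\link{henry_bmr}}.
#' @return A list of class \code{screening_config}.
#' @export
screening_config <- function(age_min = 18, age_max = 65,
                             pal_by_activity = c(low = 1.4, moderate = 1.6,
                                                 high = 1.8),
                             cv_ei = 23, cv_bmr = 8.5, cv_pal = 15,
                             equation = c("weight_height", "weight")) {
  structure(list(age_min = age_min, age_max = age_max,
                 pal_by_activity = pal_by_activity,
                 cv_ei = cv_ei, cv_bmr = cv_bmr, cv_pal = cv_pal,
                 equation = match.arg(equation)),
            class = "screening_config")
}

#' Screen a population for age and energy misreporting
#'
#' Excludes individuals outside the configured age range, then flags under-
#' and over-reporters whose ratio of mean daily reported energy intake
#' (including alcohol energy) to Henry basal metabolic rate falls outside the
#' Goldberg/Black cut-offs for their physical activity level.
#'
#' @param individuals Individuals data frame.
#' @param records Day-level consumption records.
#' @param composition A \code{composition_table}.
#' @param config A \code{\link{screening_config}}.
#' @return A list with the retained \code{individuals} and \code{records} and
#'   a \code{report} of class \code{screening_report} whose counts satisfy
#'   \code{n_input = n_age_excluded + n_under_reporters + n_over_reporters +
#'   n_retained}; the report's \code{flags} data frame carries each
#'   individual's EI:BMR ratio and the cut-offs applied.
#' @export
screen_population <- function(individuals, records, composition,
                              config = screening_config()) {
  individuals <- validate_individuals(individuals)
  records <- validate_records(records, individuals, composition)
  comp <- composition
  n_days <- tapply(records$day_index, records$individual_id,
                   function(d) length(unique(d)))
  if (any(!(individuals$individual_id %in% names(n_days))))
    stop("individual with zero recorded days", call. = FALSE)
  D <- as.numeric(n_days[individuals$individual_id])

  kcal <- (comp$energy_kcal_per_100g +
             comp$alcohol_kcal_per_100g)[match(records$food_id, comp$food_id)]
  ei_tot <- tapply(records$grams * kcal / 100, records$individual_id, sum)
  ei <- as.numeric(ei_tot[individuals$individual_id]) / D

  bmr <- henry_bmr(individuals$sex, individuals$age_y, individuals$weight_kg,
                   individuals$height_cm, equation = config$equation)
  pal <- config$pal_by_activity[individuals$activity]
  s <- sqrt(config$cv_ei^2 / D + config$cv_bmr^2 + config$cv_pal^2)
  lower <- pal * exp(-1.96 * s / 100)
  upper <- pal * exp(1.96 * s / 100)
  ratio <- ei / bmr

  age_excl <- individuals$age_y > config$age_max |
    individuals$age_y < config$age_min
  under <- !age_excl & ratio < lower
  over <- !age_excl & ratio > upper
  retained <- !age_excl & !under & !over

  status <- ifelse(age_excl, "age_excluded",
                   ifelse(under, "under_reporter",
                          ifelse(over, "over_reporter", "retained")))
  flags <- data.frame(individual_id = individuals$individual_id,
                      age_y = individuals$age_y, ei_kcal = ei, bmr_kcal = bmr,
                      ei_bmr = ratio, pal = as.numeric(pal),
                      cutoff_lower = as.numeric(lower),
                      cutoff_upper = as.numeric(upper),
                      status = status, stringsAsFactors = FALSE)
  report <- structure(list(n_input = nrow(individuals),
                           n_age_excluded = sum(age_excl),
                           n_under_reporters = sum(under),
                           n_over_reporters = sum(over),
                           n_retained = sum(retained),
                           flags = flags),
                      class = "screening_report")
  keep_ids <- individuals$individual_id[retained]
  list(individuals = individuals[retained, , drop = FALSE],
       records = records[records$individual_id %in% keep_ids, , drop = FALSE],
       report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Screening report\n")
  cat(sprintf("  input:           %d\n", x$n_input))
  cat(sprintf("  age excluded:    %d\n", x$n_age_excluded))
  cat(sprintf("  under-reporters: %d\n", x$n_under_reporters))
  cat(sprintf("  over-reporters:  %d\n", x$n_over_reporters))
  cat(sprintf("  retained:        %d (%.1f%%)\n", x$n_retained,
              100 * x$n_retained / x$n_input))
  invisible(x)
}
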