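## Probability approach to nutrient inadequacy.
##
## Individual requirements are modelled as Normal(EAR, cv * EAR). The
## probability that an individual's requirement exceeds their usual intake y
## is the left normal CDF evaluated at (EAR - y) / (cv * EAR); prevalence of
## inadequacy is the (survey-weighted) mean of these probabilities, the best
## estimate of the proportion of the population with intakes below their own
## requirement.

#' Probability that an individual's requirement exceeds their intake
#'
#' Returns \eqn{\Phi((EAR - y) / (cv \cdot EAR))} with \eqn{\Phi} the
#' standard normal left CDF and \eqn{y} the usual intake per kg body weight.
#' At \code{usual_perkg == ear} the probability is exactly 0.5; the function
#' is continuous and strictly decreasing in the intake. At an intake of
#' \code{ear * (1 + 2 cv)} the inadequacy probability is
#' \code{1 - pnorm(2) = 0.02275}, i.e. adequacy 97.72% (often quoted as the
#' conventional 97.5%).
#'
#' @param usual_perkg Usual intake per kg body weight (same unit as
#'   \code{ear}); vectorised.
#' @param ear Estimated average requirement (> 0).
#' @param cv Requirement coefficient of variation in (0, 1) (default 0.125).
#' @return Probability of inadequacy in [0, 1].
#' @export
inadequacy_probability <- function(usual_perkg, ear, cv = 0.125) {
  stopifnot(ear > 0, cv > 0, cv < 1, all(usual_perkg >= 0))
  stats::pnorm((ear - usual_perkg) / (cv * ear))
}

#' Wald confidence interval for a prevalence
#'
#' Normal-approximation binomial interval
#' \eqn{p \pm z \sqrt{p (100 - p) / n}} on the percentage scale, clipped to
#' [0, 100]. With \code{level = 0.95}, \code{z = 1.959964}.
#'
#' @param prevalence_pct Prevalence in percent, in [0, 100].
#' @param n Sample size (unweighted count of individuals).
#' @param level Confidence level (default 0.95).
#' @return Named vector \code{c(lower=, upper=)} in percent.
#' @export
wald_ci <- function(prevalence_pct, n, level = 0.95) {
  stopifnot(prevalence_pct >= 0, prevalence_pct <= 100, n >= 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(prevalence_pct * (100 - prevalence_pct) / n)
  c(lower = max(0, prevalence_pct - half),
    upper = min(100, prevalence_pct + half))
}

#' Population prevalence of inadequacy
#'
#' The survey-weighted mean of individual inadequacy probabilities, in
#' percent, with a Wald confidence interval computed on the unweighted
#' sample size (survey weights move the point estimate, not the CI
#' half-width).
#'
#' @param probabilities Individual inadequacy probabilities in [0, 1].
#' @param survey_weights Positive weights, same length (default equal).
#' @param level Confidence level (default 0.95).
#' @param nutrient Optional nutrient label carried in the result.
#' @return An object of class \code{prevalence_result} with fields
#'   \code{prevalence_pct}, \code{ci_lower_pct}, \code{ci_upper_pct},
#'   \code{n}, \code{weighted}.
#' @export
prevalence <- function(probabilities, survey_weights = NULL, level = 0.95,
                       nutrient = NA_character_) {
  if (length(probabilities) == 0) stop("empty input", call. = FALSE)
  stopifnot(all(probabilities >= 0), all(probabilities <= 1))
  weighted <- !is.null(survey_weights)
  if (weighted) {
    stopifnot(length(survey_weights) == length(probabilities),
              all(survey_weights > 0))
    p <- 100 * stats::weighted.mean(probabilities, survey_weights)
  } else {
    p <- 100 * mean(probabilities)
  }
  ci <- wald_ci(p, length(probabilities), level)
  structure(list(nutrient = nutrient, prevalence_pct = p,
                 ci_lower_pct = unname(ci["lower"]),
                 ci_upper_pct = unname(ci["upper"]),
                 n = length(probabilities), weighted = weighted),
            class = "prevalence_result")
}

#' @export
print.prevalence_result <- function(x, ...) {
  cat(sprintf("%s inadequacy: %.2f%% (95%% CI: %.2f; %.2f), n = %d%s\n",
              ifelse(is.na(x$nutrient), "Nutrient", x$nutrient),
              x$prevalence_pct, x$ci_lower_pct, x$ci_upper_pct, x$n,
              if (x$weighted) ", survey-weighted" else ""))
  invisible(x)
}

#' Monte-Carlo oracle for the inadequacy probability
#'
#' Estimates the probability that a requirement drawn from
#' Normal(EAR, cv * EAR) exceeds the intake, by simulation. Used as an
#' independent check of the closed-form \code{\link{inadequacy_probability}}.
#' The caller's RNG state is left untouched.
#'
#' @param usual_perkg Usual intake per kg.
#' @param ear Estimated average requirement.
#' @param cv Requirement CV.
#' @param n_draws Number of requirement draws (at least 1e5).
#' @param seed Integer seed for the draw.
#' @return Monte-Carlo probability of inadequacy.
#' @export
mc_oracle_probability <- function(usual_perkg, ear, cv = 0.125,
                                  n_draws = 1e6, seed = 1L) {
  stopifnot(n_draws >= 1e5)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  mean(stats::rnorm(n_draws, mean = ear, sd = cv * ear) > usual_perkg)
}

#' Prevalence of inadequacy for protein and every amino acid
#'
#' Applies the probability approach to a fitted set of usual intakes:
#' per-individual inadequacy probabilities for protein (g/kg/day against the
#' protein EAR) and each of the nine indispensable amino acids (mg/kg/day
#' against their EARs), averaged with the survey weights.
#'
#' @param usual A \code{usual_intake_fit} or its \code{usual} data frame.
#' @param ears An \code{\link{ear_table}}.
#' @param level Confidence level for the Wald intervals.
#' @return A data frame of class \code{adequacy_result}, one row per
#'   nutrient: \code{nutrient, prevalence_pct, ci_lower_pct, ci_upper_pct,
#'   n, weighted}.
#' @export
adequacy_assessment <- function(usual, ears = ear_table(), level = 0.95) {
  u <- if (inherits(usual, "usual_intake_fit")) usual$usual else usual
  w <- u$survey_weight %||% rep(1, nrow(u))
  rows <- list()
  pr <- prevalence(inadequacy_probability(u$protein_g_per_kg,
                                          ears$protein_ear_g_per_kg, ears$cv),
                   w, level, nutrient = "protein")
  rows[["protein"]] <- as.data.frame(unclass(pr), stringsAsFactors = FALSE)
  for (k in IAA_KEYS) {
    pk <- prevalence(inadequacy_probability(u[[paste0("iaa_", k, "_mg_per_kg")]],
                                            ears$iaa_ear_mg_per_kg[[k]],
                                            ears$cv),
                     w, level, nutrient = k)
    rows[[k]] <- as.data.frame(unclass(pk), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("adequacy_result", "data.frame")
  out
}

#' @export
print.adequacy_result <- function(x, ...) {
  cat("Prevalence of inadequacy (probability approach)\n")
  df <- as.data.frame(x)
  df$prevalence_pct <- sprintf("%.3f", df$prevalence_pct)
  df$ci <- sprintf("(%.2f; %.2f)", x$ci_lower_pct, x$ci_upper_pct)
  print(df[, c("nutrient", "prevalence_pct", "ci", "n")], row.names = FALSE)
  invisible(x)
}
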