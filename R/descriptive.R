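## Descriptive surfaces: food-group contribution tables and intake versus
## plant-share regressions.

weighted_sd <- function(x, w) {
  m <- stats::weighted.mean(x, w)
  sqrt(stats::weighted.mean((x - m)^2, w))
}

#' Food-group contributions to protein and lysine intake
#'
#' For each individual, the percentage contribution of every food group to
#' penalised protein intake and to lysine intake (the groups sum to 100% per
#' individual), then survey-weighted mean and SD by sex. Animal and plant
#' super-rows are the sums of their member groups; a mixed dish contributes
#' to the group it is assigned to.
#'
#' @param records Day-level consumption records.
#' @param composition A \code{composition_table}.
#' @param individuals Individuals data frame (sex and survey weights).
#' @param policy A \code{\link{digestibility_policy}}.
#' @return A data frame of class \code{contribution_table}: one row per
#'   (group, sex) with \code{protein_pct_mean, protein_pct_sd,
#'   lysine_pct_mean, lysine_pct_sd}; includes \code{animal} and
#'   \code{plant} super-rows.
#' @export
contribution_table <- function(records, composition, individuals,
                               policy = digestibility_policy()) {
  individuals <- validate_individuals(individuals)
  records <- validate_records(records, individuals, composition)
  cache <- comp_cache(composition, policy)
  fidx <- match(records$food_id, composition$food_id)
  lys_col <- match("lys", IAA_KEYS)
  prot <- records$grams * cache$protein_pen[fidx]
  lys <- records$grams * cache$iaa_pen[fidx, lys_col]
  grp <- cache$group[fidx]

  groups <- FOOD_GROUPS
  n <- nrow(individuals)
  agg <- function(v) {
    m <- matrix(0, nrow = n, ncol = length(groups),
                dimnames = list(individuals$individual_id, groups))
    t1 <- tapply(v, list(records$individual_id, grp), sum)
    t1[is.na(t1)] <- 0
    m[rownames(t1), colnames(t1)] <- t1
    sh <- m / rowSums(m) * 100
    cbind(sh, animal = rowSums(sh[, ANIMAL_GROUPS, drop = FALSE]),
          plant = rowSums(sh[, PLANT_GROUPS, drop = FALSE]))
  }
  psh <- agg(prot)
  lsh <- agg(lys)

  out <- list()
  for (sx in c("male", "female")) {
    sel <- individuals$sex == sx
    if (!any(sel)) next
    w <- individuals$survey_weight[sel]
    for (g in colnames(psh)) {
      out[[paste(g, sx)]] <- data.frame(
        group = g, sex = sx,
        protein_pct_mean = stats::weighted.mean(psh[sel, g], w),
        protein_pct_sd = weighted_sd(psh[sel, g], w),
        lysine_pct_mean = stats::weighted.mean(lsh[sel, g], w),
        lysine_pct_sd = weighted_sd(lsh[sel, g], w),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("contribution_table", "data.frame")
  res
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("Food-group contributions (% of intake, weighted mean +/- SD)\n")
  df <- as.data.frame(x)
  df$protein <- sprintf("%.1f +/- %.1f", df$protein_pct_mean,
                        df$protein_pct_sd)
  df$lysine <- sprintf("%.1f +/- %.1f", df$lysine_pct_mean, df$lysine_pct_sd)
  print(df[, c("group", "sex", "protein", "lysine")], row.names = FALSE)
  invisible(x)
}

#' Association between intake adequacy and plant-protein share
#'
#' Ordinary least squares of the usual intake:EAR ratio of a nutrient on the
#' individual plant-protein share (percent of total protein). The adjusted
#' variant adds age, sex, BMI (weight / height in metres squared) and usual
#' non-alcohol energy intake as covariates. Slopes are reported per
#' percentage point and per 10 percentage points of plant share.
#'
#' @param usual A \code{usual_intake_fit} or its \code{usual} data frame.
#' @param individuals Individuals data frame.
#' @param outcome \code{"protein"} or one of the nine amino acid keys.
#' @param ears An \code{\link{ear_table}}.
#' @param adjusted Add the age/sex/BMI/energy covariates?
#' @return An object of class \code{association_regression} with the slope
#'   (per 1 and per 10 percentage points of plant share), intercept,
#'   R-squared, the full \code{lm} fit, and the coefficient table.
#' @export
association_regression <- function(usual, individuals,
                                   outcome = "protein",
                                   ears = ear_table(), adjusted = FALSE) {
  u <- if (inherits(usual, "usual_intake_fit")) usual$usual else usual
  if (nrow(u) < 10) stop("need at least 10 individuals", call. = FALSE)
  individuals <- validate_individuals(individuals)
  mi <- match(u$individual_id, individuals$individual_id)
  ear <- if (outcome == "protein") ears$protein_ear_g_per_kg
         else ears$iaa_ear_mg_per_kg[[outcome]]
  ycol <- if (outcome == "protein") "protein_g_per_kg"
          else paste0("iaa_", outcome, "_mg_per_kg")
  if (is.null(u[[ycol]])) stop("unknown outcome: ", outcome, call. = FALSE)
  df <- data.frame(
    ratio = u[[ycol]] / ear,
    plant_share_pct = 100 * u$plant_protein_g /
      (u$plant_protein_g + u$animal_protein_g),
    age_y = individuals$age_y[mi],
    sex = factor(individuals$sex[mi], levels = c("female", "male")),
    bmi = individuals$weight_kg[mi] / (individuals$height_cm[mi] / 100)^2,
    energy_kcal = u$energy_kcal_noalc)
  fml <- if (adjusted)
    ratio ~ plant_share_pct + age_y + sex + bmi + energy_kcal
  else ratio ~ plant_share_pct
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit)))
    stop("degenerate (collinear) regression input", call. = FALSE)
  sm <- summary(fit)
  structure(list(outcome = outcome, adjusted = adjusted,
                 slope_per_pct = unname(stats::coef(fit)["plant_share_pct"]),
                 slope_per_10pct = 10 * unname(
                   stats::coef(fit)["plant_share_pct"]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 coefficients = sm$coefficients,
                 model = fit),
            class = "association_regression")
}

#' @export
print.association_regression <- function(x, ...) {
  cat(sprintf("OLS: usual %s intake:EAR ratio ~ plant protein share%s\n",
              x$outcome,
              if (x$adjusted) " (adjusted for age, sex, BMI, energy)" else ""))
  cat(sprintf("  slope: %+.4f of EAR per 10 points of plant share; R2 = %.3f\n",
              x$slope_per_10pct, x$r_squared))
  invisible(x)
}
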