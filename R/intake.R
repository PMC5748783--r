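## Intake engine: food records -> daily nutrients -> usual intakes.
##
## Plant-sourced protein (and hence plant-sourced amino acids) carries a
## multiplicative digestibility penalty before any intake or adequacy
## quantity is computed. Usual intakes are estimated by a simplified
## Multiple-Source-Method core: Box-Cox transform, one-way variance
## decomposition, best-linear-unbiased-predictor shrinkage of individual
## means toward the population mean, and a bias-corrected back-transform.
## The full MSM covariate regression and consumption-probability model are
## omitted: protein and amino acids are consumed every day, so there is no
## episodic component to model.

#' Digestibility policy for plant protein
#'
#' Multiplicative coefficient applied to plant-sourced protein, and therefore
#' to plant-sourced amino acids, before intakes are computed. The default
#' 0.95 encodes the 5% lower real ileal digestibility of plant relative to
#' animal protein.
#'
#' @param plant_penalty Coefficient in (0, 1] (default 0.95).
#' @return A list of class \code{digestibility_policy}.
#' @export
digestibility_policy <- function(plant_penalty = 0.95) {
  stopifnot(plant_penalty > 0, plant_penalty <= 1)
  structure(list(plant_penalty = plant_penalty),
            class = "digestibility_policy")
}

## Precomputed per-food coefficient vectors for fast pattern -> nutrient
## algebra; aligned with the composition table's row order.
comp_cache <- function(composition, policy) {
  pen <- policy$plant_penalty
  af <- composition$animal_protein_fraction
  p <- composition$protein_g_per_100g / 100
  iaa <- as.matrix(composition[iaa_cols()])
  list(food_id = composition$food_id,
       group = composition$group,
       protein_raw = p,                      # g protein per g food, pre-penalty
       animal = p * af,
       plant_pen = p * (1 - af) * pen,
       protein_pen = p * (af + (1 - af) * pen),
       energy = composition$energy_kcal_per_100g / 100,
       alcohol = composition$alcohol_kcal_per_100g / 100,
       ## mg IAA per g food, penalty applied to the plant part
       iaa_pen = iaa * (p * (af + (1 - af) * pen)),
       af = af,
       substitutable = composition$substitutable,
       pen = pen)
}

## Nutrients for a grams matrix (individuals x foods), columns in
## composition order. Returns a list of vectors/matrix.
pattern_nutrients <- function(M, cache) {
  list(protein_g = as.vector(M %*% cache$protein_pen),
       animal_protein_g = as.vector(M %*% cache$animal),
       plant_protein_g = as.vector(M %*% cache$plant_pen),
       protein_raw_g = as.vector(M %*% cache$protein_raw),
       energy_kcal_noalc = as.vector(M %*% cache$energy),
       alcohol_kcal = as.vector(M %*% cache$alcohol),
       iaa_mg = M %*% cache$iaa_pen)
}

#' Daily nutrient intake from one day of consumptions
#'
#' Converts a list of (food, grams) consumptions into a
#' \code{\link{nutrient_vector}}: protein split into animal and plant parts
#' by each food's \code{animal_protein_fraction}, the plant part (protein and
#' amino acids alike) multiplied by the digestibility penalty, amino acid
#' intakes computed from each food's profile in mg per g protein, and energy
#' summed separately for non-alcohol and alcohol calories.
#'
#' The function is linear in grams: doubling every consumption doubles every
#' field.
#'
#' @param consumptions Data frame with columns \code{food_id} and
#'   \code{grams} (one individual-day).
#' @param composition A \code{composition_table}.
#' @param policy A \code{\link{digestibility_policy}}.
#' @return A \code{nutrient_vector}.
#' @export
daily_nutrients <- function(consumptions, composition,
                            policy = digestibility_policy()) {
  idx <- match(consumptions$food_id, composition$food_id)
  if (anyNA(idx))
    stop("unresolvable food_id: ",
         paste(unique(consumptions$food_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  if (any(consumptions$grams < 0))
    stop("negative grams in consumptions", call. = FALSE)
  cache <- comp_cache(composition, policy)
  M <- matrix(0, nrow = 1, ncol = nrow(composition))
  for (k in seq_along(idx)) M[1, idx[k]] <- M[1, idx[k]] + consumptions$grams[k]
  nut <- pattern_nutrients(M, cache)
  nutrient_vector(protein_g = nut$protein_g,
                  animal_protein_g = nut$animal_protein_g,
                  plant_protein_g = nut$plant_protein_g,
                  energy_kcal_noalc = nut$energy_kcal_noalc,
                  alcohol_kcal = nut$alcohol_kcal,
                  iaa_mg = stats::setNames(as.vector(nut$iaa_mg), IAA_KEYS))
}

## Per-individual mean daily grams matrix (individuals x foods in
## composition row order), averaging over each individual's recorded days.
mean_daily_pattern <- function(individuals, records, composition) {
  fidx <- match(records$food_id, composition$food_id)
  if (anyNA(fidx))
    stop("unresolvable food_id in records", call. = FALSE)
  iidx <- match(records$individual_id, individuals$individual_id)
  n <- nrow(individuals)
  D <- tapply(records$day_index, records$individual_id,
              function(d) length(unique(d)))
  D <- as.numeric(D[individuals$individual_id])
  M <- matrix(0, nrow = n, ncol = nrow(composition),
              dimnames = list(individuals$individual_id, composition$food_id))
  tot <- rowsum(records$grams, group = (iidx - 1) * nrow(composition) + fidx)
  cells <- as.integer(rownames(tot))
  M[cbind((cells - 1) %/% nrow(composition) + 1,
          (cells - 1) %% nrow(composition) + 1)] <- tot[, 1]
  list(M = M / D, n_days = D)
}

## Per individual-day nutrient table, one row per (individual, day).
daily_nutrient_table <- function(individuals, records, composition, policy) {
  cache <- comp_cache(composition, policy)
  fidx <- match(records$food_id, composition$food_id)
  if (anyNA(fidx)) stop("unresolvable food_id in records", call. = FALSE)
  key <- paste(records$individual_id, records$day_index, sep = "\r")
  g <- records$grams
  out <- data.frame(
    protein_g = rowsum(g * cache$protein_pen[fidx], key)[, 1],
    animal_protein_g = rowsum(g * cache$animal[fidx], key)[, 1],
    plant_protein_g = rowsum(g * cache$plant_pen[fidx], key)[, 1],
    energy_kcal_noalc = rowsum(g * cache$energy[fidx], key)[, 1],
    alcohol_kcal = rowsum(g * cache$alcohol[fidx], key)[, 1])
  for (k in seq_along(IAA_KEYS))
    out[[paste0("iaa_", IAA_KEYS[k], "_mg")]] <-
      rowsum(g * cache$iaa_pen[fidx, k], key)[, 1]
  parts <- strsplit(rownames(out), "\r", fixed = TRUE)
  out$individual_id <- vapply(parts, `[`, "", 1)
  out$day_index <- as.integer(vapply(parts, `[`, "", 2))
  rownames(out) <- NULL
  out
}

## ---- Box-Cox helpers -------------------------------------------------------

box_cox <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

inv_box_cox <- function(z, lambda) {
  if (abs(lambda) < 1e-12) exp(z) else pmax(lambda * z + 1, 1e-12)^(1 / lambda)
}

## Second derivative of the inverse Box-Cox, for the half-variance
## back-transform bias correction E[g^-1(t + w)] ~ g^-1(t) + 0.5 var(w) g^-1''(t).
inv_box_cox_d2 <- function(z, lambda) {
  if (abs(lambda) < 1e-12) exp(z)
  else (1 - lambda) * pmax(lambda * z + 1, 1e-12)^(1 / lambda - 2)
}

## Profile log-likelihood grid search over [-1, 2] step 0.1; ties broken
## toward lambda = 1.
fit_box_cox_lambda <- function(y, grid = seq(-1, 2, by = 0.1)) {
  n <- length(y)
  slog <- sum(log(y))
  ll <- vapply(grid, function(l) {
    z <- box_cox(y, l)
    -n / 2 * log(mean((z - mean(z))^2)) + (l - 1) * slog
  }, numeric(1))
  best <- max(ll)
  cand <- grid[ll >= best - 1e-8]
  cand[which.min(abs(cand - 1))]
}

## One-way random-effects decomposition (method of moments, unbalanced) and
## BLUP shrinkage on the transformed scale for a single nutrient.
shrink_nutrient <- function(value, id, lambda = NULL) {
  ids <- unique(id)
  if (any(value <= 0)) {
    warning("non-positive daily values; returning individual means untransformed")
    m <- tapply(value, id, mean)[ids]
    return(list(usual = as.numeric(m), ids = ids, lambda = NA_real_,
                sigma2_b = NA_real_, sigma2_w = NA_real_, degenerate = TRUE))
  }
  if (is.null(lambda)) lambda <- fit_box_cox_lambda(value)
  z <- box_cox(value, lambda)
  zi <- tapply(z, id, mean)[ids]
  Di <- tapply(z, id, length)[ids]
  k <- length(ids); N <- length(z)
  if (stats::var(z) < 1e-14 || k < 2) {
    warning("zero variance across individuals; returning individual means")
    return(list(usual = inv_box_cox(as.numeric(zi), lambda), ids = ids,
                lambda = lambda, sigma2_b = 0, sigma2_w = 0,
                degenerate = TRUE))
  }
  grand <- mean(z)
  ssw <- sum((z - zi[match(id, ids)])^2)
  ssb <- sum(Di * (zi - grand)^2)
  msw <- ssw / (N - k)
  msb <- ssb / (k - 1)
  n0 <- (N - sum(Di^2) / N) / (k - 1)
  s2w <- msw
  s2b <- max((msb - msw) / n0, 0)
  shrink <- if (s2b + s2w == 0) rep(1, k) else s2b / (s2b + s2w / Di)
  t_usual <- grand + (zi - grand) * shrink
  usual <- inv_box_cox(as.numeric(t_usual), lambda) +
    0.5 * s2w * inv_box_cox_d2(as.numeric(t_usual), lambda)
  list(usual = pmax(usual, 0), ids = ids, lambda = lambda,
       sigma2_b = s2b, sigma2_w = s2w, degenerate = FALSE)
}

#' Estimate usual nutrient intakes from repeated daily records
#'
#' Fits, per nutrient, a simplified Multiple-Source-Method estimator to the
#' daily intakes: (1) a Box-Cox transform with the power fitted once on the
#' pooled daily values (grid search over \eqn{[-1, 2]} in steps of 0.1,
#' maximising the normal profile log-likelihood, ties broken toward 1);
#' (2) a one-way method-of-moments decomposition into between-person
#' (\eqn{\sigma^2_b}) and within-person (\eqn{\sigma^2_w}) variance;
#' (3) shrinkage of each individual's transformed mean toward the population
#' mean by the best-linear-unbiased-predictor factor
#' \eqn{\sigma^2_b / (\sigma^2_b + \sigma^2_w / D_i)} where \eqn{D_i} is the
#' individual's number of recorded days; (4) back-transform with a
#' second-order (half-variance) bias correction,
#' \eqn{g^{-1}(t) + \sigma^2_w g^{-1}''(t) / 2}.
#'
#' Usual intakes are reported per kg body weight for protein (g/kg/day) and
#' each indispensable amino acid (mg/kg/day), and per day for non-alcohol
#' energy and the plant/animal protein components. The estimator is
#' deterministic given the data. If the daily values have zero variance the
#' individual means are returned with a warning.
#'
#' @param individuals Individuals data frame (weights and body weights used).
#' @param records Day-level consumption records; every individual needs at
#'   least 2 days for the variance decomposition.
#' @param composition A \code{composition_table}.
#' @param policy A \code{\link{digestibility_policy}}.
#' @param lambda Optional fixed Box-Cox power applied to every nutrient
#'   (bypasses the grid search); \code{NULL} fits per nutrient.
#' @return An object of class \code{usual_intake_fit} with components
#'   \code{usual} (data frame of per-individual usual intakes),
#'   \code{components} (per-nutrient Box-Cox power and variance components on
#'   the transformed scale) and \code{n_days}.
#' @export
usual_intakes <- function(individuals, records, composition,
                          policy = digestibility_policy(), lambda = NULL) {
  individuals <- validate_individuals(individuals)
  records <- validate_records(records, individuals, composition)
  daily <- daily_nutrient_table(individuals, records, composition, policy)
  wkg <- individuals$weight_kg[match(daily$individual_id,
                                     individuals$individual_id)]
  Dn <- tapply(daily$day_index, daily$individual_id, length)
  if (any(Dn < 2))
    stop("every individual needs at least 2 recorded days", call. = FALSE)

  nutrients <- c(protein_g_per_kg = NA, energy_kcal_noalc = NA,
                 plant_protein_g = NA, animal_protein_g = NA)
  values <- list(protein_g_per_kg = daily$protein_g / wkg,
                 energy_kcal_noalc = daily$energy_kcal_noalc,
                 plant_protein_g = daily$plant_protein_g,
                 animal_protein_g = daily$animal_protein_g)
  for (k in IAA_KEYS)
    values[[paste0("iaa_", k, "_mg_per_kg")]] <-
      daily[[paste0("iaa_", k, "_mg")]] / wkg

  ids <- unique(daily$individual_id)
  usual <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  comp_rows <- list()
  for (nm in names(values)) {
    fit <- shrink_nutrient(values[[nm]], daily$individual_id, lambda = lambda)
    usual[[nm]] <- fit$usual[match(ids, fit$ids)]
    comp_rows[[nm]] <- data.frame(nutrient = nm, lambda = fit$lambda,
                                  sigma2_b = fit$sigma2_b,
                                  sigma2_w = fit$sigma2_w,
                                  degenerate = fit$degenerate)
  }
  mi <- match(ids, individuals$individual_id)
  usual$weight_kg <- individuals$weight_kg[mi]
  usual$survey_weight <- individuals$survey_weight[mi]
  structure(list(usual = usual,
                 components = do.call(rbind, c(comp_rows,
                                               make.row.names = FALSE)),
                 n_days = as.numeric(Dn[ids]),
                 policy = policy,
                 call = match.call()),
            class = "usual_intake_fit")
}

#' @export
print.usual_intake_fit <- function(x, ...) {
  cat(sprintf("Usual intake fit: %d individuals, %s days each\n",
              nrow(x$usual),
              paste(range(x$n_days), collapse = "-")))
  cat(sprintf("  mean usual protein: %.3f g/kg/day\n",
              mean(x$usual$protein_g_per_kg)))
  cat("  variance components (transformed scale):\n")
  print(x$components[, c("nutrient", "lambda", "sigma2_b", "sigma2_w")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.usual_intake_fit <- function(object, ...) {
  u <- object$usual
  qs <- t(vapply(setdiff(names(u), c("individual_id", "weight_kg",
                                     "survey_weight")),
                 function(nm) stats::quantile(u[[nm]],
                                              c(0.025, 0.25, 0.5, 0.75, 0.975)),
                 numeric(5)))
  structure(list(quantiles = qs, components = object$components,
                 n = nrow(u)), class = "summary.usual_intake_fit")
}

#' @export
print.summary.usual_intake_fit <- function(x, ...) {
  cat(sprintf("Usual intakes, n = %d\n", x$n))
  print(round(x$quantiles, 4))
  invisible(x)
}

#' @export
coef.usual_intake_fit <- function(object, ...) object$components

#' @export
fitted.usual_intake_fit <- function(object, ...) object$usual

#' @export
as.data.frame.usual_intake_fit <- function(x, ...) x$usual
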