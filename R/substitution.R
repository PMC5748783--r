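## Graded substitution of animal protein by plant protein.
##
## Model P removes a fraction s of each individual's substitutable animal
## protein and adds the same amount of (pre-penalty) protein from the plant
## foods the individual already consumes, scaled so the proportion of
## protein from each plant food is kept constant; total protein is conserved
## exactly. Models A, B and intermediates C replace the removed non-alcohol
## energy instead: Model A scales the individual's own plant foods on their
## energy pattern, Model B adds a population-level mix of legumes, nuts and
## seeds (LNS), Model C splits the replaced energy lambda : (1 - lambda)
## between the LNS mix and the Model-A pattern; non-alcohol energy is
## conserved exactly. In every model the removal scales each substitutable
## animal food by (1 - s), so the proportion of protein from each animal
## food within total animal protein is kept constant, and embedded animal
## protein in non-substitutable mixed dishes is untouched.

#' Specification of a substitution model
#'
#' @param kind \code{"P"} (protein-conserving), \code{"A"} (energy-conserving,
#'   own plant pattern), \code{"B"} (energy-conserving, LNS mix) or
#'   \code{"C"} (energy-conserving, LNS fraction \code{lns_fraction}).
#' @param lns_fraction Fraction lambda in [0, 1] of the substituting energy
#'   supplied by the LNS mix; forced to 0 for Model A and 1 for Model B and
#'   required for Model C (0.2 gives the model usually labelled C_20).
#' @param s_grid Sorted substitution fractions in [0, 1]; must contain 0.
#' @param policy A \code{\link{digestibility_policy}} applied to all plant
#'   protein, including the added foods.
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(kind = c("A", "B", "P", "C"), lns_fraction = NULL,
                       s_grid = seq(0, 1, by = 0.02),
                       policy = digestibility_policy()) {
  kind <- match.arg(kind)
  if (kind == "A") lns_fraction <- 0
  if (kind == "B") lns_fraction <- 1
  if (kind == "P") lns_fraction <- NA_real_
  if (kind == "C") {
    if (is.null(lns_fraction) || is.na(lns_fraction) ||
        lns_fraction < 0 || lns_fraction > 1)
      stop("Model C requires lns_fraction in [0, 1]", call. = FALSE)
  }
  s_grid <- as.numeric(s_grid)
  if (is.unsorted(s_grid, strictly = TRUE) || any(s_grid < 0) ||
      any(s_grid > 1) || !any(s_grid == 0))
    stop("s_grid must be strictly sorted within [0, 1] and contain 0",
         call. = FALSE)
  label <- switch(kind, P = "P", A = "A", B = "B",
                  C = sprintf("C_%d", round(100 * lns_fraction)))
  structure(list(kind = kind, lns_fraction = lns_fraction, s_grid = s_grid,
                 policy = policy, label = label),
            class = "model_spec")
}

#' Observed mix of legumes, nuts and seeds
#'
#' Per-food shares over the foods in the legumes and nuts-seeds groups,
#' proportional to the observed population-total intake on the chosen basis
#' (non-alcohol energy by default, the substitution currency of the
#' energy-conserving models; switchable to protein).
#'
#' @param records Day-level consumption records of the population.
#' @param composition A \code{composition_table}.
#' @param basis \code{"energy"} (default) or \code{"protein"}.
#' @return A data frame of class \code{lns_mix} with columns \code{food_id}
#'   and \code{share} (non-negative, summing to 1).
#' @export
build_lns_mix <- function(records, composition,
                          basis = c("energy", "protein")) {
  basis <- match.arg(basis)
  lns_ids <- composition$food_id[composition$group %in% LNS_GROUPS]
  rec <- records[records$food_id %in% lns_ids, , drop = FALSE]
  if (nrow(rec) == 0 || sum(rec$grams) == 0)
    stop("no legumes/nuts-seeds consumption observed; supply a default mix",
         call. = FALSE)
  tot <- tapply(rec$grams, rec$food_id, sum)
  idx <- match(names(tot), composition$food_id)
  dens <- if (basis == "energy") composition$energy_kcal_per_100g[idx] / 100
          else composition$protein_g_per_100g[idx] / 100
  amount <- as.numeric(tot) * dens
  out <- data.frame(food_id = names(tot), share = amount / sum(amount),
                    stringsAsFactors = FALSE)
  out <- out[out$share > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "basis") <- basis
  class(out) <- c("lns_mix", "data.frame")
  out
}

## LNS shares as a vector aligned with composition rows.
lns_share_vector <- function(lns_mix, composition) {
  v <- numeric(nrow(composition))
  idx <- match(lns_mix$food_id, composition$food_id)
  if (anyNA(idx)) stop("lns_mix references unknown food_id", call. = FALSE)
  v[idx] <- lns_mix$share
  if (abs(sum(v) - 1) > 1e-12)
    stop("lns_mix shares must sum to 1", call. = FALSE)
  v
}

## Core substitution on a grams matrix (individuals x foods, composition row
## order). Returns the modified matrix.
subst_patterns <- function(M, cache, kind, lambda, s, lns_shares = NULL,
                           ids = NULL) {
  if (s == 0) return(M)
  rem <- cache$af > 0 & cache$substitutable
  pp <- cache$af == 0
  out <- M
  out[, rem] <- M[, rem, drop = FALSE] * (1 - s)
  if (kind == "P") {
    Q <- s * as.vector(M[, rem, drop = FALSE] %*% cache$protein_raw[rem])
    base <- as.vector(M[, pp, drop = FALSE] %*% cache$protein_raw[pp])
    bad <- Q > 0 & base <= 0
    if (any(bad))
      stop("individual(s) with no plant protein pattern to scale (",
           paste(utils::head(if (is.null(ids)) which(bad) else ids[bad], 5),
                 collapse = ", "),
           "); use an energy-conserving model with lns_fraction > 0",
           call. = FALSE)
    fac <- ifelse(base > 0, Q / base, 0)
    out[, pp] <- out[, pp, drop = FALSE] * (1 + fac)
  } else {
    Q <- s * as.vector(M[, rem, drop = FALSE] %*% cache$energy[rem])
    if (lambda < 1) {
      base <- as.vector(M[, pp, drop = FALSE] %*% cache$energy[pp])
      bad <- Q > 0 & base <= 0
      if (any(bad))
        stop("individual(s) with no plant energy pattern to scale (",
             paste(utils::head(if (is.null(ids)) which(bad) else ids[bad], 5),
                   collapse = ", "),
             "); use lns_fraction > 0", call. = FALSE)
      fac <- ifelse(base > 0, (1 - lambda) * Q / base, 0)
      out[, pp] <- out[, pp, drop = FALSE] * (1 + fac)
    }
    if (lambda > 0) {
      if (is.null(lns_shares))
        stop("LNS mix required for models B and C", call. = FALSE)
      jj <- which(lns_shares > 0)
      for (j in jj)
        out[, j] <- out[, j] + lambda * Q * lns_shares[j] / cache$energy[j]
    }
  }
  out
}

#' Substitute animal protein in one individual's daily food pattern
#'
#' Applies one substitution step: removes the fraction \code{s} of the
#' individual's substitutable animal protein by scaling each substitutable
#' animal food's grams by \code{1 - s}, then adds plant foods carrying the
#' removed quantity (protein for Model P, non-alcohol energy for Models
#' A/B/C) according to the model's addition rule. The digestibility penalty
#' applies to the added plant protein as everywhere else.
#'
#' @param pattern Named numeric vector of mean daily grams by \code{food_id}.
#' @param composition A \code{composition_table}.
#' @param model A \code{\link{model_spec}}.
#' @param s Substitution fraction in [0, 1].
#' @param lns_mix An \code{\link{build_lns_mix}} result (required when the
#'   model draws on the LNS mix).
#' @return A list with \code{pattern} (modified named grams vector),
#'   \code{nutrients} (the \code{\link{nutrient_vector}} of the modified
#'   pattern) and \code{delta} (named list of nutrient changes relative to
#'   the unmodified pattern).
#' @export
substitute_individual <- function(pattern, composition, model, s,
                                  lns_mix = NULL) {
  stopifnot(s >= 0, s <= 1, inherits(model, "model_spec"))
  idx <- match(names(pattern), composition$food_id)
  if (anyNA(idx))
    stop("pattern references unknown food_id: ",
         paste(names(pattern)[is.na(idx)], collapse = ", "), call. = FALSE)
  cache <- comp_cache(composition, model$policy)
  M <- matrix(0, nrow = 1, ncol = nrow(composition))
  M[1, idx] <- pattern
  lns_shares <- if (!is.null(lns_mix)) lns_share_vector(lns_mix, composition)
  M2 <- subst_patterns(M, cache, model$kind, model$lns_fraction, s,
                       lns_shares)
  n0 <- pattern_nutrients(M, cache)
  n1 <- pattern_nutrients(M2, cache)
  nv <- nutrient_vector(protein_g = n1$protein_g,
                        animal_protein_g = n1$animal_protein_g,
                        plant_protein_g = n1$plant_protein_g,
                        energy_kcal_noalc = n1$energy_kcal_noalc,
                        alcohol_kcal = n1$alcohol_kcal,
                        iaa_mg = stats::setNames(as.vector(n1$iaa_mg),
                                                 IAA_KEYS))
  delta <- list(protein_g = n1$protein_g - n0$protein_g,
                protein_raw_g = n1$protein_raw_g - n0$protein_raw_g,
                animal_protein_g = n1$animal_protein_g - n0$animal_protein_g,
                plant_protein_g = n1$plant_protein_g - n0$plant_protein_g,
                energy_kcal_noalc = n1$energy_kcal_noalc - n0$energy_kcal_noalc,
                iaa_mg = stats::setNames(as.vector(n1$iaa_mg - n0$iaa_mg),
                                         IAA_KEYS))
  out_pattern <- stats::setNames(as.vector(M2), composition$food_id)
  list(pattern = out_pattern[out_pattern > 0], nutrients = nv, delta = delta)
}

#' Simulate a substitution curve over the model's grid
#'
#' For every substitution fraction \code{s} in the model's grid, applies
#' \code{\link{substitute_individual}}'s rule to every individual's mean
#' daily food pattern, shifts each individual's usual nutrient intakes by
#' the resulting deterministic per-kg delta (the substitution changes an
#' individual's mean, not their day-to-day variability), recomputes
#' inadequacy probabilities and survey-weighted prevalence for protein and
#' all nine amino acids, and records the weighted mean plant-protein share
#' and mean non-alcohol energy intake.
#'
#' @param individuals Screened individuals data frame.
#' @param records Their day-level records.
#' @param usual A \code{usual_intake_fit} for the same individuals.
#' @param model A \code{\link{model_spec}}.
#' @param composition A \code{composition_table}.
#' @param ears An \code{\link{ear_table}}.
#' @param lns_mix Optional \code{lns_mix}; built from \code{records} when the
#'   model needs it and none is supplied.
#' @return A data frame of class \code{substitution_curve}, one row per
#'   \code{s}, with the mean plant-protein share (percent of total protein),
#'   mean energy, and prevalence with Wald CI per nutrient
#'   (\code{prev_*, lo_*, hi_*} columns).
#' @export
simulate_curve <- function(individuals, records, usual, model, composition,
                           ears = ear_table(), lns_mix = NULL) {
  stopifnot(inherits(model, "model_spec"))
  individuals <- validate_individuals(individuals)
  u <- if (inherits(usual, "usual_intake_fit")) usual$usual else usual
  mi <- match(individuals$individual_id, u$individual_id)
  if (anyNA(mi))
    stop("usual intakes missing for some individuals", call. = FALSE)
  u <- u[mi, , drop = FALSE]
  needs_lns <- model$kind %in% c("B", "C") && model$lns_fraction > 0
  if (needs_lns && is.null(lns_mix))
    lns_mix <- build_lns_mix(records, composition)
  lns_shares <- if (!is.null(lns_mix)) lns_share_vector(lns_mix, composition)
  cache <- comp_cache(composition, model$policy)
  mp <- mean_daily_pattern(individuals, records, composition)
  M <- mp$M
  n0 <- pattern_nutrients(M, cache)
  wkg <- individuals$weight_kg
  w <- individuals$survey_weight
  nutrients <- c("protein", IAA_KEYS)

  rows <- lapply(model$s_grid, function(s) {
    M2 <- subst_patterns(M, cache, model$kind, model$lns_fraction, s,
                         lns_shares, ids = individuals$individual_id)
    nut <- pattern_nutrients(M2, cache)
    row <- list(model = model$label, lns_fraction = model$lns_fraction,
                s = s,
                plant_share_pct = 100 * stats::weighted.mean(
                  nut$plant_protein_g / nut$protein_g, w),
                energy_kcal_mean = stats::weighted.mean(nut$energy_kcal_noalc,
                                                        w))
    y <- pmax(u$protein_g_per_kg +
                (nut$protein_g - n0$protein_g) / wkg, 0)
    pr <- prevalence(inadequacy_probability(y, ears$protein_ear_g_per_kg,
                                            ears$cv), w)
    row[["prev_protein"]] <- pr$prevalence_pct
    row[["lo_protein"]] <- pr$ci_lower_pct
    row[["hi_protein"]] <- pr$ci_upper_pct
    for (k in seq_along(IAA_KEYS)) {
      key <- IAA_KEYS[k]
      yk <- pmax(u[[paste0("iaa_", key, "_mg_per_kg")]] +
                   (nut$iaa_mg[, k] - n0$iaa_mg[, k]) / wkg, 0)
      pk <- prevalence(inadequacy_probability(yk, ears$iaa_ear_mg_per_kg[[key]],
                                              ears$cv), w)
      row[[paste0("prev_", key)]] <- pk$prevalence_pct
      row[[paste0("lo_", key)]] <- pk$ci_lower_pct
      row[[paste0("hi_", key)]] <- pk$ci_upper_pct
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "nutrients") <- nutrients
  attr(out, "model_kind") <- model$kind
  class(out) <- c("substitution_curve", "data.frame")
  out
}

#' Plant-protein share at which a prevalence level is crossed
#'
#' Linear interpolation of the (mean plant-protein share, prevalence) pairs
#' of a simulation curve: returns the share at which the given nutrient's
#' prevalence of inadequacy first crosses \code{level_pct} as the share
#' increases. A level attained exactly at a grid point returns that point's
#' share; a level never bracketed returns \code{NA} (absent), not an error.
#'
#' @param curve A \code{substitution_curve}.
#' @param nutrient \code{"protein"} or one of the nine amino acid keys.
#' @param level_pct Prevalence level in percent (e.g. 5).
#' @return Mean plant-protein share (percent) at the crossing, or \code{NA}.
#' @export
find_crossing <- function(curve, nutrient = "protein", level_pct = 5) {
  ycol <- paste0("prev_", nutrient)
  if (!ycol %in% names(curve)) stop("unknown nutrient: ", nutrient,
                                    call. = FALSE)
  x <- curve$plant_share_pct
  y <- curve[[ycol]]
  for (i in seq_along(y)) {
    if (y[i] == level_pct) return(x[i])
    if (i < length(y) && (y[i] - level_pct) * (y[i + 1] - level_pct) < 0) {
      f <- (level_pct - y[i]) / (y[i + 1] - y[i])
      return(x[i] + f * (x[i + 1] - x[i]))
    }
  }
  NA_real_
}

#' @export
print.substitution_curve <- function(x, ...) {
  cat(sprintf("Substitution curve, model %s: %d grid points, plant share %.1f%% -> %.1f%%\n",
              x$model[1], nrow(x), x$plant_share_pct[1],
              x$plant_share_pct[nrow(x)]))
  cat(sprintf("  protein inadequacy: %.3f%% -> %.3f%%; lysine: %.3f%% -> %.3f%%\n",
              x$prev_protein[1], x$prev_protein[nrow(x)],
              x$prev_lys[1], x$prev_lys[nrow(x)]))
  invisible(x)
}

#' Plot a substitution curve
#'
#' Prevalence of protein and lysine inadequacy against the mean
#' plant-protein share, with shaded Wald confidence bands.
#'
#' @param x A \code{substitution_curve}.
#' @param nutrients Nutrients to draw (default protein and lysine).
#' @param ... Passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.substitution_curve <- function(x, nutrients = c("protein", "lys"), ...) {
  cols <- c(protein = "#1f6fb4", lys = "#c0392b", his = "#7f8c8d",
            ile = "#7f8c8d", leu = "#7f8c8d", saa = "#7f8c8d",
            aaa = "#7f8c8d", thr = "#7f8c8d", trp = "#7f8c8d",
            val = "#7f8c8d")
  graphics::plot(NA, xlim = range(x$plant_share_pct), ylim = c(0, 100),
                 xlab = "Mean plant protein (% of total protein)",
                 ylab = "Prevalence of inadequacy (%)",
                 main = sprintf("Substitution model %s", x$model[1]), ...)
  for (nm in nutrients) {
    cl <- if (nm %in% names(cols)) cols[[nm]] else "grey40"
    graphics::polygon(c(x$plant_share_pct, rev(x$plant_share_pct)),
                      c(x[[paste0("lo_", nm)]], rev(x[[paste0("hi_", nm)]])),
                      col = grDevices::adjustcolor(cl, 0.2), border = NA)
    graphics::lines(x$plant_share_pct, x[[paste0("prev_", nm)]], col = cl,
                    lwd = 2)
  }
  graphics::legend("topleft", legend = nutrients, col = cols[nutrients],
                   lwd = 2, bty = "n")
  invisible(x)
}
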