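## Synthetic dietary survey generator.
##
## Emulates the statistical structure of a national 7-day food-record survey
## of adults: population moments (mean protein intake per kg by sex, plant
## share of protein, cereal dominance within plant protein, meat dominance
## within animal protein), lognormal between- and within-person variation,
## anthropometry consistent with misreporter screening, and a small share of
## animal protein embedded in mixed dishes that substitution cannot remove.

#' Configuration of the synthetic survey
#'
#' Defaults reproduce the study conditions the package targets: 1678 adults
#' (717 men, 961 women) with 7-day records, mean protein intake 1.34 (men)
#' and 1.25 (women) g/kg body weight/day, 31% of protein from plants with
#' cereals contributing 67% of plant protein, meat contributing 59% (men) and
#' 51% (women) of animal protein, and 5% of animal protein locked in mixed
#' dishes and therefore non-substitutable.
#'
#' @param n_individuals Number of adults (default 1678).
#' @param sex_split Named counts \code{c(male=, female=)}; when
#'   \code{n_individuals} differs from their sum the split is rescaled
#'   proportionally.
#' @param n_days Recorded days per individual (default 7, minimum 2).
#' @param target_plant_share Mean fraction of (penalised) protein from plant
#'   sources (default 0.31).
#' @param target_protein_g_per_kg Named means \code{c(male=, female=)} of
#'   penalised protein intake, g/kg/day (defaults 1.34, 1.25).
#' @param cereal_share_of_plant Cereal fraction of plant protein (default 0.67).
#' @param meat_share_of_animal Named meat fractions of animal protein by sex
#'   (defaults 0.59 men, 0.51 women).
#' @param within_person_cv Day-to-day coefficient of variation of intake
#'   (lognormal, default 0.25).
#' @param between_person_cv Between-person CV of usual protein intake per kg
#'   (lognormal, default 0.20).
#' @param embedded_animal_fraction Fraction of animal protein embedded in
#'   mixed dishes, non-substitutable (default 0.05).
#' @param plant_share_sd Between-person SD of the individual plant share
#'   (default 0.06).
#' @return A validated list of class \code{survey_config}.
#' @export
survey_config <- function(n_individuals = 1678,
                          sex_split = c(male = 717, female = 961),
                          n_days = 7,
                          target_plant_share = 0.31,
                          target_protein_g_per_kg = c(male = 1.34,
                                                      female = 1.25),
                          cereal_share_of_plant = 0.67,
                          meat_share_of_animal = c(male = 0.59,
                                                   female = 0.51),
                          within_person_cv = 0.25,
                          between_person_cv = 0.20,
                          embedded_animal_fraction = 0.05,
                          plant_share_sd = 0.06) {
  stopifnot(n_individuals >= 1, n_days >= 2,
            target_plant_share > 0, target_plant_share < 1,
            cereal_share_of_plant > 0, cereal_share_of_plant < 1,
            all(meat_share_of_animal > 0), all(meat_share_of_animal < 1),
            within_person_cv >= 0, between_person_cv > 0,
            embedded_animal_fraction >= 0, embedded_animal_fraction < 1,
            all(target_protein_g_per_kg > 0), plant_share_sd > 0)
  if (sum(sex_split) != n_individuals) {
    n_male <- round(n_individuals * sex_split["male"] / sum(sex_split))
    sex_split <- c(male = unname(n_male),
                   female = n_individuals - unname(n_male))
  }
  structure(list(n_individuals = n_individuals, sex_split = sex_split,
                 n_days = n_days, target_plant_share = target_plant_share,
                 target_protein_g_per_kg = target_protein_g_per_kg,
                 cereal_share_of_plant = cereal_share_of_plant,
                 meat_share_of_animal = meat_share_of_animal,
                 within_person_cv = within_person_cv,
                 between_person_cv = between_person_cv,
                 embedded_animal_fraction = embedded_animal_fraction,
                 plant_share_sd = plant_share_sd),
            class = "survey_config")
}

#' Generate the synthetic food composition table
#'
#' Produces a 24-food table spanning every food group, with composition
#' anchored on well-known values: cereal items have a protein:energy ratio
#' near 15% of energy and lysine near 30 mg/g protein, red meat lysine near
#' 90 mg/g protein, legumes 25-30% protein as energy and lysine near
#' 70 mg/g protein. Animal foods carry \code{animal_protein_fraction = 1},
#' plant foods 0, and one mixed dish an intermediate fraction and
#' \code{substitutable = FALSE} (its animal protein is embedded). The table
#' is deterministic; \code{seed} is accepted for interface symmetry with the
#' other generators.
#'
#' @param config A \code{\link{survey_config}} (unused fields tolerated).
#' @param seed Ignored (the table is deterministic).
#' @return A \code{composition_table} of 24 foods.
#' @export
generate_composition <- function(config = survey_config(), seed = NULL) {
  f <- function(id, name, group, prot, kcal, alc, af, sub,
                his, ile, leu, lys, saa, aaa, thr, trp, val) {
    data.frame(food_id = id, name = name, group = group,
               protein_g_per_100g = prot, energy_kcal_per_100g = kcal,
               alcohol_kcal_per_100g = alc,
               iaa_his = his, iaa_ile = ile, iaa_leu = leu, iaa_lys = lys,
               iaa_saa = saa, iaa_aaa = aaa, iaa_thr = thr, iaa_trp = trp,
               iaa_val = val,
               animal_protein_fraction = af, substitutable = sub,
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    f("beef_steak", "Beef steak, grilled", "red_meat", 28.0, 150, 0, 1, TRUE,
      34, 47, 81, 90, 39, 77, 44, 12, 50),
    f("roast_chicken", "Chicken, roasted", "poultry", 26.5, 150, 0, 1, TRUE,
      30, 48, 76, 85, 40, 73, 43, 12, 49),
    f("venison", "Venison, cooked", "game", 22.0, 115, 0, 1, TRUE,
      34, 47, 81, 90, 39, 77, 44, 12, 50),
    f("veal_liver", "Veal liver, cooked", "offal", 24.0, 135, 0, 1, TRUE,
      27, 46, 86, 75, 38, 82, 42, 13, 57),
    f("cooked_ham", "Ham, cooked", "delicatessen", 21.0, 120, 0, 1, TRUE,
      40, 46, 78, 87, 38, 74, 43, 12, 50),
    f("salmon", "Salmon, baked", "fish", 25.0, 200, 0, 1, TRUE,
      29, 46, 81, 91, 41, 75, 44, 11, 51),
    f("semi_skimmed_milk", "Milk, semi-skimmed", "milk", 3.4, 46, 0, 1, TRUE,
      27, 49, 98, 79, 33, 101, 44, 14, 63),
    f("plain_yogurt", "Yogurt, plain", "yogurt", 4.0, 60, 0, 1, TRUE,
      27, 49, 98, 79, 33, 101, 44, 14, 63),
    f("emmental", "Emmental cheese", "cheese", 28.0, 380, 0, 1, TRUE,
      31, 51, 95, 77, 28, 108, 36, 13, 67),
    f("fromage_blanc", "Fromage blanc", "other_dairy", 7.5, 100, 0, 1, TRUE,
      27, 49, 98, 79, 33, 101, 44, 14, 63),
    f("boiled_egg", "Egg, boiled", "eggs", 12.5, 143, 0, 1, TRUE,
      24, 53, 86, 72, 55, 94, 47, 17, 66),
    f("baguette", "Baguette", "cereals", 9.9, 265, 0, 0, TRUE,
      23, 37, 69, 28, 40, 78, 29, 12, 44),
    f("cooked_pasta", "Pasta, cooked", "cereals", 5.5, 147, 0, 0, TRUE,
      23, 37, 69, 30, 40, 78, 29, 12, 44),
    f("cooked_rice", "Rice, cooked", "cereals", 4.9, 130, 0, 0, TRUE,
      24, 42, 82, 35, 42, 89, 35, 13, 58),
    f("boiled_potatoes", "Potatoes, boiled", "potatoes", 2.0, 85, 0, 0, TRUE,
      19, 39, 60, 56, 30, 72, 37, 14, 50),
    f("apple", "Apple", "fruit", 0.3, 52, 0, 0, TRUE,
      15, 35, 55, 45, 25, 55, 30, 9, 42),
    f("green_beans", "Green beans, cooked", "vegetables", 1.8, 30, 0, 0, TRUE,
      25, 40, 63, 55, 25, 67, 38, 11, 46),
    f("almonds", "Almonds", "nuts_seeds", 21.0, 600, 0, 0, TRUE,
      26, 38, 69, 30, 33, 72, 28, 10, 42),
    f("cooked_lentils", "Lentils, cooked", "legumes", 8.1, 116, 0, 0, TRUE,
      28, 43, 72, 70, 22, 80, 36, 9, 49),
    f("cooked_chickpeas", "Chickpeas, cooked", "legumes", 8.4, 120, 0, 0, TRUE,
      27, 43, 71, 67, 26, 83, 37, 10, 42),
    f("tofu", "Tofu, plain", "other_plant", 12.0, 120, 0, 0, TRUE,
      26, 48, 80, 62, 26, 90, 40, 13, 49),
    f("vegetable_oil", "Vegetable oil and fats", "seasonings", 0.0, 884, 0, 0,
      TRUE, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    f("red_wine", "Red wine", "other_plant", 0.2, 15, 68, 0, TRUE,
      25, 40, 63, 55, 25, 67, 38, 11, 46),
    f("beef_lasagna", "Beef lasagna (mixed dish)", "cereals", 7.5, 160, 0,
      0.55, FALSE, 29, 45, 79, 65, 37, 82, 38, 12, 50)
  )
  as_composition_table(df)
}

## Lognormal multiplier with unit mean and the given CV.
ln_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

## Positive jittered weights renormalised to sum to 1 per row.
jitter_weights <- function(n, base, sdlog) {
  m <- matrix(rep(base, each = n), nrow = n) *
    matrix(exp(stats::rnorm(n * length(base), 0, sdlog)), nrow = n)
  m / rowSums(m)
}

## Split a per-individual protein budget among the foods of one group,
## equally across eligible foods; returns grams (n x foods matrix columns).
group_grams <- function(protein_g, foods) {
  k <- nrow(foods)
  sweep(matrix(protein_g / k, nrow = length(protein_g), ncol = k), 2,
        foods$protein_g_per_100g / 100, "/")
}

#' Generate a synthetic population of individuals and 7-day records
#'
#' Draws per-individual mean daily food patterns so that the population hits
#' the configured targets (protein per kg by sex, plant share of protein,
#' cereal share of plant protein, meat share of animal protein, embedded
#' animal protein) in expectation, then replicates the mean pattern across
#' days with mean-preserving lognormal day-to-day noise. Anthropometry,
#' physical activity and survey weights are drawn so that Goldberg/Black
#' screening retains at least 90% of individuals under default settings.
#'
#' Within each food group the group's protein budget is split equally across
#' the group's foods with protein content of at least 1 g/100 g; alcoholic
#' beverages are consumed independently of the protein plan; a zero-protein
#' seasonings food (added fats and sugar) tops energy up to each individual's
#' target of basal metabolic rate times physical activity level.
#'
#' @param config A \code{\link{survey_config}}.
#' @param composition A \code{composition_table}; must contain plant and
#'   animal groups, at least one legumes/nuts-seeds food, a zero-protein
#'   energy food and (if \code{embedded_animal_fraction > 0}) at least one
#'   non-substitutable mixed dish.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param policy \code{\link{digestibility_policy}} used to express targets
#'   on the penalised scale reported by the intake engine.
#' @return A list with \code{individuals} and \code{records} data frames.
#' @export
generate_population <- function(config = survey_config(),
                                composition = generate_composition(config),
                                seed = 1L,
                                policy = digestibility_policy()) {
  comp <- as_composition_table(as.data.frame(composition))
  set.seed(as.integer(seed))
  n <- config$n_individuals
  pen <- policy$plant_penalty

  ## feasibility of the targets with this composition table
  elig <- comp$protein_g_per_100g > 0 & comp$alcohol_kcal_per_100g == 0
  pure_plant <- comp$animal_protein_fraction == 0 & elig
  pure_animal <- comp$animal_protein_fraction == 1 & elig
  mixed <- comp$animal_protein_fraction > 0 & comp$animal_protein_fraction < 1
  if (!any(pure_plant) || !any(pure_animal))
    stop("configuration error: composition table cannot realise the ",
         "plant/animal protein targets (need pure plant and animal foods)",
         call. = FALSE)
  if (config$embedded_animal_fraction > 0 && !any(mixed))
    stop("configuration error: embedded_animal_fraction > 0 requires a ",
         "mixed dish in the composition table", call. = FALSE)
  filler <- which(comp$protein_g_per_100g == 0 & comp$alcohol_kcal_per_100g == 0)
  if (length(filler) == 0)
    stop("configuration error: need a zero-protein energy food to reach ",
         "the energy targets", call. = FALSE)
  filler <- filler[which.max(comp$energy_kcal_per_100g[filler])]

  sex <- rep(c("male", "female"), times = config$sex_split[c("male", "female")])
  age <- stats::runif(n, 20, 64)
  weight <- ifelse(sex == "male",
                   stats::rnorm(n, 77, 11), stats::rnorm(n, 63, 10))
  weight <- pmin(pmax(weight, 48), 120)
  height <- ifelse(sex == "male",
                   stats::rnorm(n, 176, 7), stats::rnorm(n, 163, 6))
  height <- pmin(pmax(height, 145), 205)
  activity <- sample(c("low", "moderate", "high"), n, replace = TRUE,
                     prob = c(0.30, 0.50, 0.20))
  pal_base <- c(low = 1.4, moderate = 1.6, high = 1.8)[activity]
  pal <- pmin(pmax(pal_base + stats::rnorm(n, 0, 0.07), 1.28), 1.95)
  survey_weight <- ln_mult(n, 0.4)
  survey_weight <- survey_weight / mean(survey_weight)

  ## penalised protein targets
  tgt <- config$target_protein_g_per_kg[sex]
  protein_perkg <- tgt * ln_mult(n, config$between_person_cv)
  p_tot <- protein_perkg * weight

  m <- config$target_plant_share
  v <- config$plant_share_sd^2
  ab <- m * (1 - m) / v - 1
  plant_share <- pmin(pmax(stats::rbeta(n, m * ab, (1 - m) * ab), 0.10), 0.60)

  animal_pen <- (1 - plant_share) * p_tot
  plant_pen <- plant_share * p_tot

  grams <- matrix(0, nrow = n, ncol = nrow(comp),
                  dimnames = list(NULL, comp$food_id))

  ## embedded animal protein via mixed dishes (split equally among them)
  e <- config$embedded_animal_fraction
  plant_from_mixed_pen <- rep(0, n)
  if (e > 0) {
    mixed_idx <- which(mixed & !comp$substitutable)
    if (length(mixed_idx) == 0) mixed_idx <- which(mixed)
    per <- (e * animal_pen) / length(mixed_idx)
    for (j in mixed_idx) {
      af <- comp$animal_protein_fraction[j]
      g <- per / (comp$protein_g_per_100g[j] / 100 * af)
      grams[, j] <- grams[, j] + g
      plant_from_mixed_pen <- plant_from_mixed_pen +
        g * comp$protein_g_per_100g[j] / 100 * (1 - af) * pen
    }
  }

  ## animal groups: meat vs non-meat split, jittered per individual
  meat_tgt <- config$meat_share_of_animal[sex]
  meat_share <- pmin(pmax(meat_tgt * exp(stats::rnorm(n, 0, 0.12)), 0.30), 0.80)
  a_rest <- (1 - e) * animal_pen
  meat_w <- c(red_meat = 0.46, poultry = 0.26, game = 0.01, offal = 0.05,
              delicatessen = 0.22)
  nonmeat_w <- c(fish = 0.17, milk = 0.18, yogurt = 0.10, cheese = 0.34,
                 other_dairy = 0.04, eggs = 0.17)
  ## drop groups with no eligible food and renormalise so the full protein
  ## budget is always allocated
  has_food <- function(groups, mask) {
    vapply(groups, function(g) any(comp$group == g & mask), TRUE)
  }
  renorm <- function(wm, avail) {
    wm[, !avail] <- 0
    wm / rowSums(wm)
  }
  mw <- renorm(jitter_weights(n, meat_w, 0.35),
               has_food(names(meat_w), pure_animal))
  nw <- renorm(jitter_weights(n, nonmeat_w, 0.35),
               has_food(names(nonmeat_w), pure_animal))
  for (k in seq_along(meat_w)) {
    grp <- names(meat_w)[k]
    foods <- comp[comp$group == grp & pure_animal, , drop = FALSE]
    if (nrow(foods) == 0) next
    grams[, foods$food_id] <- grams[, foods$food_id, drop = FALSE] +
      group_grams(a_rest * meat_share * mw[, k], foods)
  }
  for (k in seq_along(nonmeat_w)) {
    grp <- names(nonmeat_w)[k]
    foods <- comp[comp$group == grp & pure_animal, , drop = FALSE]
    if (nrow(foods) == 0) next
    grams[, foods$food_id] <- grams[, foods$food_id, drop = FALSE] +
      group_grams(a_rest * (1 - meat_share) * nw[, k], foods)
  }

  ## plant groups: cereal-dominated pattern; raw amounts back out the penalty
  plant_budget_pen <- pmax(plant_pen - plant_from_mixed_pen, 0.05 * plant_pen)
  cs <- config$cereal_share_of_plant
  noncereal_w <- c(potatoes = 0.06, fruit = 0.03, vegetables = 0.09,
                   nuts_seeds = 0.018, legumes = 0.05, other_plant = 0.082)
  plant_w <- c(cereals = cs, noncereal_w / sum(noncereal_w) * (1 - cs))
  for (grp in c("cereals", "legumes", "nuts_seeds"))
    if (!any(comp$group == grp & pure_plant))
      stop("configuration error: no ", grp, " food available for the ",
           "plant protein pattern", call. = FALSE)
  ## cereal vs non-cereal split drawn on the logit scale (nearly unbiased
  ## around the target share); non-cereal groups jittered within the rest
  cereal_share_i <- stats::plogis(stats::qlogis(cs) + stats::rnorm(n, 0, 0.25))
  ncw <- renorm(jitter_weights(n, plant_w[-1], 0.25),
                has_food(names(plant_w)[-1], pure_plant))
  pw <- cbind(cereal_share_i, ncw * (1 - cereal_share_i))
  colnames(pw) <- names(plant_w)
  for (k in seq_along(plant_w)) {
    grp <- names(plant_w)[k]
    foods <- comp[comp$group == grp & pure_plant, , drop = FALSE]
    if (nrow(foods) == 0) next
    raw <- plant_budget_pen * pw[, k] / pen
    grams[, foods$food_id] <- grams[, foods$food_id, drop = FALSE] +
      group_grams(raw, foods)
  }

  ## alcoholic beverages, independent of the protein plan
  alc_idx <- which(comp$alcohol_kcal_per_100g > 0)
  for (j in alc_idx) grams[, j] <- grams[, j] + stats::runif(n, 0, 160)

  ## energy top-up to BMR x PAL with the zero-protein filler
  bmr <- henry_bmr(sex, age, weight, height)
  e_target <- bmr * pal
  e_now <- grams %*% ((comp$energy_kcal_per_100g +
                         comp$alcohol_kcal_per_100g) / 100)
  grams[, filler] <- grams[, filler] +
    pmax(0, e_target - as.vector(e_now)) /
    (comp$energy_kcal_per_100g[filler] / 100)

  individuals <- data.frame(
    individual_id = sprintf("I%05d", seq_len(n)), sex = sex, age_y = age,
    weight_kg = weight, height_cm = height, activity = activity,
    survey_weight = survey_weight, stringsAsFactors = FALSE)

  ## day-level records: mean pattern x mean-preserving lognormal day noise
  D <- config$n_days
  day_mult <- matrix(ln_mult(n * D, config$within_person_cv), nrow = n)
  nonzero <- grams > 0
  recs <- vector("list", D)
  for (d in seq_len(D)) {
    gd <- grams * day_mult[, d]
    idx <- which(nonzero, arr.ind = TRUE)
    recs[[d]] <- data.frame(
      individual_id = individuals$individual_id[idx[, 1]],
      day_index = d,
      food_id = comp$food_id[idx[, 2]],
      grams = gd[idx], stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$individual_id, records$day_index,
                           records$food_id), ]
  rownames(records) <- NULL
  list(individuals = individuals, records = records)
}

#' Generate and serialise a complete synthetic study
#'
#' Runs \code{\link{generate_composition}} and
#' \code{\link{generate_population}} and writes \code{composition.csv},
#' \code{individuals.csv}, \code{records.csv} and a \code{manifest.json}
#' recording the configuration, seed and package version to a directory.
#' Regenerating with the same configuration and seed reproduces the files
#' byte for byte.
#'
#' @param config A \code{\link{survey_config}}.
#' @param seed Integer RNG seed.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the composition, individuals and records.
#' @export
generate_study <- function(config = survey_config(), seed = 1L,
                           out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  comp <- generate_composition(config, seed)
  pop <- generate_population(config, comp, seed)
  write_results(comp, file.path(out_dir, "composition.csv"))
  write_results(pop$individuals, file.path(out_dir, "individuals.csv"))
  write_results(pop$records, file.path(out_dir, "records.csv"))
  manifest <- list(config = unclass(config), seed = as.integer(seed),
                   package = "protswap",
                   version = as.character(utils::packageVersion("protswap")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(composition = comp, individuals = pop$individuals,
                 records = pop$records))
}
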