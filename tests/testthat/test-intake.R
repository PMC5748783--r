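test_that("the plant digestibility penalty is applied where it should be", {
  comp <- as_composition_table(data.frame(
    food_id = c("plantfood", "animalfood", "mixed"),
    name = c("P", "A", "M"), group = c("legumes", "red_meat", "cereals"),
    protein_g_per_100g = c(10, 20, 10),
    energy_kcal_per_100g = c(100, 200, 150),
    alcohol_kcal_per_100g = 0,
    iaa_his = 20, iaa_ile = 40, iaa_leu = 70, iaa_lys = 50, iaa_saa = 30,
    iaa_aaa = 80, iaa_thr = 35, iaa_trp = 10, iaa_val = 45,
    animal_protein_fraction = c(0, 1, 0.5), substitutable = TRUE,
    stringsAsFactors = FALSE))

  # 100 g of a pure-plant food with 10 g protein/100 g -> 9.5 g plant protein
  nv <- daily_nutrients(data.frame(food_id = "plantfood", grams = 100), comp)
  expect_equal(nv$plant_protein_g, 9.5)
  expect_equal(nv$animal_protein_g, 0)
  # amino acids ride on the penalised plant protein
  expect_equal(unname(nv$iaa_mg["lys"]), 9.5 * 50)

  # 100 g of a pure-animal food with 20 g protein/100 g -> no penalty
  nv2 <- daily_nutrients(data.frame(food_id = "animalfood", grams = 100), comp)
  expect_equal(nv2$animal_protein_g, 20)
  expect_equal(nv2$plant_protein_g, 0)

  # mixed dish, 50% animal fraction, 10 g protein -> 5.0 animal + 4.75 plant
  nv3 <- daily_nutrients(data.frame(food_id = "mixed", grams = 100), comp)
  expect_equal(nv3$animal_protein_g, 5.0)
  expect_equal(nv3$plant_protein_g, 4.75)
  expect_equal(nv3$protein_g, 9.75)

  # linear in grams: doubling every consumption doubles every field
  all3 <- data.frame(food_id = c("plantfood", "animalfood", "mixed"),
                     grams = c(50, 80, 120))
  a <- daily_nutrients(all3, comp)
  b <- daily_nutrients(transform(all3, grams = 2 * grams), comp)
  expect_equal(b$protein_g, 2 * a$protein_g)
  expect_equal(b$energy_kcal_noalc, 2 * a$energy_kcal_noalc)
  expect_equal(b$iaa_mg, 2 * a$iaa_mg)

  expect_error(daily_nutrients(data.frame(food_id = "nope", grams = 1), comp),
               "unresolvable")
})

# Minimal one-food world where daily protein per kg equals the recorded
# grams: a 100 g protein / 100 g food eaten by 1-kg individuals.
protein_world <- function(values_by_id) {
  comp <- as_composition_table(data.frame(
    food_id = "pure", name = "Pure protein", group = "red_meat",
    protein_g_per_100g = 100, energy_kcal_per_100g = 400,
    alcohol_kcal_per_100g = 0,
    iaa_his = 20, iaa_ile = 40, iaa_leu = 70, iaa_lys = 50, iaa_saa = 30,
    iaa_aaa = 80, iaa_thr = 35, iaa_trp = 10, iaa_val = 45,
    animal_protein_fraction = 1, substitutable = TRUE,
    stringsAsFactors = FALSE))
  ids <- names(values_by_id)
  individuals <- data.frame(individual_id = ids, sex = "male", age_y = 40,
                            weight_kg = 1, height_cm = 175,
                            activity = "moderate", survey_weight = 1,
                            stringsAsFactors = FALSE)
  records <- do.call(rbind, lapply(ids, function(id) {
    v <- values_by_id[[id]]
    data.frame(individual_id = id, day_index = seq_along(v),
               food_id = "pure", grams = v, stringsAsFactors = FALSE)
  }))
  list(composition = comp, individuals = individuals, records = records)
}

test_that("usual-intake shrinkage matches the closed-form toy oracle", {
  w <- protein_world(list(A = c(10, 10, 10, 10), B = c(8, 12, 9, 11),
                          C = c(5, 15, 10, 14)))
  # plant protein is identically zero in this world; its degenerate
  # fallback warning is expected and not under test here
  fit <- suppressWarnings(usual_intakes(w$individuals, w$records,
                                        w$composition, lambda = 1))

  # independent method-of-moments oracle on the identity (lambda = 1) scale
  y <- list(A = c(10, 10, 10, 10), B = c(8, 12, 9, 11), C = c(5, 15, 10, 14))
  zi <- vapply(y, mean, 1)
  grand <- mean(unlist(y))
  k <- 3; D <- 4; N <- 12
  msw <- sum(vapply(y, function(v) sum((v - mean(v))^2), 1)) / (N - k)
  msb <- sum(D * (zi - grand)^2) / (k - 1)
  s2w <- msw
  s2b <- max((msb - msw) / D, 0)
  shrink <- s2b / (s2b + s2w / D)
  expected <- grand + (zi - grand) * shrink   # lambda = 1: back-transform is
  # identity (+1 offset cancels) and the bias correction term vanishes
  got <- fit$usual$protein_g_per_kg[match(names(y), fit$usual$individual_id)]
  expect_equal(got, unname(expected), tolerance = 1e-10)
  cmp <- fit$components[fit$components$nutrient == "protein_g_per_kg", ]
  expect_equal(cmp$sigma2_w, s2w, tolerance = 1e-10)
  expect_equal(cmp$sigma2_b, s2b, tolerance = 1e-10)

  # shrinkage contraction: usual intakes vary less than the raw means,
  # strictly so when within-person variance is present
  expect_lt(stats::var(got), stats::var(unname(zi)))
})

test_that("zero within-person variance leaves individual means untouched", {
  w <- protein_world(list(A = c(10, 10, 10), B = c(14, 14, 14),
                          C = c(7, 7, 7)))
  fit <- suppressWarnings(usual_intakes(w$individuals, w$records,
                                        w$composition, lambda = 1))
  got <- fit$usual$protein_g_per_kg[match(c("A", "B", "C"),
                                          fit$usual$individual_id)]
  expect_equal(got, c(10, 14, 7), tolerance = 1e-10)
})

test_that("more recorded days pull the usual intake toward the own mean", {
  base2 <- list(A = c(6, 14), B = c(12, 16), C = c(9, 11))
  more2 <- list(A = rep(c(6, 14), 4), B = rep(c(12, 16), 4),
                C = rep(c(9, 11), 4))
  g1 <- suppressWarnings(usual_intakes(protein_world(base2)$individuals,
                                       protein_world(base2)$records,
                                       protein_world(base2)$composition,
                                       lambda = 1))
  g2 <- suppressWarnings(usual_intakes(protein_world(more2)$individuals,
                                       protein_world(more2)$records,
                                       protein_world(more2)$composition,
                                       lambda = 1))
  ub1 <- g1$usual$protein_g_per_kg[g1$usual$individual_id == "B"]
  ub2 <- g2$usual$protein_g_per_kg[g2$usual$individual_id == "B"]
  expect_gt(ub2, ub1)        # closer to B's own mean of 14 with more days
  expect_lt(ub1, 14); expect_lte(ub2, 14)
})

test_that("degenerate all-constant intakes fall back to means with a warning", {
  expect_warning(protswap:::shrink_nutrient(rep(10, 6), rep(c("A", "B"), 3),
                                            lambda = 1),
                 "zero variance")
  w <- protein_world(list(A = c(10, 10, 10), B = c(10, 10, 10)))
  fit <- suppressWarnings(usual_intakes(w$individuals, w$records,
                                        w$composition, lambda = 1))
  expect_equal(sort(unique(fit$usual$protein_g_per_kg)), 10)
})

test_that("Box-Cox lambda grid prefers the true transform and ties go to 1", {
  set.seed(41)
  y <- exp(stats::rnorm(4000, 1, 0.4))         # truly lognormal
  expect_equal(protswap:::fit_box_cox_lambda(y), 0)
  z <- stats::rnorm(4000, 50, 2)               # already normal
  expect_equal(protswap:::fit_box_cox_lambda(z, grid = c(0, 1)), 1)
  # tie-break: identical log-likelihoods resolve toward lambda = 1
  expect_equal(protswap:::fit_box_cox_lambda(z, grid = c(1, 1)), 1)
})
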