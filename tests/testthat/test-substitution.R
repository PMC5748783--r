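# Hand-arithmetic oracle diet: 200 g beef (20 g protein, 200 kcal /100 g)
# plus 400 g pasta (5 g protein, 150 kcal /100 g), i.e. 40 g animal protein,
# 20 g raw plant protein, 400 + 600 kcal.

test_that("LNS mix shares follow observed intake on the chosen basis", {
  comp <- toy_composition()
  rec1 <- data.frame(individual_id = "I1", day_index = 1,
                     food_id = "lentils", grams = 100)
  mix1 <- build_lns_mix(rec1, comp)
  expect_equal(mix1$share[mix1$food_id == "lentils"], 1)

  # equal observed energy from the two LNS foods -> 50/50 on energy basis
  rec2 <- data.frame(individual_id = "I1", day_index = 1,
                     food_id = c("lentils", "nuts"),
                     grams = c(600, 600 * 116 / 600))
  mix2 <- build_lns_mix(rec2, comp)
  expect_equal(sort(mix2$share), c(0.5, 0.5))

  rec3 <- data.frame(individual_id = "I1", day_index = 1,
                     food_id = "beef", grams = 100)
  expect_error(build_lns_mix(rec3, comp), "no legumes")
})

test_that("Model A on the toy diet reproduces the hand-derived values", {
  comp <- toy_composition()
  model <- model_spec("A", policy = raw_policy())
  r <- substitute_individual(toy_pattern(), comp, model, s = 0.5)
  # remove 100 g beef (200 kcal), add 200/1.5 = 133.33 g pasta
  expect_equal(unname(r$pattern["beef"]), 100)
  expect_equal(unname(r$pattern["pasta"]), 400 + 133 + 1 / 3,
               tolerance = 1e-12)
  # energy conserved; raw plant share rises from 33.3% to 57.1%
  expect_equal(r$delta$energy_kcal_noalc, 0, tolerance = 1e-12)
  expect_equal(r$nutrients$plant_protein_g, 26 + 2 / 3, tolerance = 1e-12)
  share <- r$nutrients$plant_protein_g / r$nutrients$protein_g
  expect_equal(share, (26 + 2 / 3) / (46 + 2 / 3), tolerance = 1e-12)
  expect_equal(share, 0.5714286, tolerance = 1e-6)

  # s = 0 leaves the pattern untouched with zero delta
  r0 <- substitute_individual(toy_pattern(), comp, model, s = 0)
  expect_equal(r0$pattern[c("beef", "pasta")], toy_pattern())
  expect_equal(r0$delta$protein_g, 0)
})

test_that("Model P on the toy diet conserves total protein exactly", {
  comp <- toy_composition()
  model <- model_spec("P", policy = raw_policy())
  r <- substitute_individual(toy_pattern(), comp, model, s = 0.5)
  # 20 g removed beef protein -> 400 g pasta added (20 g plant protein)
  expect_equal(unname(r$pattern["pasta"]), 800, tolerance = 1e-12)
  expect_equal(r$nutrients$protein_g, 60, tolerance = 1e-9)
  expect_equal(r$delta$protein_raw_g, 0, tolerance = 1e-12)
})

test_that("conservation holds at every grid point on the toy diet", {
  comp <- toy_composition()
  mix <- build_lns_mix(data.frame(individual_id = "I1", day_index = 1,
                                  food_id = c("lentils", "nuts"),
                                  grams = c(500, 100)), comp)
  for (kind in c("P", "A", "B", "C")) {
    lam <- if (kind == "C") 0.4 else NULL
    model <- model_spec(kind, lns_fraction = lam)
    base <- substitute_individual(toy_pattern(), comp, model, 0, mix)
    for (s in seq(0, 1, by = 0.1)) {
      r <- substitute_individual(toy_pattern(), comp, model, s, mix)
      if (kind == "P") {
        expect_equal(r$delta$protein_raw_g, 0, tolerance = 1e-9 * 60)
      } else {
        expect_equal(r$delta$energy_kcal_noalc, 0, tolerance = 1e-9 * 1000)
      }
      # animal foods scale together: beef is the only one here, check (1-s)
      beef <- unname(r$pattern["beef"])
      if (is.na(beef)) beef <- 0
      expect_equal(beef, 200 * (1 - s), tolerance = 1e-12)
    }
  }
})

test_that("simulate_curve matches a from-scratch recomputation on the toy", {
  comp <- toy_composition()
  individuals <- data.frame(individual_id = "I1", sex = "male", age_y = 40,
                            weight_kg = 70, height_cm = 175,
                            activity = "moderate", survey_weight = 1,
                            stringsAsFactors = FALSE)
  records <- data.frame(individual_id = "I1", day_index = rep(1:2, each = 2),
                        food_id = rep(c("beef", "pasta"), 2),
                        grams = rep(c(200, 400), 2), stringsAsFactors = FALSE)
  fit <- suppressWarnings(usual_intakes(individuals, records, comp,
                                        lambda = 1))
  model <- model_spec("A", s_grid = c(0, 0.5, 1))
  curve <- simulate_curve(individuals, records, fit, model, comp)
  expect_s3_class(curve, "substitution_curve")
  expect_equal(nrow(curve), 3)

  # independent recomputation at s = 0.5 (penalised accounting):
  # pattern beef 100 g, pasta 533.333 g
  pen <- 0.95
  prot <- 100 * 0.20 + (533 + 1 / 3) * 0.05 * pen
  plant <- (533 + 1 / 3) * 0.05 * pen
  expect_equal(curve$plant_share_pct[2], 100 * plant / prot,
               tolerance = 1e-9)
  expect_equal(curve$energy_kcal_mean, rep(1000, 3), tolerance = 1e-9)

  # usual protein shifted by the per-kg delta, then the probability approach
  u0 <- fit$usual$protein_g_per_kg
  base_prot <- 40 + 20 * pen
  y <- u0 + (prot - base_prot) / 70
  expect_equal(curve$prev_protein[2],
               100 * inadequacy_probability(y, 0.66, 0.125),
               tolerance = 1e-9)
  # s = 0 equals the unmodified population
  expect_equal(curve$prev_protein[1],
               100 * inadequacy_probability(u0, 0.66, 0.125),
               tolerance = 1e-12)
  # plant share non-decreasing in s
  expect_true(all(diff(curve$plant_share_pct) >= -1e-12))
})

test_that("substitution errors guide users without a plant pattern", {
  comp <- toy_composition()
  meat_only <- c(beef = 300)
  expect_error(substitute_individual(meat_only, comp,
                                     model_spec("A"), 0.5),
               "lns_fraction")
  expect_error(substitute_individual(meat_only, comp,
                                     model_spec("P"), 0.5),
               "plant protein pattern")
  # Model B needs no pre-existing plant pattern
  mix <- build_lns_mix(data.frame(individual_id = "x", day_index = 1,
                                  food_id = "lentils", grams = 10), comp)
  r <- substitute_individual(meat_only, comp, model_spec("B"), 1, mix)
  expect_equal(r$nutrients$animal_protein_g, 0, tolerance = 1e-12)
})

test_that("full substitution saturates at 100% plant share only without embedded animal protein", {
  cfg0 <- survey_config(n_individuals = 60, embedded_animal_fraction = 0)
  st0 <- small_study(config = cfg0, seed = 9)
  scr0 <- screen_population(st0$individuals, st0$records, st0$composition)
  fit0 <- usual_intakes(scr0$individuals, scr0$records, st0$composition)
  cv0 <- simulate_curve(scr0$individuals, scr0$records, fit0,
                        model_spec("A", s_grid = c(0, 1)), st0$composition)
  expect_equal(cv0$plant_share_pct[2], 100, tolerance = 1e-6)

  cfg1 <- survey_config(n_individuals = 60, embedded_animal_fraction = 0.05)
  st1 <- small_study(config = cfg1, seed = 9)
  scr1 <- screen_population(st1$individuals, st1$records, st1$composition)
  fit1 <- usual_intakes(scr1$individuals, scr1$records, st1$composition)
  cv1 <- simulate_curve(scr1$individuals, scr1$records, fit1,
                        model_spec("A", s_grid = c(0, 1)), st1$composition)
  expect_lt(cv1$plant_share_pct[2], 100 - 1e-3)
})

test_that("crossing detection interpolates, honours grid points, returns NA", {
  fake <- data.frame(model = "A", lns_fraction = 0, s = c(0, 0.5, 1),
                     plant_share_pct = c(30, 40, 60),
                     energy_kcal_mean = 2000,
                     prev_protein = c(1, 2, 8),
                     lo_protein = 0, hi_protein = 10,
                     prev_lys = c(0, 5, 20), lo_lys = 0, hi_lys = 25)
  class(fake) <- c("substitution_curve", "data.frame")
  # bracket (2% at 40, 8% at 60), level 5% -> 50 by linear interpolation
  expect_equal(find_crossing(fake, "protein", 5), 50)
  # exact grid point
  expect_equal(find_crossing(fake, "lys", 5), 40)
  # level never bracketed -> absent, not an error
  expect_true(is.na(find_crossing(fake, "protein", 50)))
  expect_error(find_crossing(fake, "unobtainium", 5), "unknown nutrient")
})
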