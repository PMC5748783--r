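test_that("contribution table reproduces hand arithmetic on toy diets", {
  comp <- toy_composition()
  one_food <- data.frame(individual_id = "I1", day_index = 1,
                         food_id = "beef", grams = 150)
  ind1 <- data.frame(individual_id = "I1", sex = "male", age_y = 40,
                     weight_kg = 70, height_cm = 175, activity = "moderate",
                     survey_weight = 1, stringsAsFactors = FALSE)
  t1 <- contribution_table(one_food, comp, ind1)
  expect_equal(t1$protein_pct_mean[t1$group == "red_meat"], 100)
  expect_equal(t1$protein_pct_mean[t1$group == "animal"], 100)
  expect_equal(t1$protein_pct_mean[t1$group == "plant"], 0)

  # beef/pasta toy: penalised protein 40 beef + 19 pasta;
  # lysine 40*90 beef + 19*30 pasta
  two_food <- data.frame(individual_id = "I1", day_index = 1,
                         food_id = c("beef", "pasta"), grams = c(200, 400))
  t2 <- contribution_table(two_food, comp, ind1)
  expect_equal(t2$protein_pct_mean[t2$group == "red_meat"],
               100 * 40 / 59, tolerance = 1e-12)
  expect_equal(t2$protein_pct_mean[t2$group == "cereals"],
               100 * 19 / 59, tolerance = 1e-12)
  expect_equal(t2$lysine_pct_mean[t2$group == "red_meat"],
               100 * 3600 / 4170, tolerance = 1e-12)
  # per-individual group shares sum to 100 for each nutrient
  groups <- setdiff(unique(t2$group), c("animal", "plant"))
  expect_equal(sum(t2$protein_pct_mean[t2$group %in% groups]), 100,
               tolerance = 1e-9)
  expect_equal(sum(t2$lysine_pct_mean[t2$group %in% groups]), 100,
               tolerance = 1e-9)
})

test_that("animal foods contribute more to lysine than to protein", {
  st <- small_study(n = 150, seed = 12)
  scr <- screen_population(st$individuals, st$records, st$composition)
  tab <- contribution_table(scr$records, st$composition, scr$individuals)
  for (sx in c("male", "female")) {
    a_p <- tab$protein_pct_mean[tab$group == "animal" & tab$sex == sx]
    a_l <- tab$lysine_pct_mean[tab$group == "animal" & tab$sex == sx]
    expect_gt(a_l, a_p)
  }
  # sex-stratified schema covers all groups plus the two super-rows
  expect_equal(sort(unique(tab$group)),
               sort(c("animal", "plant",
                      unique(as.data.frame(st$composition)$group))))
})

test_that("regression recovers an exact linear relation to 1e-10", {
  n <- 40
  share <- seq(10, 50, length.out = n)
  u <- data.frame(individual_id = sprintf("I%03d", 1:n),
                  protein_g_per_kg = 0.66 * (2.2 - 0.015 * share),
                  plant_protein_g = share, animal_protein_g = 100 - share,
                  energy_kcal_noalc = 2200, survey_weight = 1)
  ind <- data.frame(individual_id = u$individual_id, sex = "male",
                    age_y = 40, weight_kg = 70, height_cm = 175,
                    activity = "moderate", survey_weight = 1,
                    stringsAsFactors = FALSE)
  r <- suppressWarnings(association_regression(u, ind, "protein"))
  expect_equal(r$slope_per_pct, -0.015, tolerance = 1e-10)
  expect_equal(r$slope_per_10pct, -0.15, tolerance = 1e-10)
  expect_equal(r$intercept, 2.2, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  expect_error(association_regression(u[1:5, ], ind[1:5, ], "protein"),
               "at least 10")
})

test_that("slope confidence intervals are calibrated on pure noise", {
  set.seed(1)
  n <- 60
  cover <- 0
  for (rep in 1:100) {
    share <- stats::runif(n, 10, 50)
    u <- data.frame(individual_id = sprintf("I%03d", 1:n),
                    protein_g_per_kg = stats::rnorm(n, 1.3, 0.25),
                    plant_protein_g = share, animal_protein_g = 100 - share,
                    energy_kcal_noalc = 2200, survey_weight = 1)
    ind <- data.frame(individual_id = u$individual_id, sex = "male",
                      age_y = 40, weight_kg = 70, height_cm = 175,
                      activity = "moderate", survey_weight = 1,
                      stringsAsFactors = FALSE)
    r <- association_regression(u, ind, "protein")
    ci <- stats::confint(r$model)["plant_share_pct", ]
    if (ci[1] <= 0 && ci[2] >= 0) cover <- cover + 1
  }
  expect_gte(cover, 93)
})

test_that("lysine adequacy falls faster with plant share than protein adequacy", {
  st <- small_study(n = 300, seed = 8)
  scr <- screen_population(st$individuals, st$records, st$composition)
  fit <- usual_intakes(scr$individuals, scr$records, st$composition)
  rp <- association_regression(fit, scr$individuals, "protein")
  rl <- association_regression(fit, scr$individuals, "lys")
  # in intake:EAR units per 10 points of plant share
  expect_lt(rl$slope_per_10pct, rp$slope_per_10pct)
  expect_lt(rl$slope_per_10pct, 0)
  # adjusted variant runs and reports R^2 in [0, 1]
  ra <- association_regression(fit, scr$individuals, "lys", adjusted = TRUE)
  expect_gte(ra$r_squared, 0); expect_lte(ra$r_squared, 1)
})
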