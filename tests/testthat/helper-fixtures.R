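# Shared fixtures, all built in code.

# Two-food toy diet used for hand-arithmetic oracles: 200 g of beef
# (20 g protein / 200 kcal per 100 g) and 400 g of pasta
# (5 g protein / 150 kcal per 100 g).
toy_composition <- function() {
  as_composition_table(data.frame(
    food_id = c("beef", "pasta", "lentils", "nuts"),
    name = c("Beef", "Pasta", "Lentils", "Nuts"),
    group = c("red_meat", "cereals", "legumes", "nuts_seeds"),
    protein_g_per_100g = c(20, 5, 7.2, 20.6),
    energy_kcal_per_100g = c(200, 150, 116, 600),
    alcohol_kcal_per_100g = 0,
    iaa_his = c(34, 23, 28, 26), iaa_ile = c(47, 37, 43, 38),
    iaa_leu = c(81, 69, 72, 69), iaa_lys = c(90, 30, 70, 30),
    iaa_saa = c(39, 40, 22, 33), iaa_aaa = c(77, 78, 80, 72),
    iaa_thr = c(44, 29, 36, 28), iaa_trp = c(12, 12, 9, 10),
    iaa_val = c(50, 44, 49, 42),
    animal_protein_fraction = c(1, 0, 0, 0),
    substitutable = TRUE,
    stringsAsFactors = FALSE))
}

toy_pattern <- function() c(beef = 200, pasta = 400)

# Raw (penalty-free) policy for pre-penalty arithmetic checks.
raw_policy <- function() digestibility_policy(plant_penalty = 1)

# Small synthetic study, shared across tests.
small_study <- function(n = 200, seed = 11, config = NULL) {
  cfg <- config
  if (is.null(cfg)) cfg <- survey_config(n_individuals = n)
  comp <- generate_composition(cfg)
  pop <- generate_population(cfg, comp, seed = seed)
  list(config = cfg, composition = comp, individuals = pop$individuals,
       records = pop$records)
}

# Per-individual mean daily grams, computed independently of the package's
# internal pattern builder.
mean_pattern_of <- function(records, id) {
  rec <- records[records$individual_id == id, ]
  D <- length(unique(rec$day_index))
  tot <- tapply(rec$grams, rec$food_id, sum)
  stats::setNames(as.numeric(tot) / D, names(tot))
}

individual_columns_sorted <- function() {
  c("individual_id", "sex", "age_y", "weight_kg", "height_cm", "activity",
    "survey_weight")
}

# Population moments of the generated mean daily patterns (penalised scale).
pattern_moments <- function(pop, comp) {
  mp <- protswap:::mean_daily_pattern(pop$individuals, pop$records, comp)
  cache <- protswap:::comp_cache(comp, digestibility_policy())
  nut <- protswap:::pattern_nutrients(mp$M, cache)
  pk <- nut$protein_g / pop$individuals$weight_kg
  male <- pop$individuals$sex == "male"
  list(male = mean(pk[male]), female = mean(pk[!male]),
       share = mean(nut$plant_protein_g / nut$protein_g))
}
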