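## Domain types and delimited-text exchange formats.
##
## All exchange files are CSV with a header row; no standard bioinformatics
## format covers dietary records and CSV keeps fixtures auditable. Units are
## fixed package-wide: g/100 g and kcal/100 g for composition, mg/g protein
## for amino acid composition, g/day and kcal/day for intakes, g/kg b.w./day
## (protein) and mg/kg b.w./day (amino acids) for per-kg intakes.

composition_columns <- function() {
  c("food_id", "name", "group", "protein_g_per_100g", "energy_kcal_per_100g",
    "alcohol_kcal_per_100g", iaa_cols(), "animal_protein_fraction",
    "substitutable")
}

individual_columns <- function() {
  c("individual_id", "sex", "age_y", "weight_kg", "height_cm", "activity",
    "survey_weight")
}

record_columns <- function() c("individual_id", "day_index", "food_id", "grams")

fmt_err <- function(row, col, what) {
  stop(sprintf("format error at row %s, column '%s': %s", row, col, what),
       call. = FALSE)
}

#' Validate a food composition table
#'
#' Checks the schema and invariants of a composition table: one row per food,
#' non-negative composition values, \code{animal_protein_fraction} in [0, 1],
#' protein at most 100 g/100 g, each amino acid content at most 1000 mg per g
#' protein, and unique \code{food_id}.
#'
#' @param df A data frame with the columns returned by the composition schema
#'   (\code{food_id}, \code{name}, \code{group}, \code{protein_g_per_100g},
#'   \code{energy_kcal_per_100g}, \code{alcohol_kcal_per_100g}, the nine
#'   \code{iaa_*} columns in mg/g protein, \code{animal_protein_fraction},
#'   \code{substitutable}).
#' @return The validated data frame with class \code{composition_table}.
#' @export
as_composition_table <- function(df) {
  need <- composition_columns()
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s) in composition table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$food_id <- as.character(df$food_id)
  df$group <- as.character(df$group)
  df$substitutable <- as.logical(df$substitutable)
  if (anyDuplicated(df$food_id))
    stop("duplicate food_id in composition table: ",
         paste(unique(df$food_id[duplicated(df$food_id)]), collapse = ", "),
         call. = FALSE)
  bad_grp <- setdiff(unique(df$group), FOOD_GROUPS)
  if (length(bad_grp) > 0)
    stop("unknown food group(s): ", paste(bad_grp, collapse = ", "),
         call. = FALSE)
  num_cols <- c("protein_g_per_100g", "energy_kcal_per_100g",
                "alcohol_kcal_per_100g", iaa_cols(), "animal_protein_fraction")
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) fmt_err("all", cl, "not numeric")
    if (anyNA(v)) fmt_err(which(is.na(v))[1], cl, "missing value")
    if (any(v < 0)) fmt_err(which(v < 0)[1], cl, "negative value")
  }
  if (any(df$animal_protein_fraction > 1))
    fmt_err(which(df$animal_protein_fraction > 1)[1],
            "animal_protein_fraction", "outside [0, 1]")
  if (any(df$protein_g_per_100g > 100))
    fmt_err(which(df$protein_g_per_100g > 100)[1], "protein_g_per_100g",
            "exceeds 100 g per 100 g")
  for (cl in iaa_cols())
    if (any(df[[cl]] > 1000))
      fmt_err(which(df[[cl]] > 1000)[1], cl, "exceeds 1000 mg per g protein")
  rownames(df) <- NULL
  class(df) <- c("composition_table", "data.frame")
  df
}

#' Read a food composition table from CSV
#'
#' @param path Path to a CSV file with a header row naming every composition
#'   field; amino acid columns are named \code{iaa_<key>} with keys
#'   \code{his, ile, leu, lys, saa, aaa, thr, trp, val}.
#' @return A \code{composition_table} (validated data frame keyed by
#'   \code{food_id}).
#' @seealso [as_composition_table()] for the schema and invariants.
#' @export
read_composition_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_composition_table(df)
}

validate_individuals <- function(df) {
  need <- individual_columns()
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s) in individuals: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$individual_id <- as.character(df$individual_id)
  if (anyDuplicated(df$individual_id))
    stop("duplicate individual_id", call. = FALSE)
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  if (!all(df$activity %in% c("low", "moderate", "high")))
    stop("activity must be low/moderate/high", call. = FALSE)
  if (any(df$weight_kg <= 0)) fmt_err(which(df$weight_kg <= 0)[1],
                                      "weight_kg", "must be positive")
  if (any(df$survey_weight <= 0)) fmt_err(which(df$survey_weight <= 0)[1],
                                          "survey_weight", "must be positive")
  rownames(df) <- NULL
  df
}

validate_records <- function(df, individuals = NULL, composition = NULL) {
  need <- record_columns()
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s) in records: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$individual_id <- as.character(df$individual_id)
  df$food_id <- as.character(df$food_id)
  if (any(df$grams < 0))
    fmt_err(which(df$grams < 0)[1], "grams", "negative value")
  if (any(df$day_index < 1 | df$day_index != round(df$day_index)))
    fmt_err(which(df$day_index < 1)[1], "day_index", "must be a positive integer")
  if (!is.null(composition)) {
    unknown <- setdiff(unique(df$food_id), composition$food_id)
    if (length(unknown) > 0)
      stop("records reference unknown food_id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(individuals)) {
    unknown <- setdiff(unique(df$individual_id), individuals$individual_id)
    if (length(unknown) > 0)
      stop("records reference unknown individual_id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read individuals and day-level diet records
#'
#' Accepts either two files (individual attributes plus day-level
#' consumptions) or one long-format file in which every consumption row also
#' carries the individual attributes. Both layouts produce identical
#' in-memory content.
#'
#' @param records_path CSV of consumptions with columns
#'   \code{individual_id, day_index, food_id, grams}; in the one-file layout
#'   it additionally carries \code{sex, age_y, weight_kg, height_cm, activity,
#'   survey_weight}.
#' @param individuals_path Optional CSV of individual attributes
#'   (\code{individual_id, sex, age_y, weight_kg, height_cm, activity,
#'   survey_weight}); omit for the long-format layout.
#' @param composition Optional \code{composition_table}; when supplied, every
#'   \code{food_id} in the records must resolve against it.
#' @return A list with elements \code{individuals} and \code{records}.
#' @export
read_diet_records <- function(records_path, individuals_path = NULL,
                              composition = NULL) {
  rec <- utils::read.csv(records_path, stringsAsFactors = FALSE)
  if (is.null(individuals_path)) {
    need <- union(individual_columns(), record_columns())
    miss <- setdiff(need, names(rec))
    if (length(miss) > 0)
      stop("long-format records file lacks column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    ind <- unique(rec[individual_columns()])
    rec <- rec[record_columns()]
  } else {
    ind <- utils::read.csv(individuals_path, stringsAsFactors = FALSE)
  }
  ind <- validate_individuals(ind)
  rec <- validate_records(rec, individuals = ind, composition = composition)
  days <- table(unique(rec[c("individual_id", "day_index")])$individual_id)
  none <- setdiff(ind$individual_id, names(days))
  if (length(none) > 0)
    stop("individual(s) with no recorded day: ", paste(none, collapse = ", "),
         call. = FALSE)
  list(individuals = ind, records = rec)
}

#' Write a pipeline result table to CSV
#'
#' Writes any tabular pipeline output (composition tables, records,
#' prevalence tables, simulation curves, contribution tables) as CSV with a
#' stable column order and full numeric precision, so that re-reading
#' reproduces every numeric field to 1e-12.
#'
#' @param x A data frame (possibly classed).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct a per-day nutrient vector
#'
#' A nutrient vector holds one individual-day of intake: total protein,
#' its animal and plant components (plant already carrying the digestibility
#' penalty), non-alcohol and alcohol energy, and the nine indispensable amino
#' acids in mg. The decomposition invariant
#' \code{protein_g == plant_protein_g + animal_protein_g} is enforced to
#' 1e-9 relative.
#'
#' @param protein_g Total protein, g/day.
#' @param animal_protein_g Animal-source protein, g/day.
#' @param plant_protein_g Plant-source (penalised) protein, g/day.
#' @param energy_kcal_noalc Non-alcohol energy, kcal/day.
#' @param alcohol_kcal Alcohol energy, kcal/day.
#' @param iaa_mg Named numeric vector over the nine IAA keys, mg/day.
#' @return An object of class \code{nutrient_vector} (named list).
#' @export
nutrient_vector <- function(protein_g, animal_protein_g, plant_protein_g,
                            energy_kcal_noalc, alcohol_kcal = 0,
                            iaa_mg = stats::setNames(numeric(9), IAA_KEYS)) {
  stopifnot(all(c(protein_g, animal_protein_g, plant_protein_g,
                  energy_kcal_noalc, alcohol_kcal) >= 0),
            setequal(names(iaa_mg), IAA_KEYS), all(iaa_mg >= 0))
  tol <- 1e-9 * max(protein_g, 1e-12)
  if (abs(protein_g - (animal_protein_g + plant_protein_g)) > tol)
    stop("nutrient vector violates plant + animal = total protein",
         call. = FALSE)
  structure(list(protein_g = protein_g,
                 animal_protein_g = animal_protein_g,
                 plant_protein_g = plant_protein_g,
                 energy_kcal_noalc = energy_kcal_noalc,
                 alcohol_kcal = alcohol_kcal,
                 iaa_mg = iaa_mg[IAA_KEYS]),
            class = "nutrient_vector")
}

#' @export
print.nutrient_vector <- function(x, ...) {
  cat(sprintf("Daily nutrients: %.2f g protein (%.2f animal + %.2f plant*), %.0f kcal\n",
              x$protein_g, x$animal_protein_g, x$plant_protein_g,
              x$energy_kcal_noalc))
  cat("  *plant protein after digestibility penalty\n")
  cat("  IAA (mg):", paste(sprintf("%s %.0f", names(x$iaa_mg), x$iaa_mg),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Reference table of average requirements
#'
#' Estimated Average Requirements (EAR) for protein (g/kg body weight/day)
#' and the nine indispensable amino acids (mg/kg body weight/day), with the
#' coefficient of variation of the requirement distribution used by the
#' probability approach. Defaults follow the FAO/WHO/UNU adult values and a
#' requirement CV of 12.5%; all entries can be overridden.
#'
#' @param protein_ear_g_per_kg Protein EAR, g/kg/day (default 0.66).
#' @param iaa_ear_mg_per_kg Named vector of amino acid EARs, mg/kg/day.
#' @param cv Requirement coefficient of variation, in (0, 1) (default 0.125).
#' @return An object of class \code{ear_table}.
#' @export
ear_table <- function(protein_ear_g_per_kg = 0.66,
                      iaa_ear_mg_per_kg = c(his = 10, ile = 20, leu = 39,
                                            lys = 30, saa = 15, aaa = 25,
                                            thr = 15, trp = 4, val = 26),
                      cv = 0.125) {
  stopifnot(protein_ear_g_per_kg > 0, cv > 0, cv < 1,
            setequal(names(iaa_ear_mg_per_kg), IAA_KEYS),
            all(iaa_ear_mg_per_kg > 0))
  structure(list(protein_ear_g_per_kg = protein_ear_g_per_kg,
                 iaa_ear_mg_per_kg = iaa_ear_mg_per_kg[IAA_KEYS],
                 cv = cv),
            class = "ear_table")
}

#' @export
print.ear_table <- function(x, ...) {
  cat(sprintf("EAR table: protein %.2f g/kg/d, requirement CV %.1f%%\n",
              x$protein_ear_g_per_kg, 100 * x$cv))
  print(x$iaa_ear_mg_per_kg)
  invisible(x)
}
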