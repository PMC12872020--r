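#' Read an allometric coefficient table
#'
#' Loads the power-law coefficients used for compartment biomass: one row per
#' `(allometric_key, compartment)` with `beta1` (kg cm^-beta2) and `beta2`
#' (dimensionless), compartments `wood`, `bark`, `branches`. The keys
#' `"hardwood"` and `"softwood"` must be present: species without their own
#' rows resolve to the wood-type fallback.
#'
#' @param path CSV or YAML file with columns/fields `allometric_key`,
#'   `compartment`, `beta1`, `beta2`.
#' @return A `data.frame` with class `"AllometricCoefficients"`.
#' @export
readAllometry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("yml", "yaml")) {
    rows <- yaml::read_yaml(path)
    do.call(rbind, lapply(rows, function(r) data.frame(
      allometric_key = r$allometric_key, compartment = r$compartment,
      beta1 = as.numeric(r$beta1), beta2 = as.numeric(r$beta2),
      stringsAsFactors = FALSE)))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  }
  allometricCoefficients(tab)
}

#' Validate an allometric coefficient table
#'
#' @param tab `data.frame` with columns `allometric_key`, `compartment`,
#'   `beta1`, `beta2`.
#' @return The validated table, classed `"AllometricCoefficients"`.
#' @export
allometricCoefficients <- function(tab) {
  need <- c("allometric_key", "compartment", "beta1", "beta2")
  if (!all(need %in% names(tab)))
    stop("coefficient table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(c("hardwood", "softwood") %in% tab$allometric_key))
    stop("coefficient table must include 'hardwood' and 'softwood' fallback rows",
         call. = FALSE)
  if (any(tab$beta1 <= 0) || any(tab$beta2 <= 0))
    stop("beta1 and beta2 must be strictly positive", call. = FALSE)
  bad <- setdiff(unique(tab$compartment), c("wood", "bark", "branches"))
  if (length(bad))
    stop("unknown compartments: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(as.data.frame(tab), class = c("AllometricCoefficients", "data.frame"))
}

#' Default allometric coefficients shipped with the package
#'
#' Loads `inst/extdata/allometry_default_synthetic.csv`, a synthetic set of
#' representative temperate-zone power-law coefficients (it is a placeholder
#' table with realistic magnitudes, not published regression estimates;
#' replace it with a fitted coefficient file for real valuation work).
#'
#' @return An `"AllometricCoefficients"` table.
#' @export
defaultAllometry <- function() {
  readAllometry(system.file("extdata", "allometry_default_synthetic.csv",
                            package = "CanopyPlan", mustWork = TRUE))
}

#' Carbon pipeline configuration
#'
#' @param carbon_fraction fraction of dry biomass that is carbon
#'   (default 0.5).
#' @param urban_factor open-grown correction applied to total biomass:
#'   street trees carry less biomass than forest-derived equations predict
#'   (default 0.8).
#' @param price_per_ton social cost of carbon, CAD per 1000 kg carbon
#'   (default 994.57, 2025 CAD).
#' @return A list with class `"CarbonConfig"`.
#' @export
carbonConfig <- function(carbon_fraction = 0.5, urban_factor = 0.8,
                         price_per_ton = 994.57) {
  .assertScalarNumber(carbon_fraction, "carbon_fraction", 0, Inf, open_lower = TRUE)
  .assertScalarNumber(urban_factor, "urban_factor", 0, Inf, open_lower = TRUE)
  .assertScalarNumber(price_per_ton, "price_per_ton", 0, Inf, open_lower = TRUE)
  structure(list(carbon_fraction = carbon_fraction, urban_factor = urban_factor,
                 price_per_ton = price_per_ton), class = "CarbonConfig")
}

# resolve the coefficient rows for a key, falling back to the wood type
.resolveKey <- function(coeffs, key, wood_type = NA_character_) {
  if (!is.na(key) && key %in% coeffs$allometric_key) return(key)
  if (!is.na(wood_type) && wood_type %in% coeffs$allometric_key) return(wood_type)
  stop("no allometric coefficients for key '", key, "' and no wood-type fallback",
       call. = FALSE)
}

#' Aboveground biomass by compartment
#'
#' Evaluates the power law `beta1 * dbh^beta2` for each of the three
#' compartments (wood, bark, branches) and sums them into the aboveground dry
#' biomass. Error terms of the underlying regressions are taken as zero, so
#' the compartment predictions add up exactly.
#'
#' @param dbh diameter at breast height, cm, > 0.
#' @param coeffs an `"AllometricCoefficients"` table.
#' @param key allometric key; unknown keys fall back via `wood_type`.
#' @param wood_type optional `"softwood"`/`"hardwood"` fallback.
#' @return Named list: `wood`, `bark`, `branches`, `aboveground` (kg dry
#'   biomass).
#' @export
#' @examples
#' compartmentBiomass(20, defaultAllometry(), "hardwood")
compartmentBiomass <- function(dbh, coeffs, key, wood_type = NA_character_) {
  .assertScalarNumber(dbh, "dbh", 0, Inf, open_lower = TRUE)
  key <- .resolveKey(coeffs, key, wood_type)
  rows <- coeffs[coeffs$allometric_key == key, , drop = FALSE]
  comp <- stats::setNames(rows$beta1 * dbh^rows$beta2, rows$compartment)
  for (j in c("wood", "bark", "branches"))
    if (!j %in% names(comp)) comp[[j]] <- 0
  out <- as.list(comp[c("wood", "bark", "branches")])
  out$aboveground <- sum(comp)
  out
}

#' Root biomass from aboveground biomass
#'
#' Softwoods: `0.222 * AB`; hardwoods: `1.576 * AB^0.615` (kg dry biomass).
#'
#' @param aboveground aboveground dry biomass, kg, >= 0.
#' @param wood_type `"softwood"` or `"hardwood"`.
#' @return Root dry biomass, kg.
#' @export
#' @examples
#' rootBiomass(100, "softwood")  # 22.2
rootBiomass <- function(aboveground, wood_type) {
  .assertScalarNumber(aboveground, "aboveground", 0)
  switch(wood_type,
         softwood = 0.222 * aboveground,
         hardwood = 1.576 * aboveground^0.615,
         stop("wood_type must be 'softwood' or 'hardwood'", call. = FALSE))
}

#' Full biomass chain for one stem
#'
#' Aboveground compartments, root biomass, their total, and the open-grown
#' ("urban") corrected biomass `urban_factor * total`.
#'
#' @inheritParams compartmentBiomass
#' @param wood_type `"softwood"` or `"hardwood"` (drives the root equation
#'   and the coefficient fallback).
#' @param cfg a [carbonConfig()].
#' @return Named list with `wood`, `bark`, `branches`, `aboveground`,
#'   `root`, `total`, `urban` (kg dry biomass).
#' @export
biomassEstimate <- function(dbh, coeffs, key, wood_type, cfg = carbonConfig()) {
  ab <- compartmentBiomass(dbh, coeffs, key, wood_type)
  ab$root <- rootBiomass(ab$aboveground, wood_type)
  ab$total <- ab$aboveground + ab$root
  ab$urban <- cfg$urban_factor * ab$total
  ab
}

#' Carbon storage and monetary value of one tree
#'
#' Carbon mass is `carbon_fraction * urban_factor * (aboveground + root)`;
#' its monetary value is `carbon_kg / 1000 * price_per_ton` CAD (unrounded;
#' reports round to whole CAD). Trees without a DBH cannot be estimated and
#' return `NULL`; the inventory-level wrapper counts them as skipped.
#'
#' @param tree single-row tree `data.frame` (as in [treeData()]) or a list
#'   with `dbh`, `wood_type` and optionally `species`.
#' @param coeffs an `"AllometricCoefficients"` table.
#' @param cfg a [carbonConfig()].
#' @param catalog optional [SpeciesCatalog-class] used to resolve the
#'   allometric key and wood type from the species.
#' @return Named list `carbon_kg`, `value_cad`, or `NULL` when the DBH is
#'   missing.
#' @export
treeCarbon <- function(tree, coeffs, cfg = carbonConfig(), catalog = NULL) {
  dbh <- tree$dbh
  if (is.null(dbh) || is.na(dbh)) return(NULL)
  key <- NA_character_
  wood <- tree$wood_type %||% NA_character_
  if (!is.null(catalog) && !is.null(tree$species) && !is.na(tree$species)) {
    en <- catalogEntries(catalog)
    i <- match(tree$species, en$species)
    if (!is.na(i)) {
      key <- en$allometric_key[i]
      if (is.na(wood)) wood <- en$wood_type[i]
    }
  }
  if (is.na(key) && !is.null(tree$species) && !is.na(tree$species) &&
      tree$species %in% coeffs$allometric_key)
    key <- tree$species
  if (is.na(wood)) return(NULL)
  bio <- biomassEstimate(dbh, coeffs, key, wood, cfg)
  carbon <- cfg$carbon_fraction * bio$urban
  list(carbon_kg = carbon, value_cad = carbon / 1000 * cfg$price_per_ton)
}

#' Carbon storage and monetary value of an inventory
#'
#' Sums per-tree carbon over all trees with a DBH and a resolvable wood type;
#' the others are counted as skipped. The monetary value is computed on the
#' summed carbon; `value_cad_rounded` rounds it to whole CAD for reporting.
#'
#' @param inv a [TreeInventory-class].
#' @param coeffs an `"AllometricCoefficients"` table.
#' @param cfg a [carbonConfig()].
#' @param catalog optional [SpeciesCatalog-class] to resolve keys/wood types.
#' @return Named list `carbon_kg`, `value_cad`, `value_cad_rounded`,
#'   `n_included`, `n_skipped`.
#' @export
#' @examples
#' inv <- generateSyntheticInventory(20, defaultCatalog(), seed = 7)
#' inventoryCarbon(inv, defaultAllometry(), catalog = defaultCatalog())
inventoryCarbon <- function(inv, coeffs, cfg = carbonConfig(), catalog = NULL) {
  stopifnot(is(inv, "TreeInventory"))
  tr <- inv@trees
  carbon <- 0
  skipped <- 0L
  for (i in seq_len(nrow(tr))) {
    est <- treeCarbon(tr[i, ], coeffs, cfg, catalog)
    if (is.null(est)) skipped <- skipped + 1L else carbon <- carbon + est$carbon_kg
  }
  value <- carbon / 1000 * cfg$price_per_ton
  list(carbon_kg = carbon, value_cad = value,
       value_cad_rounded = roundHalfAway(value),
       n_included = nrow(tr) - skipped, n_skipped = skipped)
}
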