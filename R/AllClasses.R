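#' @import methods
NULL

#' The ten functional groups
#'
#' Labels of the ten functional groups used to classify urban tree species by
#' shared trait profiles (two conifer groups 1A/1B, tall broadleaves 2A/2B/2C,
#' small and medium broadleaves 3A/3B, large-seeded 4A/4B, pioneers 5).
#'
#' @return Character vector of the ten group labels.
#' @export
#' @examples
#' functionalGroups()
functionalGroups <- function() {
  c("1A", "1B", "2A", "2B", "2C", "3A", "3B", "4A", "4B", "5")
}

# canonical columns of the tree table; order is the storage order
.TREE_COLUMNS <- c("tree_id", "species", "genus", "family",
                   "functional_group", "wood_type", "dbh",
                   "planted_date", "measured_date",
                   "lat", "lon", "location_type")

.LOCATION_TYPES <- c("street", "park", "other")

#' TreeInventory: a set of inventoried urban trees
#'
#' S4 container for an urban tree inventory: one row per stem with taxonomy
#' (species, genus, family), functional group, wood type, diameter at breast
#' height (DBH, cm), planting/measurement dates, WGS84 coordinates and
#' location type. Missing values are allowed everywhere except `tree_id`,
#' which must be unique. Build objects with [TreeInventory()] or
#' [readInventory()].
#'
#' @slot trees `data.frame` with the canonical tree columns.
#' @slot provenance character scalar describing where the trees came from.
#'
#' @seealso [readInventory()], [generateSyntheticInventory()],
#'   [selectRegion()], [abundance()]
#' @export
setClass("TreeInventory",
  representation(trees = "data.frame", provenance = "character"),
  prototype(trees = data.frame(), provenance = "unspecified"))

setValidity("TreeInventory", function(object) {
  tr <- object@trees
  msgs <- character()
  if (nrow(tr) > 0) {
    missing_cols <- setdiff(.TREE_COLUMNS, names(tr))
    if (length(missing_cols))
      return(paste("missing tree columns:", paste(missing_cols, collapse = ", ")))
    if (anyDuplicated(tr$tree_id))
      msgs <- c(msgs, "tree_id values must be unique")
    dbh <- tr$dbh[!is.na(tr$dbh)]
    if (any(dbh <= 0))
      msgs <- c(msgs, "dbh, when present, must be > 0")
    fg <- tr$functional_group[!is.na(tr$functional_group)]
    if (!all(fg %in% functionalGroups()))
      msgs <- c(msgs, "functional_group must be one of the ten group labels")
    lat <- tr$lat[!is.na(tr$lat)]
    lon <- tr$lon[!is.na(tr$lon)]
    if (any(lat < -90 | lat > 90)) msgs <- c(msgs, "lat must lie in [-90, 90]")
    if (any(lon < -180 | lon > 180)) msgs <- c(msgs, "lon must lie in [-180, 180]")
  }
  if (length(object@provenance) != 1)
    msgs <- c(msgs, "provenance must be a single string")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a TreeInventory
#'
#' Builds a [TreeInventory-class] object from per-tree vectors. All arguments
#' other than `species` are optional; missing fields are filled with `NA`.
#' When `catalog` is supplied, genus, family, functional group and wood type
#' are looked up from it for any tree whose value is missing.
#'
#' @param species character vector of scientific names (may contain `NA`).
#' @param dbh numeric vector, diameter at breast height in cm (`NA` allowed,
#'   positive otherwise).
#' @param lat,lon numeric WGS84 coordinates in degrees.
#' @param genus,family character taxonomy vectors.
#' @param functional_group character vector of group labels (see
#'   [functionalGroups()]).
#' @param wood_type `"softwood"` or `"hardwood"`.
#' @param tree_id identifiers; defaults to `"t1"`, `"t2"`, ...
#' @param planted_date,measured_date `Date` vectors or parseable strings.
#' @param location_type `"street"`, `"park"` or `"other"`.
#' @param catalog optional [SpeciesCatalog-class] used to fill missing
#'   taxonomy.
#' @param provenance source description stored with the object.
#' @return A [TreeInventory-class] object.
#' @export
#' @examples
#' inv <- TreeInventory(species = c("Acer saccharum", "Acer saccharum",
#'                                  "Quercus rubra"),
#'                      dbh = c(20, 35, 50),
#'                      functional_group = c("2A", "2A", "4A"))
#' nTrees(inv)
TreeInventory <- function(species, dbh = NA_real_, lat = NA_real_,
                          lon = NA_real_, genus = NA_character_,
                          family = NA_character_,
                          functional_group = NA_character_,
                          wood_type = NA_character_,
                          tree_id = NULL,
                          planted_date = as.Date(NA),
                          measured_date = as.Date(NA),
                          location_type = NA_character_,
                          catalog = NULL,
                          provenance = "constructed") {
  n <- length(species)
  if (is.null(tree_id)) tree_id <- if (n) paste0("t", seq_len(n)) else character()
  tr <- data.frame(
    tree_id = as.character(tree_id),
    species = as.character(species),
    genus = rep_len(as.character(genus), n),
    family = rep_len(as.character(family), n),
    functional_group = rep_len(as.character(functional_group), n),
    wood_type = rep_len(as.character(wood_type), n),
    dbh = rep_len(as.numeric(dbh), n),
    planted_date = rep_len(as.Date(planted_date), n),
    measured_date = rep_len(as.Date(measured_date), n),
    lat = rep_len(as.numeric(lat), n),
    lon = rep_len(as.numeric(lon), n),
    location_type = rep_len(as.character(location_type), n),
    stringsAsFactors = FALSE
  )
  if (n == 0) tr <- .emptyTreeTable()
  if (!is.null(catalog)) tr <- .fillTaxonomy(tr, catalog, warn = FALSE)
  new("TreeInventory", trees = tr, provenance = provenance)
}

.emptyTreeTable <- function() {
  data.frame(
    tree_id = character(), species = character(), genus = character(),
    family = character(), functional_group = character(),
    wood_type = character(), dbh = numeric(),
    planted_date = as.Date(character()), measured_date = as.Date(character()),
    lat = numeric(), lon = numeric(), location_type = character(),
    stringsAsFactors = FALSE
  )
}

#' SpeciesCatalog: reference table of plantable and inventoried species
#'
#' S4 container mapping each scientific name to its genus, family, functional
#' group, wood type, allometric key (a species-specific coefficient key or the
#' `"hardwood"`/`"softwood"` fallback), a candidate flag (eligible for
#' planting recommendation) and an exclusion flag with a reason (invasive or
#' pest-affected species are never candidates).
#'
#' @slot entries `data.frame` keyed by `species`.
#' @seealso [SpeciesCatalog()], [readSpeciesCatalog()], [defaultCatalog()]
#' @export
setClass("SpeciesCatalog",
  representation(entries = "data.frame"),
  prototype(entries = data.frame()))

setValidity("SpeciesCatalog", function(object) {
  en <- object@entries
  need <- c("species", "genus", "family", "functional_group", "wood_type",
            "allometric_key", "candidate", "excluded", "exclusion_reason")
  missing_cols <- setdiff(need, names(en))
  if (length(missing_cols))
    return(paste("missing catalog columns:", paste(missing_cols, collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(en$species))
    msgs <- c(msgs, "species must be unique within a catalog")
  if (any(en$candidate & en$excluded))
    msgs <- c(msgs, "excluded species can never be candidates")
  cand <- en[en$candidate, , drop = FALSE]
  if (any(is.na(cand$functional_group)) || any(is.na(cand$allometric_key)))
    msgs <- c(msgs, "every candidate needs a functional_group and an allometric_key")
  fg <- en$functional_group[!is.na(en$functional_group)]
  if (!all(fg %in% functionalGroups()))
    msgs <- c(msgs, "functional_group must be one of the ten group labels")
  wt <- en$wood_type[!is.na(en$wood_type)]
  if (!all(wt %in% c("softwood", "hardwood")))
    msgs <- c(msgs, "wood_type must be 'softwood' or 'hardwood'")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a SpeciesCatalog
#'
#' @param species character vector of scientific names (unique).
#' @param genus,family taxonomy.
#' @param functional_group group labels (see [functionalGroups()]).
#' @param wood_type `"softwood"` or `"hardwood"`.
#' @param allometric_key coefficient-table key; defaults to the wood type
#'   (the fallback rows every coefficient table carries).
#' @param candidate logical, eligible for planting recommendation.
#' @param excluded logical; `exclusion_reason` says why (e.g. `"invasive"`,
#'   `"pest"`). Excluded species are forced out of the candidate set.
#' @param exclusion_reason character.
#' @return A [SpeciesCatalog-class] object.
#' @export
SpeciesCatalog <- function(species, genus, family, functional_group,
                           wood_type, allometric_key = wood_type,
                           candidate = TRUE, excluded = FALSE,
                           exclusion_reason = NA_character_) {
  n <- length(species)
  en <- data.frame(
    species = as.character(species),
    genus = rep_len(as.character(genus), n),
    family = rep_len(as.character(family), n),
    functional_group = rep_len(as.character(functional_group), n),
    wood_type = rep_len(as.character(wood_type), n),
    allometric_key = rep_len(as.character(allometric_key), n),
    candidate = rep_len(as.logical(candidate), n),
    excluded = rep_len(as.logical(excluded), n),
    exclusion_reason = rep_len(as.character(exclusion_reason), n),
    stringsAsFactors = FALSE
  )
  en$candidate <- en$candidate & !en$excluded
  new("SpeciesCatalog", entries = en)
}

# ---- accessors -------------------------------------------------------------

#' Number of trees in an inventory
#' @param x a [TreeInventory-class].
#' @return integer count.
#' @export
nTrees <- function(x) {
  stopifnot(is(x, "TreeInventory"))
  nrow(x@trees)
}

#' Tree table of an inventory
#' @param x a [TreeInventory-class].
#' @return the underlying `data.frame`, one row per tree.
#' @export
treeData <- function(x) {
  stopifnot(is(x, "TreeInventory"))
  x@trees
}

#' Provenance string of an inventory
#' @param x a [TreeInventory-class].
#' @return character scalar.
#' @export
provenance <- function(x) {
  stopifnot(is(x, "TreeInventory"))
  x@provenance
}

#' Entries of a species catalog
#' @param x a [SpeciesCatalog-class].
#' @return the underlying `data.frame`, one row per species.
#' @export
catalogEntries <- function(x) {
  stopifnot(is(x, "SpeciesCatalog"))
  x@entries
}

setMethod("show", "TreeInventory", function(object) {
  tr <- object@trees
  cat("TreeInventory with", nrow(tr), "trees\n")
  cat("  provenance:", object@provenance, "\n")
  if (nrow(tr)) {
    cat("  species:", length(unique(stats::na.omit(tr$species))),
        " functional groups:",
        length(unique(stats::na.omit(tr$functional_group))), "\n")
    dbh <- tr$dbh
    cat("  dbh (cm): present for", sum(!is.na(dbh)), "trees")
    if (any(!is.na(dbh)))
      cat(sprintf(", median %.1f", stats::median(dbh, na.rm = TRUE)))
    cat("\n")
  }
  invisible(object)
})

setMethod("show", "SpeciesCatalog", function(object) {
  en <- object@entries
  cat("SpeciesCatalog with", nrow(en), "species;",
      sum(en$candidate), "candidates,", sum(en$excluded), "excluded\n")
  invisible(object)
})
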