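#' Column maps for inventory CSV dialects
#'
#' A column map is a named character vector translating the canonical tree
#' fields to the column headers of a CSV dialect. `genericColumnMap()` is the
#' identity mapping (headers already canonical); `montrealColumnMap()` covers
#' the Montreal open-data street/park tree inventory headers.
#'
#' @return Named character vector, names are canonical fields, values are the
#'   file's column names.
#' @export
#' @examples
#' montrealColumnMap()
genericColumnMap <- function() {
  stats::setNames(.TREE_COLUMNS, .TREE_COLUMNS)
}

#' @rdname genericColumnMap
#' @export
montrealColumnMap <- function() {
  c(tree_id = "EMP_NO",
    species = "Essence_latin",
    dbh = "DHP",
    planted_date = "Date_Plantation",
    measured_date = "Date_Releve",
    lat = "Latitude",
    lon = "Longitude",
    location_type = "EMPLACEMENT")
}

#' Read a tree inventory from CSV
#'
#' Parses a one-row-per-tree CSV into a [TreeInventory-class]. The column map
#' adapts the reader to a dialect; only `species` and `dbh` mappings are
#' required. Rows with unparseable numbers or dates keep the tree and flag the
#' field as missing; row order is preserved. When a [SpeciesCatalog-class] is
#' given, missing genus, family, functional group and wood type are filled
#' from it; species absent from the catalog with no taxonomy columns in the
#' file trigger a per-row warning, and the tree is kept without a functional
#' group.
#'
#' @param path CSV file (UTF-8, comma separated, header row).
#' @param column_map named character vector, see [genericColumnMap()].
#' @param catalog optional [SpeciesCatalog-class].
#' @return A [TreeInventory-class]; provenance records the file name.
#' @export
readInventory <- function(path, column_map = genericColumnMap(),
                          catalog = NULL) {
  if (!file.exists(path)) stop("cannot read inventory file: ", path, call. = FALSE)
  need <- c("species", "dbh")
  if (!all(need %in% names(column_map)))
    stop("column_map must cover at least: ", paste(need, collapse = ", "),
         call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  n <- nrow(raw)
  get_col <- function(field, default) {
    src <- if (field %in% names(column_map)) column_map[[field]] else NA
    if (!is.na(src) && src %in% names(raw)) raw[[src]] else rep(default, n)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  dat <- function(x) suppressWarnings(as.Date(as.character(x)))
  tr <- data.frame(
    tree_id = {
      id <- as.character(get_col("tree_id", NA_character_))
      if (all(is.na(id)) || anyDuplicated(stats::na.omit(id)))
        id <- if (n) paste0("t", seq_len(n)) else character()
      id
    },
    species = as.character(get_col("species", NA_character_)),
    genus = as.character(get_col("genus", NA_character_)),
    family = as.character(get_col("family", NA_character_)),
    functional_group = as.character(get_col("functional_group", NA_character_)),
    wood_type = as.character(get_col("wood_type", NA_character_)),
    dbh = num(get_col("dbh", NA_real_)),
    planted_date = dat(get_col("planted_date", NA)),
    measured_date = dat(get_col("measured_date", NA)),
    lat = num(get_col("lat", NA_real_)),
    lon = num(get_col("lon", NA_real_)),
    location_type = as.character(get_col("location_type", NA_character_)),
    stringsAsFactors = FALSE
  )
  if (n == 0) tr <- .emptyTreeTable()
  tr$species[!is.na(tr$species) & !nzchar(trimws(tr$species))] <- NA_character_
  tr$dbh[!is.na(tr$dbh) & tr$dbh <= 0] <- NA_real_
  tr$lat[!is.na(tr$lat) & (tr$lat < -90 | tr$lat > 90)] <- NA_real_
  tr$lon[!is.na(tr$lon) & (tr$lon < -180 | tr$lon > 180)] <- NA_real_
  bad_fg <- !is.na(tr$functional_group) &
    !(tr$functional_group %in% functionalGroups())
  tr$functional_group[bad_fg] <- NA_character_
  if (!is.null(catalog)) tr <- .fillTaxonomy(tr, catalog, warn = TRUE)
  new("TreeInventory", trees = tr, provenance = paste0("file:", basename(path)))
}

# fill missing taxonomy columns from the catalog, by species
.fillTaxonomy <- function(tr, catalog, warn = FALSE) {
  en <- catalogEntries(catalog)
  idx <- match(tr$species, en$species)
  for (field in c("genus", "family", "functional_group", "wood_type")) {
    fill <- is.na(tr[[field]]) & !is.na(idx)
    tr[[field]][fill] <- en[[field]][idx[fill]]
  }
  if (warn) {
    orphan <- !is.na(tr$species) & is.na(idx) & is.na(tr$genus) & is.na(tr$family)
    if (any(orphan))
      warning(sum(orphan), " tree(s) with species absent from the catalog and ",
              "no taxonomy columns; kept without functional group",
              call. = FALSE)
  }
  tr
}

#' Select the trees inside a geographic region
#'
#' Keeps trees whose WGS84 point lies inside or on the boundary of the region.
#' Trees without coordinates are dropped from the selection. The region may be
#' a bounding box (`c(minlon, minlat, maxlon, maxlat)` or the equivalent
#' comma-separated string), a two-column `(lon, lat)` polygon matrix, or a
#' path to a GeoJSON file containing a Polygon.
#'
#' @param inv a [TreeInventory-class].
#' @param region region specification, see Details.
#' @return A [TreeInventory-class] subset; provenance records the region.
#' @export
#' @examples
#' inv <- TreeInventory(species = c("a", "b"), lat = c(1, 10), lon = c(1, 10))
#' nTrees(selectRegion(inv, c(0, 0, 5, 5)))
selectRegion <- function(inv, region) {
  stopifnot(is(inv, "TreeInventory"))
  poly <- .asRegionPolygon(region)
  tr <- inv@trees
  keep <- if (nrow(tr)) .pointInPolygon(tr$lon, tr$lat, poly) else logical()
  desc <- sprintf("region[%s] of (%s)",
                  paste(sprintf("%.6g", as.vector(t(poly[1:min(2, nrow(poly)), ]))),
                        collapse = ","),
                  inv@provenance)
  new("TreeInventory", trees = tr[keep, , drop = FALSE], provenance = desc)
}

#' Abundance distribution at a taxonomic or functional level
#'
#' Counts trees per category at one of the four levels. Trees with the field
#' missing are omitted; zero-count categories are not reported, so the counts
#' sum to the number of trees carrying the field.
#'
#' @param inv a [TreeInventory-class].
#' @param level one of `"species"`, `"genus"`, `"family"`,
#'   `"functional_group"`.
#' @return Named integer vector of counts, decreasing, with attribute
#'   `"total"` (the sum) and `"level"`.
#' @export
#' @examples
#' inv <- TreeInventory(species = c("A", "A", "B"))
#' abundance(inv, "species")
abundance <- function(inv, level = c("species", "genus", "family",
                                     "functional_group")) {
  stopifnot(is(inv, "TreeInventory"))
  level <- match.arg(level)
  vals <- inv@trees[[level]]
  vals <- vals[!is.na(vals)]
  tab <- table(vals)
  counts <- sort(stats::setNames(as.integer(tab), names(tab)),
                 decreasing = TRUE)
  structure(counts, total = sum(counts), level = level)
}

#' Configuration for max-DBH thresholds
#'
#' @param percentile percentile of a species' DBH distribution taken as its
#'   "max DBH" (default 95, in (0, 100)).
#' @param min_cohort minimum number of measured trees for a species-level
#'   percentile (default 150); smaller cohorts fall back to the unweighted
#'   mean of same-genus species thresholds.
#' @return A list with class `"MaxDbhConfig"`.
#' @export
maxDbhConfig <- function(percentile = 95, min_cohort = 150) {
  .assertScalarNumber(percentile, "percentile", 0, 100,
                      open_lower = TRUE, open_upper = TRUE)
  .assertScalarNumber(min_cohort, "min_cohort", 1)
  structure(list(percentile = percentile, min_cohort = as.integer(min_cohort)),
            class = "MaxDbhConfig")
}

#' Species max-DBH thresholds from a reference inventory
#'
#' For each species with at least `min_cohort` measured trees, the threshold
#' is the configured percentile (linear interpolation between order
#' statistics) of its DBH values; these thresholds serve as a proxy for
#' identifying old trees. Species with smaller cohorts receive the unweighted
#' mean of the thresholds of same-genus species; species with no genus-level
#' fallback are omitted.
#'
#' @param reference a [TreeInventory-class] (typically a large pooled
#'   reference inventory).
#' @param cfg a [maxDbhConfig()].
#' @return Named numeric vector, species to threshold DBH (cm).
#' @export
maxDbhThresholds <- function(reference, cfg = maxDbhConfig()) {
  stopifnot(is(reference, "TreeInventory"), inherits(cfg, "MaxDbhConfig"))
  tr <- reference@trees
  tr <- tr[!is.na(tr$species) & !is.na(tr$dbh), , drop = FALSE]
  if (nrow(tr) == 0) return(stats::setNames(numeric(), character()))
  by_sp <- split(tr$dbh, tr$species)
  big <- names(by_sp)[vapply(by_sp, length, 0L) >= cfg$min_cohort]
  thr <- vapply(by_sp[big], .percentile, numeric(1), p = cfg$percentile)
  # genus fallback: mean of species-level thresholds within the genus
  genus_of <- vapply(split(tr$genus, tr$species),
                     function(g) {
                       g <- stats::na.omit(g)
                       if (length(g)) g[[1]] else NA_character_
                     }, character(1))
  small <- setdiff(names(by_sp), big)
  for (sp in small) {
    g <- genus_of[[sp]]
    if (is.na(g)) next
    sibs <- big[genus_of[big] %in% g]
    if (length(sibs)) thr[[sp]] <- mean(thr[sibs])
  }
  thr[order(names(thr))]
}

#' Flag old trees and summarise them by functional group
#'
#' A tree is flagged "old" when its DBH is at or above its species threshold
#' (the threshold is itself a high-percentile observation, so the boundary is
#' inclusive). Trees without a threshold or without a DBH are left unflagged.
#' Two functional-group summaries are returned: the share of each group among
#' old trees (sums to 1 over old trees) and, for context, the proportion of
#' old trees within each group.
#'
#' @param inv a [TreeInventory-class].
#' @param thresholds named numeric vector from [maxDbhThresholds()].
#' @return List with `flags` (logical per tree, named by tree_id),
#'   `share_of_old` (named numeric per functional group) and
#'   `old_within_group` (named numeric per functional group).
#' @export
oldTreeFlags <- function(inv, thresholds) {
  stopifnot(is(inv, "TreeInventory"))
  tr <- inv@trees
  thr <- unname(thresholds[match(tr$species, names(thresholds))])
  flags <- !is.na(tr$dbh) & !is.na(thr) & tr$dbh >= thr
  names(flags) <- tr$tree_id
  fg_old <- tr$functional_group[flags]
  fg_old <- fg_old[!is.na(fg_old)]
  share <- if (length(fg_old)) {
    tab <- table(fg_old)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  } else stats::setNames(numeric(), character())
  within_group <- vapply(
    split(flags, tr$functional_group)[unique(stats::na.omit(tr$functional_group))],
    mean, numeric(1))
  list(flags = flags, share_of_old = share, old_within_group = within_group)
}

#' Write an inventory to normalized CSV
#'
#' Writes the canonical tree table (canonical headers, UTF-8, comma
#' separated). Reading the file back with [readInventory()] and the default
#' column map reproduces the inventory.
#'
#' @param inv a [TreeInventory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeInventory <- function(inv, path) {
  stopifnot(is(inv, "TreeInventory"))
  utils::write.csv(inv@trees, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Export inventory points as GeoJSON
#'
#' Writes a `FeatureCollection` of Point features (WGS84) with the tree
#' attributes as properties. Trees without coordinates are skipped.
#'
#' @param inv a [TreeInventory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportGeoJSON <- function(inv, path) {
  stopifnot(is(inv, "TreeInventory"))
  tr <- inv@trees
  tr <- tr[!is.na(tr$lat) & !is.na(tr$lon), , drop = FALSE]
  features <- lapply(seq_len(nrow(tr)), function(i) {
    row <- tr[i, ]
    props <- as.list(row[setdiff(names(row), c("lat", "lon"))])
    props <- lapply(props, function(v) if (is.na(v)) NULL else as.character(v))
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(row$lon, row$lat)),
         properties = props[!vapply(props, is.null, logical(1))])
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
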