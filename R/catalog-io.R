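#' Read a species catalog from CSV or YAML
#'
#' CSV: one row per species with columns `species`, `genus`, `family`,
#' `functional_group`, `wood_type`, `allometric_key`, `candidate`,
#' `excluded`, `exclusion_reason` (the last three optional). YAML: a list of
#' mappings with the same fields.
#'
#' @param path catalog file.
#' @return A [SpeciesCatalog-class].
#' @export
readSpeciesCatalog <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("yml", "yaml")) {
    rows <- yaml::read_yaml(path)
    do.call(rbind, lapply(rows, function(r) data.frame(
      species = r$species, genus = r$genus %||% NA, family = r$family %||% NA,
      functional_group = r$functional_group %||% NA,
      wood_type = r$wood_type %||% NA,
      allometric_key = r$allometric_key %||% r$wood_type %||% NA,
      candidate = isTRUE(r$candidate %||% TRUE),
      excluded = isTRUE(r$excluded %||% FALSE),
      exclusion_reason = r$exclusion_reason %||% NA,
      stringsAsFactors = FALSE)))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  }
  if (is.null(tab$allometric_key)) tab$allometric_key <- tab$wood_type
  if (is.null(tab$candidate)) tab$candidate <- TRUE
  if (is.null(tab$excluded)) tab$excluded <- FALSE
  if (is.null(tab$exclusion_reason)) tab$exclusion_reason <- NA_character_
  tab$functional_group[!is.na(tab$functional_group) &
                         !nzchar(tab$functional_group)] <- NA_character_
  tab$exclusion_reason[!is.na(tab$exclusion_reason) &
                         !nzchar(tab$exclusion_reason)] <- NA_character_
  with(tab, SpeciesCatalog(
    species = species, genus = genus, family = family,
    functional_group = functional_group, wood_type = wood_type,
    allometric_key = allometric_key,
    candidate = as.logical(candidate) & !as.logical(excluded),
    excluded = as.logical(excluded), exclusion_reason = exclusion_reason))
}

#' Default species catalog shipped with the package
#'
#' A compact catalog of common northeastern North American urban tree
#' species covering all ten functional groups, with the usual exclusions
#' (invasive buckthorns; ash and butternut, severely affected by pests).
#'
#' @return A [SpeciesCatalog-class].
#' @export
defaultCatalog <- function() {
  readSpeciesCatalog(system.file("extdata", "species_catalog.csv",
                                 package = "CanopyPlan", mustWork = TRUE))
}
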