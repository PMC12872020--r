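#' Recommendation criteria and weights
#'
#' Five criteria drive the score of a candidate species: functional-group
#' diversity and functional-group richness carry a fixed weight of 10 each
#' (diversifying functional groups is the system's non-negotiable goal);
#' species diversity, species richness and carbon storage carry user weights
#' in `[1, 10]`. Planted trees are assumed to have a fixed DBH (default
#' 15 cm, a standard nursery-stock assumption reflecting current inventory
#' averages).
#'
#' @param w_sp_diversity,w_sp_richness,w_carbon user weights in `[1, 10]`.
#' @param included_groups functional groups from which species may be
#'   recommended (default: all ten).
#' @param new_tree_dbh assumed DBH of a newly planted tree, cm.
#' @return A list with class `"RecommendationCriteria"`; elements
#'   `w_fg_diversity` and `w_fg_richness` are fixed at 10.
#' @export
recommendationCriteria <- function(w_sp_diversity = 5, w_sp_richness = 5,
                                   w_carbon = 5,
                                   included_groups = functionalGroups(),
                                   new_tree_dbh = 15) {
  for (nm in c("w_sp_diversity", "w_sp_richness", "w_carbon"))
    .assertScalarNumber(get(nm), nm, 1, 10)
  .assertScalarNumber(new_tree_dbh, "new_tree_dbh", 0, Inf, open_lower = TRUE)
  included_groups <- as.character(included_groups)
  if (length(included_groups) == 0 ||
      !all(included_groups %in% functionalGroups()))
    stop("included_groups must be a nonempty subset of functionalGroups()",
         call. = FALSE)
  structure(list(w_fg_diversity = 10, w_fg_richness = 10,
                 w_sp_diversity = w_sp_diversity,
                 w_sp_richness = w_sp_richness, w_carbon = w_carbon,
                 included_groups = included_groups,
                 new_tree_dbh = new_tree_dbh),
            class = "RecommendationCriteria")
}

#' Filter plantable candidate species
#'
#' Keeps catalog species that are flagged as candidates, not excluded
#' (invasive or pest-affected species never pass), belong to an included
#' functional group, and whose hypothetical addition of a single tree keeps
#' the inventory within the composition rule: the post-addition shares
#' `(count+1)/(n+1)` at the species, genus and family levels must not exceed
#' their caps. On an empty inventory every eligible catalog candidate passes.
#'
#' @param inv a [TreeInventory-class].
#' @param catalog a [SpeciesCatalog-class].
#' @param thresholds a [ruleThresholds()].
#' @param criteria a [recommendationCriteria()].
#' @return Character vector of candidate scientific names (catalog order).
#' @export
filterCandidates <- function(inv, catalog,
                             thresholds = ruleThresholds("10-20-30"),
                             criteria = recommendationCriteria()) {
  stopifnot(is(inv, "TreeInventory"), is(catalog, "SpeciesCatalog"))
  en <- catalogEntries(catalog)
  en <- en[en$candidate & !en$excluded &
             en$functional_group %in% criteria$included_groups, , drop = FALSE]
  if (nrow(en) == 0) return(character())
  caps <- c(species = thresholds$species_max, genus = thresholds$genus_max,
            family = thresholds$family_max)
  counts <- lapply(c(species = "species", genus = "genus", family = "family"),
                   function(lv) abundance(inv, lv))
  keep <- vapply(seq_len(nrow(en)), function(i) {
    for (lv in names(caps)) {
      tab <- counts[[lv]]
      n <- attr(tab, "total") %||% 0L
      if (n == 0) next  # no proportions to violate
      cat_val <- en[[lv]][i]
      have <- if (!is.na(cat_val) && cat_val %in% names(tab)) tab[[cat_val]] else 0L
      if ((have + 1) / (n + 1) > caps[[lv]]) return(FALSE)
    }
    TRUE
  }, logical(1))
  en$species[keep]
}

#' Relative improvement of a metric
#'
#' The improvement rate caused by an addition is `n1 / n0 - 1`: the relative
#' change of the metric (an effective number, a richness count, or a carbon
#' total) from its value before (`n0 > 0`) to its value after (`n1`).
#'
#' @param before metric value before the addition (> 0).
#' @param after metric value after the addition.
#' @return List `n0`, `n1`, `m` (the rate) and `percent`
#'   (`m * 100` rounded half away from zero to 1 decimal).
#' @export
#' @examples
#' improvement(40, 50)$percent  # 25.0
improvement <- function(before, after) {
  .assertScalarNumber(after, "after")
  if (!is.numeric(before) || length(before) != 1 || is.na(before) || before <= 0)
    stop("improvement is undefined for a baseline <= 0", call. = FALSE)
  m <- after / before - 1
  list(n0 = before, n1 = after, m = m, percent = roundHalfAway(100 * m, 1))
}

# per-candidate incremental metrics; shared by scoreCandidates
.candidateRates <- function(sp_counts, fg_counts, carbon0, sp, fg, carbon_add) {
  n_sp <- sum(sp_counts)
  new_sp <- c(sp_counts, stats::setNames(0L, sp)[setdiff(sp, names(sp_counts))])
  new_sp[sp] <- new_sp[sp] + 1L
  new_fg <- c(fg_counts, stats::setNames(0L, fg)[setdiff(fg, names(fg_counts))])
  new_fg[fg] <- new_fg[fg] + 1L
  ens0 <- shannonEffectiveNumber(sp_counts)
  enfg0 <- shannonEffectiveNumber(fg_counts)
  rates <- c(
    fg_diversity = shannonEffectiveNumber(new_fg) / enfg0 - 1,
    fg_richness = length(new_fg) / length(fg_counts) - 1,
    sp_diversity = shannonEffectiveNumber(new_sp) / ens0 - 1,
    sp_richness = length(new_sp) / length(sp_counts) - 1,
    carbon = if (carbon0 > 0) (carbon0 + carbon_add) / carbon0 - 1 else NA_real_)
  rates
}

#' Score and rank candidate species
#'
#' For each candidate, simulates the addition of one tree of that species at
#' the assumed planting DBH to the inventory and computes the relative
#' improvement of five metrics: effective number of functional groups,
#' functional-group richness, effective number of species, species richness,
#' and inventory carbon storage. The score is the weighted sum of the five
#' rates; candidates are ranked by decreasing score with alphabetical
#' tie-breaking, so the ranking is fully deterministic. A candidate whose
#' carbon cannot be estimated contributes 0 for that criterion and is flagged.
#'
#' @param inv a nonempty [TreeInventory-class] (all baselines must exist).
#' @param candidates character vector from [filterCandidates()].
#' @param catalog a [SpeciesCatalog-class].
#' @param coeffs an `"AllometricCoefficients"` table.
#' @param criteria a [recommendationCriteria()].
#' @param cfg a [carbonConfig()].
#' @return `data.frame`, one row per candidate, sorted: `species`,
#'   `functional_group`, the five rate columns `x_fg_diversity`,
#'   `x_fg_richness`, `x_sp_diversity`, `x_sp_richness`, `x_carbon`,
#'   `carbon_available`, `score`.
#' @export
scoreCandidates <- function(inv, candidates, catalog, coeffs,
                            criteria = recommendationCriteria(),
                            cfg = carbonConfig()) {
  stopifnot(is(inv, "TreeInventory"), is(catalog, "SpeciesCatalog"))
  if (nTrees(inv) == 0)
    stop("scoring requires a nonempty inventory", call. = FALSE)
  sp_counts <- abundance(inv, "species")
  fg_counts <- abundance(inv, "functional_group")
  if (length(sp_counts) == 0 || length(fg_counts) == 0)
    stop("inventory has no species or no functional-group assignments",
         call. = FALSE)
  carbon0 <- inventoryCarbon(inv, coeffs, cfg, catalog)$carbon_kg
  en <- catalogEntries(catalog)
  rows <- lapply(candidates, function(sp) {
    i <- match(sp, en$species)
    if (is.na(i)) stop("candidate not in catalog: ", sp, call. = FALSE)
    fg <- en$functional_group[i]
    new_tree <- list(species = sp, dbh = criteria$new_tree_dbh,
                     wood_type = en$wood_type[i])
    est <- treeCarbon(new_tree, coeffs, cfg, catalog)
    carbon_add <- if (is.null(est)) NA_real_ else est$carbon_kg
    x <- .candidateRates(sp_counts, fg_counts, carbon0, sp, fg,
                         if (is.na(carbon_add)) 0 else carbon_add)
    if (is.na(carbon_add)) x[["carbon"]] <- NA_real_
    carbon_ok <- !is.na(x[["carbon"]])
    w <- c(criteria$w_fg_diversity, criteria$w_fg_richness,
           criteria$w_sp_diversity, criteria$w_sp_richness, criteria$w_carbon)
    xs <- ifelse(is.na(x), 0, x)
    data.frame(species = sp, functional_group = fg,
               x_fg_diversity = x[["fg_diversity"]],
               x_fg_richness = x[["fg_richness"]],
               x_sp_diversity = x[["sp_diversity"]],
               x_sp_richness = x[["sp_richness"]],
               x_carbon = x[["carbon"]],
               carbon_available = carbon_ok,
               score = sum(w * xs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(), functional_group = character(),
                      x_fg_diversity = numeric(), x_fg_richness = numeric(),
                      x_sp_diversity = numeric(), x_sp_richness = numeric(),
                      x_carbon = numeric(), carbon_available = logical(),
                      score = numeric(), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Planting plan from a ranking
#'
#' The number of trees to plant is `fraction` of the inventory size, rounded
#' half away from zero. The budget is split evenly over the `top_k`
#' best-ranked species; the integer remainder is handed out one tree per
#' species from the top of the ranking. With fewer than `top_k` ranked
#' candidates all of them are used.
#'
#' @param inv a [TreeInventory-class].
#' @param ranked ranking from [scoreCandidates()] (nonempty).
#' @param fraction planting budget as a fraction of the current tree count
#'   (default 0.05).
#' @param top_k number of species to allocate across (default 10).
#' @param n_to_plant absolute tree count overriding `fraction` when given.
#' @return List with class `"PlantingPlan"`: `n_to_plant`, `allocation`
#'   (named integer vector, species to count), `fraction`, `top_k`.
#' @export
#' @examples
#' # 5% of 176 trees -> 9 to plant
planPlanting <- function(inv, ranked, fraction = 0.05, top_k = 10,
                         n_to_plant = NULL) {
  stopifnot(is(inv, "TreeInventory"))
  .assertScalarNumber(fraction, "fraction", 0, 1, open_lower = TRUE)
  .assertScalarNumber(top_k, "top_k", 1)
  if (NROW(ranked) == 0) stop("ranking is empty", call. = FALSE)
  n_to_plant <- if (is.null(n_to_plant))
    as.integer(roundHalfAway(fraction * nTrees(inv)))
  else as.integer(.assertScalarNumber(n_to_plant, "n_to_plant", 0))
  species <- if (is.data.frame(ranked)) ranked$species else as.character(ranked)
  k <- min(as.integer(top_k), length(species))
  top <- species[seq_len(k)]
  base <- n_to_plant %/% k
  rem <- n_to_plant %% k
  alloc <- stats::setNames(rep(base, k) + as.integer(seq_len(k) <= rem), top)
  alloc <- alloc[alloc > 0]
  structure(list(n_to_plant = n_to_plant, allocation = alloc,
                 fraction = fraction, top_k = as.integer(top_k)),
            class = "PlantingPlan")
}

# build the planted trees implied by a plan, taxonomy from the catalog
.plantedTrees <- function(plan, catalog, criteria, id_prefix = "new") {
  en <- catalogEntries(catalog)
  species <- rep(names(plan$allocation), times = plan$allocation)
  if (length(species) == 0) return(.emptyTreeTable())
  i <- match(species, en$species)
  if (anyNA(i))
    stop("plan species absent from catalog: ",
         paste(unique(species[is.na(i)]), collapse = ", "), call. = FALSE)
  data.frame(
    tree_id = paste0(id_prefix, seq_along(species)),
    species = species, genus = en$genus[i], family = en$family[i],
    functional_group = en$functional_group[i], wood_type = en$wood_type[i],
    dbh = criteria$new_tree_dbh,
    planted_date = as.Date(NA), measured_date = as.Date(NA),
    lat = NA_real_, lon = NA_real_, location_type = NA_character_,
    stringsAsFactors = FALSE)
}

#' Simulate a planting plan
#'
#' Builds the augmented inventory (planted trees at the assumed DBH, no
#' coordinates), recomputes species and functional-group richness and
#' diversity and the carbon total from scratch, and reports the relative
#' improvements as percentages rounded to one decimal. The input inventory
#' is not modified.
#'
#' @param inv a nonempty [TreeInventory-class].
#' @param plan a [planPlanting()] result.
#' @param catalog a [SpeciesCatalog-class].
#' @param coeffs an `"AllometricCoefficients"` table.
#' @param criteria a [recommendationCriteria()].
#' @param cfg a [carbonConfig()].
#' @return List with class `"SimulationReport"`: `before` and `after`
#'   (each holding the two diversity reports and the carbon summary),
#'   `improvements` (named percents: `sp_richness`, `sp_diversity`,
#'   `fg_richness`, `fg_diversity`, `carbon`), `table` (a `data.frame` in
#'   before/after/improvement column layout), and `augmented` (the
#'   augmented [TreeInventory-class]).
#' @export
simulatePlanting <- function(inv, plan, catalog, coeffs,
                             criteria = recommendationCriteria(),
                             cfg = carbonConfig()) {
  stopifnot(is(inv, "TreeInventory"), inherits(plan, "PlantingPlan"))
  new_rows <- .plantedTrees(plan, catalog, criteria)
  aug <- new("TreeInventory",
             trees = rbind(inv@trees, new_rows),
             provenance = paste0(inv@provenance, " + plan(",
                                 sum(plan$allocation), " trees)"))
  metrics <- function(x) list(
    sp = diversityReport(x, "species"),
    fg = diversityReport(x, "functional_group"),
    carbon = inventoryCarbon(x, coeffs, cfg, catalog))
  before <- metrics(inv)
  after <- metrics(aug)
  pct <- function(b, a) if (!is.na(b) && b > 0) improvement(b, a)$percent else NA_real_
  improvements <- c(
    sp_richness = pct(before$sp$richness, after$sp$richness),
    sp_diversity = pct(before$sp$effective_number, after$sp$effective_number),
    fg_richness = pct(before$fg$richness, after$fg$richness),
    fg_diversity = pct(before$fg$effective_number, after$fg$effective_number),
    carbon = pct(before$carbon$carbon_kg, after$carbon$carbon_kg))
  table <- data.frame(
    sp_richness_before = before$sp$richness,
    sp_diversity_before = before$sp$effective_number,
    sp_richness_after = after$sp$richness,
    sp_diversity_after = after$sp$effective_number,
    sp_richness_improvement_pct = improvements[["sp_richness"]],
    sp_diversity_improvement_pct = improvements[["sp_diversity"]],
    fg_richness_before = before$fg$richness,
    fg_diversity_before = before$fg$effective_number,
    fg_richness_after = after$fg$richness,
    fg_diversity_after = after$fg$effective_number,
    fg_diversity_improvement_pct = improvements[["fg_diversity"]],
    carbon_kg_before = before$carbon$carbon_kg,
    carbon_kg_after = after$carbon$carbon_kg,
    carbon_improvement_pct = improvements[["carbon"]],
    stringsAsFactors = FALSE)
  structure(list(before = before, after = after, improvements = improvements,
                 table = table, augmented = aug),
            class = "SimulationReport")
}
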