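#' Exp-Shannon effective number of categories
#'
#' The Hill number of order 1: `exp(-sum(p_i * ln(p_i)))` with `p_i` the
#' relative abundances. Applied to species counts this is the effective
#' number of species (ENS); to functional-group counts, the effective number
#' of functional groups (ENFG). Equals the number of categories when counts
#' are perfectly even and 1 when a single category is present.
#'
#' @param counts named or unnamed vector of positive counts (an
#'   [abundance()] result, for instance), or a `table`.
#' @return The effective number, a real >= 1.
#' @export
#' @examples
#' shannonEffectiveNumber(c(2, 1, 1))  # 2^1.5
shannonEffectiveNumber <- function(counts) {
  counts <- as.numeric(counts)
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  counts <- counts[counts > 0]
  if (length(counts) == 0 || sum(counts) <= 0)
    stop("effective number is undefined for an empty distribution", call. = FALSE)
  p <- counts / sum(counts)
  exp(-sum(p * log(p)))
}

.DIVERSITY_BANDS <- data.frame(
  lower = c(1, 3, 5, 8), upper = c(3, 5, 8, 10),
  label = c("Very low", "Low", "Intermediate", "High"),
  stringsAsFactors = FALSE)

#' Functional-diversity band for an ENFG value
#'
#' Bands are lower-inclusive and cover `[1, 10]`: `[1,3)` Very low, `[3,5)`
#' Low, `[5,8)` Intermediate, `[8,10]` High.
#'
#' @param enfg effective number of functional groups in `[1, 10]`.
#' @return One of `"Very low"`, `"Low"`, `"Intermediate"`, `"High"`.
#' @export
diversityBand <- function(enfg) {
  .assertScalarNumber(enfg, "enfg", 1, 10)
  i <- findInterval(enfg, .DIVERSITY_BANDS$lower)
  .DIVERSITY_BANDS$label[i]
}

#' Richness and diversity report
#'
#' Richness (number of distinct categories), the exp-Shannon effective
#' number, and — at the functional-group level — the qualitative diversity
#' band. Trees with the level field missing are omitted. An empty inventory
#' (or one with no assigned trees) reports richness 0 and no effective
#' number.
#'
#' @param inv a [TreeInventory-class].
#' @param level `"species"` or `"functional_group"`.
#' @return List with `level`, `richness`, `effective_number` (`NA` when
#'   undefined), `band` (functional-group level only, else `NA`), `n_trees`
#'   (trees carrying the field).
#' @export
#' @examples
#' inv <- TreeInventory(species = c("A", "A", "B"),
#'                      functional_group = c("2A", "2A", "5"))
#' diversityReport(inv, "species")$effective_number  # 2^1.5
diversityReport <- function(inv, level = c("species", "functional_group")) {
  stopifnot(is(inv, "TreeInventory"))
  level <- match.arg(level)
  counts <- abundance(inv, level)
  if (length(counts) == 0)
    return(list(level = level, richness = 0L, effective_number = NA_real_,
                band = NA_character_, n_trees = 0L))
  en <- shannonEffectiveNumber(counts)
  band <- if (level == "functional_group") diversityBand(min(en, 10)) else NA_character_
  list(level = level, richness = length(counts), effective_number = en,
       band = band, n_trees = attr(counts, "total"))
}

#' Composition-rule thresholds
#'
#' The 10-20-30 rule caps any one species at 10% of the inventory, any genus
#' at 20% and any family at 30%; the stricter 5-10-15 variant halves them.
#' "Not more than" is read as allowing exactly the threshold: a category is
#' violating only when its proportion strictly exceeds the cap.
#'
#' @param preset `"10-20-30"` or `"5-10-15"`, or `NULL` when giving caps
#'   explicitly.
#' @param species_max,genus_max,family_max explicit proportions,
#'   `0 < species_max <= genus_max <= family_max < 1`.
#' @return A list with class `"RuleThresholds"`.
#' @export
ruleThresholds <- function(preset = c("10-20-30", "5-10-15"),
                           species_max = NULL, genus_max = NULL,
                           family_max = NULL) {
  if (is.null(species_max)) {
    preset <- match.arg(preset)
    v <- if (preset == "10-20-30") c(0.10, 0.20, 0.30) else c(0.05, 0.10, 0.15)
    species_max <- v[1]; genus_max <- v[2]; family_max <- v[3]
    name <- preset
  } else {
    name <- "custom"
  }
  if (!(species_max > 0 && species_max <= genus_max &&
        genus_max <= family_max && family_max < 1))
    stop("need 0 < species_max <= genus_max <= family_max < 1", call. = FALSE)
  structure(list(name = name, species_max = species_max,
                 genus_max = genus_max, family_max = family_max),
            class = "RuleThresholds")
}

#' Composition-rule compliance of an inventory
#'
#' Computes per-category proportions at the species, genus and family levels
#' (over the trees carrying each field) and reports every category whose
#' share strictly exceeds its cap. The inventory passes when no level has a
#' violation.
#'
#' @param inv a [TreeInventory-class].
#' @param thresholds a [ruleThresholds()].
#' @return List with `rule` (threshold set name), `violations` (a
#'   `data.frame` of level, category, count, proportion, threshold), `pass`
#'   (logical), and `denominators` (trees per level carrying the field).
#' @export
ruleCompliance <- function(inv, thresholds = ruleThresholds("10-20-30")) {
  stopifnot(is(inv, "TreeInventory"), inherits(thresholds, "RuleThresholds"))
  caps <- c(species = thresholds$species_max, genus = thresholds$genus_max,
            family = thresholds$family_max)
  viols <- list()
  denoms <- integer()
  for (level in names(caps)) {
    counts <- abundance(inv, level)
    total <- attr(counts, "total") %||% 0L
    denoms[[level]] <- as.integer(total)
    if (length(counts) == 0) next
    prop <- as.numeric(counts) / total
    bad <- prop > caps[[level]]
    if (any(bad))
      viols[[level]] <- data.frame(
        level = level, category = names(counts)[bad],
        count = as.integer(counts[bad]), proportion = prop[bad],
        threshold = caps[[level]], stringsAsFactors = FALSE, row.names = NULL)
  }
  violations <- if (length(viols)) do.call(rbind, viols) else
    data.frame(level = character(), category = character(), count = integer(),
               proportion = numeric(), threshold = numeric(),
               stringsAsFactors = FALSE)
  rownames(violations) <- NULL
  list(rule = thresholds$name, violations = violations,
       pass = nrow(violations) == 0, denominators = denoms)
}

#' DBH class distribution
#'
#' Counts trees per half-open diameter class `[0, w)`, `[w, 2w)`, ... up to
#' the largest occupied class; trees without a DBH are reported separately.
#'
#' @param inv a [TreeInventory-class].
#' @param class_width class width in cm (default 10, > 0).
#' @return List with `counts` (named integer vector, names like
#'   `"[10,20)"`), `missing` (trees without DBH), `class_width`.
#' @export
dbhClassDistribution <- function(inv, class_width = 10) {
  stopifnot(is(inv, "TreeInventory"))
  .assertScalarNumber(class_width, "class_width", 0, Inf, open_lower = TRUE)
  dbh <- inv@trees$dbh
  missing <- sum(is.na(dbh))
  dbh <- dbh[!is.na(dbh)]
  if (length(dbh) == 0)
    return(list(counts = stats::setNames(integer(), character()),
                missing = missing, class_width = class_width))
  idx <- floor(dbh / class_width)
  k <- 0:max(idx)
  counts <- vapply(k, function(i) sum(idx == i), integer(1))
  names(counts) <- sprintf("[%g,%g)", k * class_width, (k + 1) * class_width)
  list(counts = counts, missing = missing, class_width = class_width)
}
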