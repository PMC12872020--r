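#' Generate a synthetic urban tree inventory
#'
#' Draws a seeded, reproducible inventory emulating a municipal street/park
#' tree CSV. Each tree's functional group is sampled from `fg_mix` (or
#' assigned round-robin when `balanced = TRUE`, giving exactly proportional
#' counts), its species uniformly among the pool species of that group, its
#' DBH from a lognormal (default: median ~17 cm, emulating a young urban
#' canopy where more than half the stems stay under 20 cm) or a fixed value,
#' and its coordinates uniformly in a bounding box. The same seed always
#' reproduces the identical inventory.
#'
#' @param n number of trees.
#' @param pool a [SpeciesCatalog-class]; species are drawn from it.
#' @param fg_mix named numeric vector of sampling probabilities per
#'   functional group (must sum to 1); default uniform over the groups
#'   present in `pool`.
#' @param dbh_model `list(type = "lognormal", meanlog =, sdlog =)` or
#'   `list(type = "fixed", value =)`.
#' @param bbox numeric `c(minlon, minlat, maxlon, maxlat)`; default a small
#'   box over Montreal.
#' @param seed integer seed; the global RNG state is left untouched.
#' @param balanced logical; `TRUE` assigns groups deterministically in
#'   proportion to `fg_mix` (largest-remainder apportionment) instead of
#'   sampling them.
#' @return A [TreeInventory-class] with `n` trees.
#' @export
#' @examples
#' inv <- generateSyntheticInventory(50, defaultCatalog(), seed = 1)
#' nTrees(inv)
generateSyntheticInventory <- function(n, pool,
                                       fg_mix = NULL,
                                       dbh_model = list(type = "lognormal",
                                                        meanlog = log(17),
                                                        sdlog = 0.6),
                                       bbox = c(-73.60, 45.44, -73.54, 45.48),
                                       seed = 1L,
                                       balanced = FALSE) {
  stopifnot(is(pool, "SpeciesCatalog"), length(bbox) == 4)
  .assertScalarNumber(n, "n", 0)
  en <- catalogEntries(pool)
  en <- en[!is.na(en$functional_group), , drop = FALSE]
  if (nrow(en) == 0) stop("pool has no species with functional groups", call. = FALSE)
  pool_groups <- sort(unique(en$functional_group))
  if (is.null(fg_mix))
    fg_mix <- stats::setNames(rep(1 / length(pool_groups), length(pool_groups)),
                              pool_groups)
  if (abs(sum(fg_mix) - 1) > 1e-8)
    stop("fg_mix must sum to 1", call. = FALSE)
  missing_pool <- setdiff(names(fg_mix)[fg_mix > 0], pool_groups)
  if (length(missing_pool))
    stop("no pool species for functional group(s): ",
         paste(missing_pool, collapse = ", "), call. = FALSE)
  if (n == 0)
    return(new("TreeInventory", trees = .emptyTreeTable(),
               provenance = sprintf("synthetic(n=0,seed=%d)", seed)))

  withr::with_seed(as.integer(seed), {
    groups <- if (balanced) {
      base <- floor(fg_mix * n)
      rem <- n - sum(base)
      frac <- fg_mix * n - base
      extra <- names(sort(frac, decreasing = TRUE))[seq_len(rem)]
      base[extra] <- base[extra] + 1
      rep(names(base), times = base)
    } else {
      sample(names(fg_mix), n, replace = TRUE, prob = fg_mix)
    }
    species <- vapply(groups, function(g) {
      sp <- en$species[en$functional_group == g]
      sp[sample.int(length(sp), 1)]
    }, character(1))
    dbh <- switch(dbh_model$type,
      lognormal = stats::rlnorm(n, dbh_model$meanlog, dbh_model$sdlog),
      fixed = rep(dbh_model$value, n),
      stop("dbh_model$type must be 'lognormal' or 'fixed'", call. = FALSE))
    dbh <- round(pmax(dbh, 0.5), 1)
    lon <- stats::runif(n, bbox[1], bbox[3])
    lat <- stats::runif(n, bbox[2], bbox[4])
    loc <- sample(c("street", "park"), n, replace = TRUE, prob = c(0.7, 0.3))
    TreeInventory(
      species = unname(species), dbh = dbh, lat = round(lat, 6),
      lon = round(lon, 6), location_type = loc, catalog = pool,
      provenance = sprintf("synthetic(n=%d,seed=%d)", n, as.integer(seed)))
  })
}
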