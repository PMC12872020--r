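test_that("CSV reading parses rows, preserves order, and flags bad fields", {
  path <- writeInventoryCsv(data.frame(
    species = c("Acer saccharum", "Quercus rubra", "Picea glauca"),
    dbh = c(20, 35.5, 12),
    lat = c(45.45, 45.46, 45.47), lon = c(-73.57, -73.58, -73.59)))
  inv <- readInventory(path, catalog = tinyCatalog())
  expect_equal(nTrees(inv), 3)
  tr <- treeData(inv)
  expect_equal(tr$species,
               c("Acer saccharum", "Quercus rubra", "Picea glauca"))
  expect_equal(tr$dbh, c(20, 35.5, 12))
  # taxonomy filled from the catalog
  expect_equal(tr$functional_group, c("2A", "4A", "1A"))
  expect_equal(tr$wood_type, c("hardwood", "hardwood", "softwood"))

  # header-only file
  empty <- readInventory(writeInventoryCsv(
    data.frame(species = character(), dbh = numeric())))
  expect_equal(nTrees(empty), 0)

  # blank DBH: tree kept, dbh missing, still counted for diversity but
  # skipped by the carbon pipeline
  path2 <- writeInventoryCsv(data.frame(
    species = c("Acer saccharum", "Quercus rubra"), dbh = c(NA, 30)))
  inv2 <- readInventory(path2, catalog = tinyCatalog())
  expect_equal(nTrees(inv2), 2)
  expect_true(is.na(treeData(inv2)$dbh[1]))
  expect_equal(diversityReport(inv2, "species")$richness, 2)
  cc <- inventoryCarbon(inv2, tinyCoeffs(), catalog = tinyCatalog())
  expect_equal(cc$n_skipped, 1)
  expect_equal(cc$n_included, 1)
})

test_that("Montreal open-data dialect loads through its column map", {
  path <- writeInventoryCsv(data.frame(
    EMP_NO = c("1001", "1002"),
    Essence_latin = c("Acer saccharum", "Ulmus americana"),
    DHP = c(25, 40),
    Date_Plantation = c("2014-05-02", ""),
    Date_Releve = c("2023-06-10", "2023-06-11"),
    Latitude = c(45.45, 45.46), Longitude = c(-73.57, -73.58),
    EMPLACEMENT = c("street", "park"), check.names = FALSE))
  inv <- readInventory(path, montrealColumnMap(), tinyCatalog())
  tr <- treeData(inv)
  expect_equal(tr$tree_id, c("1001", "1002"))
  expect_equal(tr$dbh, c(25, 40))
  expect_equal(tr$planted_date[1], as.Date("2014-05-02"))
  expect_true(is.na(tr$planted_date[2]))
  expect_equal(tr$functional_group, c("2A", "2C"))
})

test_that("species unknown to the catalog warn but keep the tree", {
  path <- writeInventoryCsv(data.frame(species = "Ficus whatever", dbh = 12))
  expect_warning(inv <- readInventory(path, catalog = tinyCatalog()),
                 "absent from the catalog")
  expect_equal(nTrees(inv), 1)
  expect_true(is.na(treeData(inv)$functional_group))
})

test_that("spatial selection keeps boundary points and is idempotent", {
  # 5 points on a grid, box covering 3 (one exactly on the boundary)
  inv <- TreeInventory(species = letters[1:5],
                       lon = c(0, 1, 2, 3, 4), lat = c(0, 1, 2, 3, 4))
  box <- c(0, 0, 2, 2)
  sel <- selectRegion(inv, box)
  expect_equal(treeData(sel)$species, c("a", "b", "c"))

  expect_equal(nTrees(selectRegion(inv, c(-1, -1, 10, 10))), 5)
  expect_equal(nTrees(selectRegion(inv, c(10, 10, 11, 11))), 0)

  # idempotence
  expect_identical(treeData(selectRegion(sel, box)), treeData(sel))

  # box string and polygon forms agree
  expect_equal(nTrees(selectRegion(inv, "0,0,2,2")), 3)
  poly <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  expect_equal(nTrees(selectRegion(inv, poly)), 3)

  # trees without coordinates never match
  inv_na <- TreeInventory(species = "x", lat = NA, lon = NA)
  expect_equal(nTrees(selectRegion(inv_na, c(-180, -90, 180, 90))), 0)

  expect_error(selectRegion(inv, cbind(0:1, 0:1)), "polygon")
  expect_error(selectRegion(inv, c(5, 5, 1, 1)), "bounding box")
})

test_that("GeoJSON polygons drive region selection", {
  gj <- list(type = "Polygon",
             coordinates = list(list(c(0, 0), c(2.5, 0), c(2.5, 2.5),
                                     c(0, 2.5), c(0, 0))))
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  inv <- TreeInventory(species = letters[1:5],
                       lon = c(0.5, 1, 2, 3, 4), lat = c(0.5, 1, 2, 3, 4))
  expect_equal(treeData(selectRegion(inv, path))$species, c("a", "b", "c"))
})

test_that("abundance counts omit missing fields and sum to carriers", {
  inv <- TreeInventory(species = c("A", "A", "B"),
                       functional_group = c("2A", NA, "5"))
  ab <- abundance(inv, "species")
  expect_equal(as.integer(ab[c("A", "B")]), c(2, 1))
  expect_equal(attr(ab, "total"), 3)
  fg <- abundance(inv, "functional_group")
  expect_equal(attr(fg, "total"), 2)  # only assigned trees
  expect_equal(sum(fg), 2)

  one <- TreeInventory(species = rep("sp", 10))
  expect_equal(as.integer(abundance(one, "species")), 10)

  # totals at every level equal the number of trees carrying the field
  set.seed(3)
  inv2 <- generateSyntheticInventory(80, tinyCatalog(), seed = 3)
  for (lv in c("species", "genus", "family", "functional_group")) {
    ab2 <- abundance(inv2, lv)
    expect_equal(attr(ab2, "total"), sum(!is.na(treeData(inv2)[[lv]])))
  }
})

test_that("max-DBH thresholds use interpolated percentiles with genus fallback", {
  cfg <- maxDbhConfig()  # 95th percentile, min cohort 150
  # constant cohort
  inv_const <- TreeInventory(species = rep("Acer saccharum", 200), dbh = 30,
                             catalog = tinyCatalog())
  expect_equal(unname(maxDbhThresholds(inv_const, cfg)["Acer saccharum"]), 30)

  # 150 trees, DBH 1..150 -> 142.55 under linear interpolation
  inv_seq <- TreeInventory(species = rep("Quercus rubra", 150), dbh = 1:150,
                           catalog = tinyCatalog())
  expect_equal(unname(maxDbhThresholds(inv_seq, cfg)["Quercus rubra"]),
               142.55, tolerance = 1e-12)

  # small cohort falls back to the mean of same-genus species thresholds
  inv_fb <- TreeInventory(
    species = c(rep("Acer saccharum", 200), rep("Acer platanoides", 10)),
    genus = "Acer", dbh = c(rep(40, 200), rep(5, 10)))
  thr <- maxDbhThresholds(inv_fb, cfg)
  expect_equal(unname(thr["Acer platanoides"]), 40)

  # no genus sibling -> omitted
  inv_orphan <- TreeInventory(species = rep("Solo species", 10),
                              genus = "Solo", dbh = 10)
  expect_false("Solo species" %in% names(maxDbhThresholds(inv_orphan, cfg)))

  # permutation invariance in tree order
  perm <- sample(nrow(treeData(inv_fb)))
  tr <- treeData(inv_fb)[perm, ]
  inv_perm <- TreeInventory(species = tr$species, genus = tr$genus,
                            dbh = tr$dbh)
  expect_equal(maxDbhThresholds(inv_perm, cfg), thr)

  # empty reference
  expect_length(maxDbhThresholds(TreeInventory(species = character()), cfg), 0)

  # configurable percentile
  expect_equal(
    unname(maxDbhThresholds(inv_seq, maxDbhConfig(percentile = 50))),
    75.5)
})

test_that("old-tree flags are threshold-inclusive and proportions sum to 1", {
  thr <- c("A" = 30, "B" = 50)
  inv <- TreeInventory(species = c("A", "A", "A", "B", "B", "C"),
                       functional_group = c("2A", "2A", "2C", "5", "2C", "1A"),
                       dbh = c(30, 29.99, 45, 60, 10, 100))
  flags <- oldTreeFlags(inv, thr)
  # boundary: dbh exactly at the threshold is old; C has no threshold
  expect_equal(unname(flags$flags), c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(sum(flags$share_of_old), 1)
  expect_equal(flags$share_of_old[["2A"]], 1 / 3)

  # all below thresholds -> no old trees
  young <- TreeInventory(species = c("A", "B"), dbh = c(1, 2))
  expect_equal(sum(oldTreeFlags(young, thr)$flags), 0)

  # stated proportions example: old trees in groups {2A, 2A, 2C, 5}
  inv4 <- TreeInventory(species = rep("A", 4),
                        functional_group = c("2A", "2A", "2C", "5"),
                        dbh = rep(30, 4))
  share <- oldTreeFlags(inv4, thr)$share_of_old
  expect_equal(share[c("2A", "2C", "5")], c(`2A` = 0.5, `2C` = 0.25, `5` = 0.25))
})

test_that("synthetic generator is seed-reproducible and respects its config", {
  cat_ <- tinyCatalog()
  expect_equal(nTrees(generateSyntheticInventory(0, cat_, seed = 1)), 0)

  a <- generateSyntheticInventory(100, cat_, seed = 99)
  b <- generateSyntheticInventory(100, cat_, seed = 99)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  writeInventory(a, fa); writeInventory(b, fb)
  expect_identical(readLines(fa), readLines(fb))  # byte-identical export

  expect_false(identical(treeData(a)$species,
                         treeData(generateSyntheticInventory(100, cat_,
                                                             seed = 100))$species))

  # species are drawn within the sampled group
  en <- catalogEntries(cat_)
  fg_of <- setNames(en$functional_group, en$species)
  expect_equal(unname(fg_of[treeData(a)$species]),
               treeData(a)$functional_group)

  # invalid mixes
  expect_error(generateSyntheticInventory(
    10, cat_, fg_mix = c(`1A` = 0.5, `1B` = 0.2), seed = 1), "sum to 1")
  only_conifers <- SpeciesCatalog(species = "Picea glauca", genus = "Picea",
                                  family = "Pinaceae", functional_group = "1A",
                                  wood_type = "softwood")
  expect_error(generateSyntheticInventory(
    10, only_conifers, fg_mix = c(`1A` = 0.5, `5` = 0.5), seed = 1),
    "no pool species")

  # fixed-DBH model and balanced assignment
  fixed <- generateSyntheticInventory(
    40, cat_, dbh_model = list(type = "fixed", value = 15), seed = 5,
    balanced = TRUE)
  expect_true(all(treeData(fixed)$dbh == 15))
  expect_equal(unname(table(treeData(fixed)$functional_group)),
               rep(4L, 10), ignore_attr = TRUE)
})

test_that("inventory round-trips through normalized CSV and GeoJSON export", {
  inv <- generateSyntheticInventory(25, tinyCatalog(), seed = 4)
  f <- tempfile(fileext = ".csv")
  writeInventory(inv, f)
  back <- readInventory(f)
  expect_equal(treeData(back)$species, treeData(inv)$species)
  expect_equal(treeData(back)$dbh, treeData(inv)$dbh)

  gj <- tempfile(fileext = ".geojson")
  exportGeoJSON(inv, gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, 25)
  expect_equal(parsed$features[[1]]$geometry$type, "Point")
})

test_that("inventory validity rejects malformed trees", {
  expect_error(TreeInventory(species = "A", dbh = -3), "dbh")
  expect_error(TreeInventory(species = "A", functional_group = "9Z"),
               "functional_group")
  expect_error(TreeInventory(species = "A", lat = 95), "lat")
  expect_error(TreeInventory(species = c("A", "B"), tree_id = c("t", "t")),
               "unique")
})
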