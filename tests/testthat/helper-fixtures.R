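# Fixtures built in code; everything deterministic.

tinyCatalog <- function() {
  SpeciesCatalog(
    species = c("Picea glauca", "Pinus resinosa", "Acer saccharum",
                "Aesculus glabra", "Ulmus americana", "Sorbus aucuparia",
                "Malus baccata", "Quercus rubra", "Gleditsia triacanthos",
                "Betula papyrifera", "Rhamnus cathartica"),
    genus = c("Picea", "Pinus", "Acer", "Aesculus", "Ulmus", "Sorbus",
              "Malus", "Quercus", "Gleditsia", "Betula", "Rhamnus"),
    family = c("Pinaceae", "Pinaceae", "Sapindaceae", "Sapindaceae",
               "Ulmaceae", "Rosaceae", "Rosaceae", "Fagaceae", "Fabaceae",
               "Betulaceae", "Rhamnaceae"),
    functional_group = c("1A", "1B", "2A", "2B", "2C", "3A", "3B", "4A",
                         "4B", "5", NA),
    wood_type = c("softwood", "softwood", rep("hardwood", 9)),
    candidate = c(rep(TRUE, 10), FALSE),
    excluded = c(rep(FALSE, 10), TRUE),
    exclusion_reason = c(rep(NA, 10), "invasive"))
}

# flat coefficients: every compartment beta1 * dbh^beta2 with simple numbers
tinyCoeffs <- function(beta1 = 0.05, beta2 = 2) {
  allometricCoefficients(data.frame(
    allometric_key = rep(c("hardwood", "softwood"), each = 3),
    compartment = rep(c("wood", "bark", "branches"), 2),
    beta1 = beta1, beta2 = beta2))
}

# inventory with known counts per species from the tiny catalog
countedInventory <- function(counts, dbh = 20) {
  species <- rep(names(counts), times = counts)
  TreeInventory(species = species, dbh = dbh, catalog = tinyCatalog())
}

writeInventoryCsv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# independent ENS oracle (vegan's Shannon entropy, exponentiated)
ensOracle <- function(counts) exp(vegan::diversity(as.numeric(counts),
                                                   index = "shannon"))
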