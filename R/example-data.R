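#' Bundled ten-park planting case study
#'
#' Two small reference tables from a published planting scenario over ten
#' Montreal city parks: `plan` gives each park's tree count and the number of
#' trees planted under a 5% budget; `improvements` gives species and
#' functional-group richness and diversity (exp-Shannon effective numbers)
#' before and after planting the ten top-ranked recommended species, with the
#' printed percent improvements. Useful for validating the improvement
#' arithmetic and the budget rule against independently published numbers.
#'
#' @return List of two `data.frame`s, `plan` and `improvements`.
#' @export
#' @examples
#' parks <- montrealParkTables()
#' parks$plan$n_to_plant
montrealParkTables <- function() {
  read_tab <- function(f)
    utils::read.csv(system.file("extdata", f, package = "CanopyPlan",
                                mustWork = TRUE),
                    stringsAsFactors = FALSE, check.names = FALSE)
  list(plan = read_tab("montreal_parks_plan.csv"),
       improvements = read_tab("montreal_parks_improvements.csv"))
}
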