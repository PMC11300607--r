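#' Lake Erie mean demersal-gear catch matrix, 2019-2022
#'
#' The reported month-by-SMU mean commercial catch (Imperial pounds) of Lake
#' Whitefish from demersal fishing gears in Lake Erie, summed per month and
#' averaged over 2019-2022, as published in the binational fishery reporting
#' for the tag-deployment period. The matrix spans 12 months and 8 SMUs; 59
#' cells are nonzero, with the maximum (31,265 lb) in Ohio waters of district
#' 1 in November, reflecting the short-duration trap-net fishery on spawning
#' aggregations.
#'
#' @return `data.table` with `month` (1-12), `smu_id`, `mean_catch_lb`.
#' @export
#' @examples
#' m <- lake_erie_catch_matrix()
#' pr <- percentile_ranks(m)
#' pr[which.max(pr$mean_catch_lb)]
lake_erie_catch_matrix <- function() {
  path <- system.file("extdata", "lake_erie_mean_catch_2019_2022.csv",
                      package = "riskdays", mustWork = TRUE)
  dt <- fread(path)
  dt[, smu_id := as.character(smu_id)]
  dt[]
}
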