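#' Build a province exposure table
#'
#' Creates the area-level exposure table: one row per province with its
#' annual mean 2m air temperature in degrees Celsius. Provinces are the
#' clustering unit of the multilevel outcome model; each individual inherits
#' the temperature of their province.
#'
#' @param n_provinces number of provinces (>= 1).
#' @param temp_min,temp_max temperature range in degrees C (`temp_min <=
#'   temp_max`). The Argentine gradient runs roughly 4.6 C in the far south
#'   to 23 C in the north.
#' @param mode `"equispaced"` (default) places temperatures on a
#'   deterministic evenly spaced grid including both endpoints (a single
#'   province gets the midpoint); `"uniform_random"` draws them uniformly.
#' @param seed integer seed, used only in `"uniform_random"` mode.
#'
#' @return A `data.frame` with columns `province_id` (integer, unique) and
#'   `mean_temp_c` (numeric, within `[temp_min, temp_max]`).
#' @examples
#' make_province_table(5, 0, 20)
#' @export
make_province_table <- function(n_provinces, temp_min, temp_max,
                                mode = c("equispaced", "uniform_random"),
                                seed = 1L) {
  n_provinces <- assert_count(n_provinces, "n_provinces")
  assert_number(temp_min, "temp_min")
  assert_number(temp_max, "temp_max")
  if (temp_min > temp_max)
    stop_invalid("'temp_min' (%g) must be <= 'temp_max' (%g)", temp_min, temp_max)
  mode <- match.arg(mode)
  temps <- switch(mode,
    equispaced = if (n_provinces == 1L) (temp_min + temp_max) / 2
                 else seq(temp_min, temp_max, length.out = n_provinces),
    uniform_random = with_seed(stage_seed(seed, "province_temp"),
                               stats::runif(n_provinces, temp_min, temp_max))
  )
  data.frame(province_id = seq_len(n_provinces), mean_temp_c = temps)
}
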