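#' Read and write multiplier tables
#'
#' The on-disk multiplier format is long: `species,site,quantity,value,cv`,
#' with quantities named `false_rate`, `click_rate`, `group_size`, `p_v`,
#' `p_k`, `w_km`. `read_multipliers()` pivots it into the wide one-row-per
#' species/site form the estimators take.
#'
#' @param path CSV path.
#' @return `read_multipliers()`: a wide multiplier tibble compatible with
#'   [weekly_series()].
#' @export
read_multipliers <- function(path) {
  raw <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  wide_v <- raw %>%
    select("species", "site", "quantity", "value") %>%
    tidyr::pivot_wider(names_from = "quantity", values_from = "value")
  wide_cv <- raw %>%
    filter(.data$quantity != "w_km") %>%
    mutate(quantity = paste0(.data$quantity, "_cv")) %>%
    select("species", "site", "quantity", "cv") %>%
    tidyr::pivot_wider(names_from = "quantity", values_from = "cv")
  left_join(wide_v, wide_cv, by = c("species", "site"))
}

#' @rdname read_multipliers
#' @param multipliers Wide multiplier tibble (e.g. from [multiplier_set()]).
#' @export
write_multipliers <- function(multipliers, path) {
  quantities <- intersect(
    c("false_rate", "click_rate", "group_size", "p_v", "p_k", "w_km"),
    names(multipliers)
  )
  long <- purrr::map_dfr(quantities, function(q) {
    cvcol <- paste0(q, "_cv")
    tibble(
      species = multipliers$species, site = multipliers$site,
      quantity = q, value = multipliers[[q]],
      cv = if (cvcol %in% names(multipliers)) multipliers[[cvcol]] else 0
    )
  }) %>% filter(!is.na(.data$value))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(long)
}

#' Write weekly counts to CSV
#'
#' Columns `week_start,site,species,n_clicks,n_bins_detected,t_seconds,t_bins`.
#'
#' @param weekly Weekly counts from [weekly_aggregate()].
#' @param path CSV path.
#' @export
write_weekly_counts <- function(weekly, path) {
  utils::write.csv(weekly, path, row.names = FALSE)
  invisible(weekly)
}

#' Write a density series to CSV
#'
#' Columns `week_start,site,species,method,density_per_1000km2,cv,sd,ci_low,
#' ci_high`.
#'
#' @param series Output of [weekly_series()].
#' @param path CSV path.
#' @export
write_density_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(series)
}
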