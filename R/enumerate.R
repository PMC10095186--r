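#' Flow-cytometric concentrations per subpopulation
#'
#' Converts pooled label counts into concentrations (obj/mL) given the
#' acquired sample volume. The per-label concentrations plus the total
#' (all acquired events) are returned; labels outside the four
#' subpopulations account for the difference between the subpopulation sum
#' and the total.
#'
#' @param summary A [summarize_subpopulations()] result.
#' @param acquisition_volume_ml Acquired volume (mL), > 0. Instrument
#'   acquisition volume is not inferable from event counts and must be
#'   supplied explicitly.
#' @return A tibble with `label`, `count`, `obj_per_ml`, including a
#'   `"total"` row.
#' @export
flow_concentrations <- function(summary, acquisition_volume_ml) {
  stopifnot(inherits(summary, "subpop_summary"))
  if (!is.numeric(acquisition_volume_ml) || acquisition_volume_ml <= 0) {
    abort("`acquisition_volume_ml` must be > 0.",
          class = "ifcgate_config_error")
  }
  s <- summary$summary
  out <- tibble::tibble(label = c(s$label, "total"),
                        count = c(s$count, summary$n_events))
  out$obj_per_ml <- out$count / acquisition_volume_ml
  out
}

#' Plate-count estimate under the 30-300 rule
#'
#' Colony counts are statistically usable only on plates carrying between
#' 30 and 300 colonies. Each qualifying plate yields the estimate
#' `colonies / (10^exponent * plated_volume)`; qualifying plates are
#' averaged, either plainly or weighted by colony count (equivalent to
#' pooling colonies over pooled effective volumes). When no plate
#' qualifies, the no-estimate flag is set and the estimate is `NA`.
#'
#' @param series A [simulate_plating()] result or a data frame with columns
#'   `dilution_exponent`, `colonies`, `plated_volume_ml`.
#' @param count_range Qualifying colony count range (inclusive).
#' @param weighting `"plain"` (mean of per-plate estimates) or `"weighted"`
#'   (colony-weighted).
#' @return A list with `estimate` (cfu/mL or `NA`), `n_qualifying`, and
#'   logical `no_estimate`.
#' @export
plate_count_estimate <- function(series, count_range = c(30, 300),
                                 weighting = c("plain", "weighted")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("dilution_exponent", "colonies", "plated_volume_ml")
                %in% names(series)))
  if (any(series$colonies < 0)) {
    abort("Colony counts must be >= 0.", class = "ifcgate_validation_error")
  }
  ok <- series$colonies >= count_range[1] & series$colonies <= count_range[2]
  if (!any(ok)) {
    return(list(estimate = NA_real_, n_qualifying = 0L, no_estimate = TRUE))
  }
  eff_vol <- 10^series$dilution_exponent[ok] * series$plated_volume_ml[ok]
  est <- if (weighting == "plain") {
    mean(series$colonies[ok] / eff_vol)
  } else {
    sum(series$colonies[ok]) / sum(eff_vol)
  }
  list(estimate = est, n_qualifying = sum(ok), no_estimate = FALSE)
}

#' Compare flow-cytometric and plate-count enumeration
#'
#' Appends the plate/flow ratios used to interpret enumeration differences:
#' plate counts see only cells able to grow (roughly the active group),
#' while cytometry counts every gated object but drops aggregates, so the
#' two methods bracket each other depending on sample state.
#'
#' @param flow A [flow_concentrations()] tibble.
#' @param plate_cfu_ml Plate-count estimate (cfu/mL).
#' @return A one-row tibble with the totals and ratios.
#' @export
compare_counts <- function(flow, plate_cfu_ml) {
  total <- flow$obj_per_ml[flow$label == "total"]
  active <- flow$obj_per_ml[flow$label == "active"]
  tibble::tibble(
    flow_total_obj_ml = total,
    flow_active_obj_ml = active,
    plate_cfu_ml = plate_cfu_ml,
    ratio_plate_to_flow_total = plate_cfu_ml / total,
    ratio_plate_to_flow_active = plate_cfu_ml / active
  )
}

#' Post-sort growth percentages
#'
#' Tabulates a sorting outcome into growth percentages per subpopulation,
#' medium and timepoint: broth wells grow when blank-subtracted OD600
#' exceeds the threshold (0.1); agar growth is counted from colony
#' formation. Percentages are `100 * k / n_sorted` rounded to one decimal
#' place.
#'
#' @param outcome A [simulate_sorting()] result.
#' @return A tibble with `subpopulation`, `medium`, `hours`, `n_grew`,
#'   `percent`.
#' @export
growth_percentages <- function(outcome) {
  stopifnot(inherits(outcome, "sorting_outcome"))
  if (outcome$n_sorted == 0L) {
    abort("No sorted cells; growth percentage undefined.",
          class = "ifcgate_validation_error")
  }
  cells <- outcome$cells
  grew <- function(d, hours) {
    if (d$medium[1] == "broth") {
      od <- if (hours == 48L) d$od600_48h else d$od600_72h
      sum(od - outcome$od_blank > outcome$od_threshold)
    } else {
      sum(if (hours == 48L) d$colony_48h else d$colony_72h)
    }
  }
  groups <- split(cells, list(cells$subpopulation, cells$medium), drop = TRUE)
  out <- lapply(groups, function(d) {
    tibble::tibble(subpopulation = d$subpopulation[1], medium = d$medium[1],
                   hours = c(48L, 72L),
                   n_grew = c(grew(d, 48L), grew(d, 72L)))
  })
  out <- dplyr::bind_rows(out)
  out$percent <- round(100 * out$n_grew / outcome$n_sorted, 1)
  dplyr::arrange(out, .data$subpopulation, .data$medium, .data$hours)
}
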