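#' Reference subpopulation compositions for dual-stained LAB strains
#'
#' Published mean subpopulation percentages (with between-replicate SDs) from
#' imaging-flow-cytometry viability measurements of three lactic acid
#' bacteria strains (*Enterococcus faecium*, *Leuconostoc mesenteroides*,
#' *Carnobacterium divergens*) under six culture/processing conditions.
#' Percentages are of all acquired events; the four subpopulations do not sum
#' to 100 because debris and other unclassifiable events make up the
#' remainder. These tables parameterize the synthetic event generator via
#' [composition_mixture_spec()].
#'
#' @return A tibble with columns `strain`, `treatment`, `subpopulation`,
#'   `percent`, `sd`.
#' @export
reference_compositions <- function() {
  rows <- list(
    # strain, treatment, active, mid_active_1, mid_active_2, dead (percent, sd)
    list("E_faecium",       "control",         62.90, 0.22,  0.84, 0.07, 17.93, 0.26,  9.15, 0.62),
    list("L_mesenteroides", "control",         77.50, 1.20,  0.39, 0.10,  6.21, 0.73,  8.02, 0.60),
    list("C_divergens",     "control",         69.70, 0.35,  0.21, 0.08, 15.35, 0.27,  8.07, 0.37),
    list("E_faecium",       "heat_shock",      63.79, 1.12,  0.09, 0.06, 21.60, 1.24,  6.12, 0.68),
    list("L_mesenteroides", "heat_shock",      25.23, 1.20,  1.03, 0.17, 33.86, 0.18, 26.50, 0.88),
    list("C_divergens",     "heat_shock",      57.87, 1.50,  0.41, 0.14, 21.46, 1.17, 10.50, 0.37),
    list("E_faecium",       "ph_shock",         3.17, 0.68,  2.06, 0.27, 16.54, 1.03, 71.68, 1.23),
    list("L_mesenteroides", "ph_shock",         3.04, 0.12,  1.03, 0.10,  8.47, 0.56, 83.86, 0.53),
    list("C_divergens",     "ph_shock",         9.08, 0.26,  6.63, 0.91, 11.49, 0.76, 65.05, 0.65),
    list("E_faecium",       "uncontrolled_ph", 32.22, 1.00, 14.22, 0.53, 11.08, 0.53, 34.59, 0.20),
    list("L_mesenteroides", "uncontrolled_ph", 32.32, 1.85,  6.15, 0.36, 20.58, 0.52, 34.25, 2.09),
    list("C_divergens",     "uncontrolled_ph", 29.85, 1.39, 17.79, 0.54, 11.02, 0.73, 32.88, 1.73),
    list("E_faecium",       "dried",           36.31, 0.61,  0.69, 0.10, 41.77, 0.22,  6.49, 0.31),
    list("L_mesenteroides", "dried",           33.23, 0.39,  0.41, 0.05, 44.61, 0.05, 10.42, 0.42),
    list("C_divergens",     "dried",           34.78, 0.91,  0.68, 0.12, 39.45, 0.32,  9.22, 0.43),
    list("E_faecium",       "coated",           0.99, 0.12, 11.71, 0.93,  8.67, 0.46, 73.53, 0.59),
    list("L_mesenteroides", "coated",           0.43, 0.07,  7.63, 0.58,  1.94, 0.30, 87.05, 0.66),
    list("C_divergens",     "coated",           0.32, 0.20,  6.18, 0.40,  1.26, 0.15, 90.06, 0.53)
  )
  subpops <- c("active", "mid_active_1", "mid_active_2", "dead")
  out <- lapply(rows, function(r) {
    tibble::tibble(
      strain = r[[1]], treatment = r[[2]], subpopulation = subpops,
      percent = unlist(r[c(3, 5, 7, 9)]), sd = unlist(r[c(4, 6, 8, 10)])
    )
  })
  dplyr::bind_rows(out)
}

#' Reference enumeration table (plate counts vs flow cytometry)
#'
#' Published enumeration of the same cultures by plate counting (cfu/mL) and
#' by imaging flow cytometry (obj/mL, total and per subpopulation). The
#' subpopulation concentrations do not sum to the totals; the gap corresponds
#' to unclassified events and is preserved as published.
#'
#' @return A tibble with one row per sample.
#' @export
reference_enumeration <- function() {
  tibble::tribble(
    ~strain, ~treatment, ~plate_cfu_ml, ~flow_total, ~flow_dead,
    ~flow_mid_active_1, ~flow_mid_active_2, ~flow_active,
    "L_mesenteroides", "control",    2.70e8, 3.57e8, 2.16e7, 1.05e6, 1.68e7, 2.10e8,
    "L_mesenteroides", "heat_shock", 1.29e8, 1.85e8, 3.52e7, 1.36e6, 4.50e7, 3.35e7,
    "E_faecium",       "control",    4.05e8, 2.72e8, 2.17e7, 2.02e5, 4.26e7, 1.47e8,
    "E_faecium",       "heat_shock", 5.85e8, 2.53e8, 1.32e7, 2.04e5, 4.65e7, 1.37e8,
    "C_divergens",     "control",    4.05e8, 3.40e8, 2.13e7, 5.68e5, 4.05e7, 1.84e8,
    "C_divergens",     "heat_shock", 9.35e7, 2.50e8, 2.13e7, 8.37e5, 4.36e7, 1.18e8
  )
}

#' Reference post-sort growth table
#'
#' Published growth percentages of 24 single cells sorted per subpopulation
#' onto MRS agar (colony formation) and into MRS broth (blank-subtracted
#' OD600 > 0.1), read at 48 h and 72 h. All values are k/24 rounded to one
#' decimal place.
#'
#' @return A tidy tibble with columns `strain`, `treatment`, `medium`,
#'   `subpopulation`, `hours`, `percent`.
#' @export
reference_growth <- function() {
  grid <- function(strain, treatment, medium, p48, p72) {
    subpops <- c("active", "mid_active_1", "mid_active_2", "dead")
    tibble::tibble(
      strain = strain, treatment = treatment, medium = medium,
      subpopulation = rep(subpops, 2L),
      hours = rep(c(48L, 72L), each = 4L),
      percent = c(p48, p72)
    )
  }
  dplyr::bind_rows(
    grid("E_faecium", "dried",  "agar",  c(20.8, 0, 8.3, 0),  c(37.5, 0, 8.3, 0)),
    grid("E_faecium", "dried",  "broth", c(75.0, 0, 8.3, 0),  c(83.3, 0, 16.7, 0)),
    grid("E_faecium", "coated", "agar",  c(20.8, 0, 25.0, 0), c(29.2, 0, 29.2, 0)),
    grid("E_faecium", "coated", "broth", c(20.8, 0, 12.5, 0), c(29.2, 0, 12.5, 0)),
    grid("L_mesenteroides", "dried",  "agar",  c(4.2, 0, 8.3, 0),  c(8.3, 0, 8.3, 0)),
    grid("L_mesenteroides", "dried",  "broth", c(4.2, 0, 0, 0),    c(8.3, 0, 0, 0)),
    grid("L_mesenteroides", "coated", "agar",  c(20.8, 0, 4.2, 0), c(33.3, 0, 12.5, 0)),
    grid("L_mesenteroides", "coated", "broth", c(8.3, 4.2, 4.2, 0), c(20.8, 12.5, 4.2, 4.2))
  )
}
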