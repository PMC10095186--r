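#' Gate configuration
#'
#' Thresholds for the three morphological gates and the RSG/PI quadrant
#' boundaries. Quadrant thresholds are expressed in RFU on the raw scale but
#' are applied on log10 intensities (with zeros floored at `pseudo_count`);
#' `calibrate_gates()` re-places them at the valley of the pooled
#' log-intensity densities inside the configured search windows (log10 RFU).
#'
#' @param gradient_rms_min Focus gate: events below are out of focus.
#' @param area_min_um2,area_max_um2 Singles gate area window (µm²); below
#'   the window is shape-classified debris, above is an aggregate.
#' @param aspect_ratio_min Singles gate: events less round than this are
#'   aggregates.
#' @param t_rsg RSG positivity threshold (RFU).
#' @param t_pi PI positivity threshold (RFU).
#' @param t_mid RSG threshold splitting the PI-positive double-positives
#'   into mid-active I (below) and mid-active II (at or above), RFU.
#' @param pseudo_count Intensity floor applied before the log10 transform.
#' @param rsg_window,pi_window,mid_window Calibration search windows
#'   (log10 RFU) for `t_rsg`, `t_pi` and `t_mid`.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(gradient_rms_min = 0.2,
                        area_min_um2 = 0.3, area_max_um2 = 1.4,
                        aspect_ratio_min = 0.4,
                        t_rsg = 10^1.45, t_pi = 10^1.75, t_mid = 10^2.55,
                        pseudo_count = 0.1,
                        rsg_window = c(1.2, 1.8),
                        pi_window = c(1.4, 2.2),
                        mid_window = c(2.3, 2.85)) {
  if (area_min_um2 >= area_max_um2) {
    abort("`area_min_um2` must be < `area_max_um2`.",
          class = "ifcgate_validation_error")
  }
  for (v in list(t_rsg, t_pi, t_mid, pseudo_count)) {
    if (!is.finite(v) || v <= 0) {
      abort("Quadrant thresholds and pseudo_count must be finite and > 0.",
            class = "ifcgate_validation_error")
    }
  }
  structure(list(gradient_rms_min = gradient_rms_min,
                 area_min_um2 = area_min_um2, area_max_um2 = area_max_um2,
                 aspect_ratio_min = aspect_ratio_min,
                 t_rsg = t_rsg, t_pi = t_pi, t_mid = t_mid,
                 pseudo_count = pseudo_count,
                 rsg_window = rsg_window, pi_window = pi_window,
                 mid_window = mid_window),
            class = "gate_config")
}

require_columns <- function(table, cols) {
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    abort(paste0("Event table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ifcgate_schema_error")
  }
}

# rows still in play: not yet flagged by an earlier gate, not excluded
gate_open <- function(table) {
  if (!"gate_excluded" %in% names(table)) table$gate_excluded <- FALSE
  table
}

open_rows <- function(table) {
  table$assigned_label == "unclassified" & !table$gate_excluded
}

#' Focus gate
#'
#' Flags events whose brightfield gradient RMS falls below
#' `gradient_rms_min` as `out_of_focus`. Events with an undefined gradient
#' RMS are excluded from further gating and stay `unclassified`.
#'
#' @param table An event table with a `gradient_rms` column.
#' @param config A [gate_config()].
#' @return The table with `assigned_label` updated.
#' @export
gate_focus <- function(table, config) {
  require_columns(table, "gradient_rms")
  table <- gate_open(table)
  open <- open_rows(table)
  na_feat <- open & !is.finite(table$gradient_rms)
  table$gate_excluded[na_feat] <- TRUE
  hit <- open & !na_feat & table$gradient_rms < config$gradient_rms_min
  table$assigned_label[hit] <- "out_of_focus"
  table
}

#' Singles gate
#'
#' Shape/size gate on brightfield morphology: events larger than
#' `area_max_um2` or less round than `aspect_ratio_min` are flagged as
#' aggregates; events smaller than `area_min_um2` are shape-classified
#' debris. The rest pass as single-cell candidates.
#'
#' @param table An event table with `area_um2` and `aspect_ratio` columns.
#' @param config A [gate_config()].
#' @return The table with `assigned_label` updated.
#' @export
gate_singles <- function(table, config) {
  require_columns(table, c("area_um2", "aspect_ratio"))
  table <- gate_open(table)
  open <- open_rows(table)
  na_feat <- open & (!is.finite(table$area_um2) | !is.finite(table$aspect_ratio))
  table$gate_excluded[na_feat] <- TRUE
  open <- open & !na_feat
  agg <- open & (table$area_um2 > config$area_max_um2 |
                   table$aspect_ratio < config$aspect_ratio_min)
  table$assigned_label[agg] <- "aggregate"
  small <- open & !agg & table$area_um2 < config$area_min_um2
  table$assigned_label[small] <- "debris"
  table
}

#' Classifier gate
#'
#' Applies the trained cells-vs-debris discriminant to the events that
#' passed the focus and singles gates. Events scoring at or below 0 (debris
#' orientation) are flagged `debris`; positive scores pass as cells. Events
#' with undefined features are excluded and stay `unclassified`.
#'
#' @param table An event table carrying the model's feature columns.
#' @param model An `ifc_classifier`.
#' @return The table with `assigned_label` and `classifier_score` updated.
#' @export
gate_cells <- function(table, model) {
  table <- gate_open(table)
  if (nrow(table) == 0L) {
    table$classifier_score <- numeric(0)
    return(table)
  }
  s <- classifier_scores(model, table)
  table$classifier_score <- s
  open <- open_rows(table)
  na_feat <- open & is.na(s)
  table$gate_excluded[na_feat] <- TRUE
  hit <- open & !na_feat & s <= 0
  table$assigned_label[hit] <- "debris"
  table
}

#' Quadrant assignment into the four physiological subpopulations
#'
#' Among events that passed all morphological gates, assigns labels from the
#' log10 RSG/PI plane: RSG-positive/PI-negative events are `active`;
#' RSG-negative/PI-positive events are `dead`; double-positive events are
#' split at `t_mid` into `mid_active_2` (RSG at or above, the higher
#' metabolic activity) and `mid_active_1` (below); double-negative events
#' stay `unclassified`.
#'
#' @param table An event table with `rsg_intensity`, `pi_intensity`.
#' @param config A [gate_config()] providing `t_rsg`, `t_pi`, `t_mid`.
#' @return The table with subpopulation labels assigned.
#' @export
assign_subpopulations <- function(table, config) {
  require_columns(table, c("rsg_intensity", "pi_intensity"))
  if (is.null(config$t_rsg) || is.null(config$t_pi) || is.null(config$t_mid)) {
    abort("Gate config lacks quadrant thresholds.",
          class = "ifcgate_config_error")
  }
  table <- gate_open(table)
  open <- open_rows(table)
  lr <- log10(pmax(table$rsg_intensity, config$pseudo_count))
  lp <- log10(pmax(table$pi_intensity, config$pseudo_count))
  rsg_pos <- lr > log10(config$t_rsg)
  pi_pos <- lp > log10(config$t_pi)
  lab <- table$assigned_label
  lab[open & rsg_pos & !pi_pos] <- "active"
  lab[open & !rsg_pos & pi_pos] <- "dead"
  lab[open & rsg_pos & pi_pos & lr >= log10(config$t_mid)] <- "mid_active_2"
  lab[open & rsg_pos & pi_pos & lr < log10(config$t_mid)] <- "mid_active_1"
  table$assigned_label <- lab
  table
}

#' Calibrate gate thresholds from the data
#'
#' Histogram-based threshold placement. Quadrant thresholds are moved to the
#' minimum-density point of the pooled log10 intensity distributions inside
#' the configured search windows: `t_pi` from the PI density of all open
#' events, `t_rsg` from the RSG density, and `t_mid` from the RSG density of
#' the double-positive events. Subsets with fewer than `min_n` events keep
#' the current threshold. With `focus = TRUE`, `gradient_rms_min` is set by
#' Otsu's method on the gradient RMS histogram (use only when a defocused
#' mode is actually present).
#'
#' @param table An event table (ideally after the morphological gates).
#' @param config A [gate_config()] to update.
#' @param focus Also calibrate the focus threshold (Otsu).
#' @param min_n Minimum subset size for a density estimate.
#' @return The updated `gate_config`.
#' @export
calibrate_gates <- function(table, config, focus = FALSE, min_n = 50L) {
  table <- gate_open(table)
  open <- open_rows(table)
  lr <- log10(pmax(table$rsg_intensity[open], config$pseudo_count))
  lp <- log10(pmax(table$pi_intensity[open], config$pseudo_count))
  t_pi <- 10^density_valley(lp, config$pi_window, log10(config$t_pi), min_n)
  t_rsg <- 10^density_valley(lr, config$rsg_window, log10(config$t_rsg), min_n)
  dp <- lp > log10(t_pi) & lr > log10(t_rsg)
  t_mid <- 10^density_valley(lr[dp], config$mid_window, log10(config$t_mid),
                             min_n)
  config$t_pi <- t_pi
  config$t_rsg <- t_rsg
  config$t_mid <- t_mid
  if (focus) {
    require_columns(table, "gradient_rms")
    g <- table$gradient_rms[is.finite(table$gradient_rms)]
    config$gradient_rms_min <- otsu_threshold(g)
  }
  config
}

#' Run the full gating chain
#'
#' Applies the gates in their canonical order — (i) focus, (ii) singles,
#' (iii) cells-vs-debris classifier, (iv) RSG/PI quadrants — optionally
#' recalibrating the quadrant thresholds on the events that survive the
#' morphological gates. Every event ends up with exactly one label.
#'
#' @param table An event table with the required feature columns.
#' @param config A [gate_config()].
#' @param model An `ifc_classifier`, or `NULL` to skip the classifier gate.
#' @param calibrate Recalibrate quadrant thresholds before assignment.
#' @return The labelled table, with the (possibly calibrated) `gate_config`
#'   attached as attribute `"gate_config"`.
#' @export
apply_gates <- function(table, config = gate_config(), model = NULL,
                        calibrate = TRUE) {
  table <- gate_focus(table, config)
  table <- gate_singles(table, config)
  if (!is.null(model)) table <- gate_cells(table, model)
  if (calibrate) config <- calibrate_gates(table, config)
  table <- assign_subpopulations(table, config)
  attr(table, "gate_config") <- config
  table
}

#' Subpopulation summary
#'
#' Per-replicate counts and percentages for every label, plus the
#' mean ± sample SD of the percentages across replicates. With denominator
#' `"all_events"` the eight label percentages sum to 100 within each
#' replicate; with `"gated_cells"` percentages are relative to the events
#' that reached quadrant assignment (the four subpopulations plus
#' double-negative unclassified events that passed all gates — flagged
#' debris, aggregates, out-of-focus and excluded events are dropped from the
#' denominator).
#'
#' @param table A labelled event table.
#' @param denominator `"all_events"` or `"gated_cells"`.
#' @return An object of class `subpop_summary` with elements
#'   `per_replicate` (tibble), `summary` (mean/SD across replicates),
#'   `denominator`, `n_replicates`.
#' @export
summarize_subpopulations <- function(table,
                                     denominator = c("all_events",
                                                     "gated_cells")) {
  denominator <- match.arg(denominator)
  table <- gate_open(table)
  labs <- event_labels()
  per <- lapply(split(table, table$replicate_id), function(d) {
    denom <- if (denominator == "all_events") {
      nrow(d)
    } else {
      sum(d$assigned_label %in% c("active", "mid_active_1", "mid_active_2",
                                  "dead") |
            (d$assigned_label == "unclassified" & !d$gate_excluded))
    }
    counts <- vapply(labs, function(l) sum(d$assigned_label == l), integer(1))
    tibble::tibble(replicate_id = d$replicate_id[1], label = labs,
                   count = counts,
                   percent = if (denom > 0) 100 * counts / denom else NA_real_,
                   denom = denom)
  })
  per <- dplyr::bind_rows(per)
  n_rep <- length(unique(per$replicate_id))
  summary <- per |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      count = sum(.data$count),
      mean_percent = mean(.data$percent),
      sd_percent = if (n_rep >= 2) stats::sd(.data$percent) else NA_real_,
      .groups = "drop"
    )
  structure(list(per_replicate = per, summary = summary,
                 denominator = denominator, n_replicates = n_rep,
                 n_events = nrow(table)),
            class = "subpop_summary")
}

#' @export
print.subpop_summary <- function(x, ...) {
  cat(sprintf("<subpop_summary> %d events, %d replicate(s), denominator: %s\n",
              x$n_events, x$n_replicates, x$denominator))
  print(x$summary)
  invisible(x)
}

#' RSG/PI scatter plot with gate overlays
#'
#' Log10 RSG vs PI scatter of a labelled event table with the quadrant
#' thresholds drawn as gate lines.
#'
#' @param table A labelled event table.
#' @param config A [gate_config()] (defaults to the one attached by
#'   [apply_gates()]).
#' @param max_points Subsample cap for plotting.
#' @return A ggplot object.
#' @export
plot_gates <- function(table, config = NULL, max_points = 20000L) {
  config <- config %||% attr(table, "gate_config") %||% gate_config()
  if (nrow(table) > max_points) {
    table <- table[seq(1, nrow(table), length.out = max_points), ]
  }
  df <- tibble::tibble(
    rsg = log10(pmax(table$rsg_intensity, config$pseudo_count)),
    pi = log10(pmax(table$pi_intensity, config$pseudo_count)),
    label = table$assigned_label
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rsg, y = .data$pi,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_vline(xintercept = log10(config$t_rsg), linetype = 2) +
    ggplot2::geom_vline(xintercept = log10(config$t_mid), linetype = 3) +
    ggplot2::geom_hline(yintercept = log10(config$t_pi), linetype = 2) +
    ggplot2::labs(x = "log10 RSG intensity (RFU)",
                  y = "log10 PI intensity (RFU)", colour = "label") +
    ggplot2::theme_minimal()
}
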