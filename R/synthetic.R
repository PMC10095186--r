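#' Default bivariate log-normal fluorescence parameters
#'
#' Per-class parameters of the bivariate log-normal RSG/PI intensity model,
#' on the log10 RFU scale: `mu_rsg`, `mu_pi` (centers), `sd_rsg`, `sd_pi`
#' (spreads) and `rho` (correlation). The class geometry follows the
#' dual-stain semantics: active cells are RSG-high/PI-low, dead cells
#' RSG-low/PI-high, the two mid-active classes are PI-positive with an RSG
#' level that is higher for mid-active II than mid-active I, and debris is
#' dim on average but broad in both channels (stained fragments and
#' autofluorescent particles reach into the positive quadrants, which is
#' why debris removal cannot rely on fluorescence alone). Numeric centers are a
#' documented calibration choice (no published values exist), not constants
#' of nature; override any entry to study other geometries.
#'
#' @return A named list of per-class parameter lists.
#' @export
default_intensity_params <- function() {
  list(
    active       = list(mu_rsg = 3.6, mu_pi = 0.9, sd_rsg = 0.15, sd_pi = 0.20, rho = 0.1),
    mid_active_1 = list(mu_rsg = 2.0, mu_pi = 2.6, sd_rsg = 0.15, sd_pi = 0.18, rho = 0.2),
    mid_active_2 = list(mu_rsg = 3.1, mu_pi = 2.6, sd_rsg = 0.15, sd_pi = 0.18, rho = 0.2),
    dead         = list(mu_rsg = 0.9, mu_pi = 3.3, sd_rsg = 0.15, sd_pi = 0.18, rho = 0.1),
    debris       = list(mu_rsg = 0.8, mu_pi = 1.2, sd_rsg = 0.50, sd_pi = 0.50, rho = 0.1)
  )
}

#' Default label-conditional feature distributions
#'
#' Parameters of the per-event feature distributions emitted by
#' [sample_events()]: focus quality (gradient RMS) for in-focus and defocused
#' events, and brightfield/fluorescence texture summaries for single cells
#' versus non-cellular debris. Debris carries higher co-occurrence entropy
#' and entropy/homogeneity spread than cells (irregular, grainy objects),
#' which is what the cells-vs-debris classifier exploits.
#'
#' @return A named list with elements `cell`, `debris`, `defocus`.
#' @export
default_feature_params <- function() {
  list(
    cell = list(
      gradient_rms = c(0.55, 0.08),
      h_entropy_mean_bf = c(2.20, 0.15), h_entropy_std_bf = c(0.25, 0.05),
      h_homogeneity_mean_bf = c(0.75, 0.04), h_homogeneity_std_bf = c(0.050, 0.012),
      h_entropy_mean_rsg = c(2.00, 0.15), h_entropy_std_rsg = c(0.22, 0.05)
    ),
    debris = list(
      gradient_rms = c(0.45, 0.15),
      h_entropy_mean_bf = c(3.00, 0.30), h_entropy_std_bf = c(0.80, 0.12),
      h_homogeneity_mean_bf = c(0.50, 0.08), h_homogeneity_std_bf = c(0.150, 0.030),
      h_entropy_mean_rsg = c(2.80, 0.30), h_entropy_std_rsg = c(0.75, 0.12),
      area_meanlog = log(0.7), area_sdlog = 0.5,
      aspect_range = c(0.3, 1.0)
    ),
    defocus = list(gradient_rms = c(0.07, 0.025))
  )
}

#' Mixture specification for the synthetic event generator
#'
#' Ground truth of a simulated acquisition: class fractions, per-class
#' bivariate log-normal RSG/PI parameters, feature distribution parameters,
#' and the nominal cell concentration. Fractions may be given for any subset
#' of `active`, `mid_active_1`, `mid_active_2`, `dead`, `debris`,
#' `aggregate`, `out_of_focus`; they must each lie in \[0, 1\] and sum to at
#' most 1. Any remainder is added to the debris fraction (events outside the
#' four physiological groups are non-cellular or otherwise unclassifiable).
#'
#' @param fractions Named numeric vector of class fractions.
#' @param intensity_params Per-class fluorescence parameters, see
#'   [default_intensity_params()].
#' @param feature_params Feature distribution parameters, see
#'   [default_feature_params()].
#' @param concentration Nominal concentration (objects/mL) represented by the
#'   simulated sample.
#' @param n_replicates Number of replicates the generator should emulate.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(fractions = c(active = 0.6, mid_active_1 = 0.01,
                                       mid_active_2 = 0.18, dead = 0.09),
                         intensity_params = default_intensity_params(),
                         feature_params = default_feature_params(),
                         concentration = 1e8,
                         n_replicates = 1L) {
  known <- c("active", "mid_active_1", "mid_active_2", "dead",
             "debris", "aggregate", "out_of_focus")
  if (is.null(names(fractions)) || !all(names(fractions) %in% known)) {
    abort(paste0("`fractions` must be named with classes among: ",
                 paste(known, collapse = ", ")))
  }
  if (any(fractions < 0 | fractions > 1)) {
    abort("All fractions must lie in [0, 1].", class = "ifcgate_validation_error")
  }
  if (sum(fractions) > 1 + 1e-9) {
    abort("Fractions must sum to at most 1.", class = "ifcgate_validation_error")
  }
  f <- setNames(numeric(length(known)), known)
  f[names(fractions)] <- fractions
  f["debris"] <- f["debris"] + max(0, 1 - sum(f))
  for (p in intensity_params) {
    if (p$sd_rsg <= 0 || p$sd_pi <= 0 || abs(p$rho) >= 1) {
      abort("Intensity params require sd > 0 and |rho| < 1.",
            class = "ifcgate_validation_error")
    }
  }
  stopifnot_scalar_number(concentration, "concentration")
  structure(list(fractions = f,
                 intensity_params = intensity_params,
                 feature_params = feature_params,
                 concentration = concentration,
                 n_replicates = as.integer(n_replicates)),
            class = "mixture_spec")
}

#' Cell and artifact shape specification
#'
#' Morphological ground truth for the generator: cell length/width
#' distributions (µm), the aggregate size distribution (`k = 2 +
#' Poisson(aggregate_lambda)` member cells) and the defocus blur range
#' (Gaussian sigma, µm). Defaults describe a slightly elongated
#' coccobacillus, the typical LAB morphology.
#'
#' @param morphology `"coccus"` or `"rod"`.
#' @param length_mean,length_sd Cell length distribution (µm).
#' @param width_mean,width_sd Cell width distribution (µm).
#' @param aggregate_lambda Poisson rate of extra aggregate members beyond 2.
#' @param defocus_sigma_um Range of the defocus blur sigma (µm).
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(morphology = c("coccus", "rod"),
                       length_mean = 1.3, length_sd = 0.10,
                       width_mean = 0.8, width_sd = 0.06,
                       aggregate_lambda = 1.0,
                       defocus_sigma_um = c(1.0, 2.0)) {
  morphology <- match.arg(morphology)
  if (morphology == "rod") {
    # rods are longer relative to their width
    if (missing(length_mean)) length_mean <- 2.2
    if (missing(length_sd)) length_sd <- 0.25
  }
  if (length_mean < width_mean) {
    abort("Cell length must be >= width.", class = "ifcgate_validation_error")
  }
  if (width_mean <= 0) abort("Cell width must be > 0.",
                             class = "ifcgate_validation_error")
  structure(list(morphology = morphology,
                 length_mean = length_mean, length_sd = length_sd,
                 width_mean = width_mean, width_sd = width_sd,
                 aggregate_lambda = aggregate_lambda,
                 defocus_sigma_um = defocus_sigma_um),
            class = "shape_spec")
}

#' Build a mixture specification from a reference composition
#'
#' Looks up the published subpopulation percentages for a strain/treatment
#' combination in [reference_compositions()] and returns a [mixture_spec()]
#' whose four subpopulation fractions equal those percentages divided by
#' 100, with the remainder assigned to debris.
#'
#' @param strain One of `"E_faecium"`, `"L_mesenteroides"`, `"C_divergens"`.
#' @param treatment One of `"control"`, `"heat_shock"`, `"ph_shock"`,
#'   `"uncontrolled_ph"`, `"dried"`, `"coated"`.
#' @param ... Passed on to [mixture_spec()].
#' @return A `mixture_spec` object.
#' @export
composition_mixture_spec <- function(strain, treatment, ...) {
  comp <- reference_compositions()
  comp <- comp[comp$strain == strain & comp$treatment == treatment, ]
  if (nrow(comp) != 4L) {
    abort(sprintf("No reference composition for strain '%s', treatment '%s'.",
                  strain, treatment))
  }
  fr <- setNames(comp$percent / 100, comp$subpopulation)
  mixture_spec(fractions = fr, ...)
}

cell_classes <- function() c("active", "mid_active_1", "mid_active_2", "dead")

# draw bivariate log-normal RSG/PI intensities for n events of one class
draw_intensities <- function(n, p) {
  z <- rbinorm(n, p$rho)
  cbind(rsg = 10^(p$mu_rsg + p$sd_rsg * z[, 1]),
        pi  = 10^(p$mu_pi + p$sd_pi * z[, 2]))
}

rnorm2 <- function(n, ms) pmax(stats::rnorm(n, ms[1], ms[2]), 1e-4)

# label-conditional feature draws for n events that look like single cells
draw_cell_features <- function(n, shape, fp) {
  len <- pmax(stats::rnorm(n, shape$length_mean, shape$length_sd), 0.2)
  wid <- pmax(stats::rnorm(n, shape$width_mean, shape$width_sd), 0.1)
  wid <- pmin(wid, len)
  tibble::tibble(
    gradient_rms = rnorm2(n, fp$cell$gradient_rms),
    area_um2 = pi / 4 * len * wid,
    aspect_ratio = wid / len,
    major_axis_um = len,
    major_axis_intensity_um = len * stats::rnorm(n, 1.0, 0.05),
    h_entropy_mean_bf = rnorm2(n, fp$cell$h_entropy_mean_bf),
    h_entropy_std_bf = rnorm2(n, fp$cell$h_entropy_std_bf),
    h_homogeneity_mean_bf = pmin(rnorm2(n, fp$cell$h_homogeneity_mean_bf), 1),
    h_homogeneity_std_bf = pmin(rnorm2(n, fp$cell$h_homogeneity_std_bf), 1),
    h_entropy_mean_rsg = rnorm2(n, fp$cell$h_entropy_mean_rsg),
    h_entropy_std_rsg = rnorm2(n, fp$cell$h_entropy_std_rsg)
  )
}

draw_debris_features <- function(n, fp) {
  d <- fp$debris
  tibble::tibble(
    gradient_rms = rnorm2(n, d$gradient_rms),
    area_um2 = stats::rlnorm(n, d$area_meanlog, d$area_sdlog),
    aspect_ratio = stats::runif(n, d$aspect_range[1], d$aspect_range[2]),
    major_axis_um = sqrt(stats::rlnorm(n, d$area_meanlog, d$area_sdlog)) * 1.5,
    major_axis_intensity_um = stats::rlnorm(n, 0, 0.4),
    h_entropy_mean_bf = rnorm2(n, d$h_entropy_mean_bf),
    h_entropy_std_bf = rnorm2(n, d$h_entropy_std_bf),
    h_homogeneity_mean_bf = pmin(rnorm2(n, d$h_homogeneity_mean_bf), 1),
    h_homogeneity_std_bf = pmin(rnorm2(n, d$h_homogeneity_std_bf), 1),
    h_entropy_mean_rsg = rnorm2(n, d$h_entropy_mean_rsg),
    h_entropy_std_rsg = rnorm2(n, d$h_entropy_std_rsg)
  )
}

#' Sample a ground-truth-labelled synthetic event table
#'
#' Draws `n` events from the mixture: each event's true class is multinomial
#' in the mixture fractions; RSG/PI intensities follow the class's bivariate
#' log-normal; feature columns follow the label-conditional feature
#' distributions. Aggregates sum the intensities (and areas) of `k >= 2`
#' member cells drawn from the cell-class mixture; defocused events are
#' cells with a degraded gradient RMS. Identical `(spec, shape, n, seed)`
#' give identical tables.
#'
#' @param spec A [mixture_spec()].
#' @param shape A [shape_spec()].
#' @param n Number of events (>= 1).
#' @param seed Integer RNG seed.
#' @param replicate_id Replicate identifier stored in the table.
#' @return A validated event table with `true_label` ground truth.
#' @export
sample_events <- function(spec, shape = shape_spec(), n, seed = 1L,
                          replicate_id = 1L) {
  stopifnot(inherits(spec, "mixture_spec"), inherits(shape, "shape_spec"))
  if (n < 1) abort("`n` must be >= 1.")
  with_seed(seed, {
    classes <- sample(names(spec$fractions), n, replace = TRUE,
                      prob = spec$fractions)
    fp <- spec$feature_params
    ip <- spec$intensity_params
    out <- vector("list", length(unique(classes)))
    names(out) <- unique(classes)
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      m <- length(idx)
      if (cl %in% cell_classes()) {
        feats <- draw_cell_features(m, shape, fp)
        ints <- draw_intensities(m, ip[[cl]])
      } else if (cl == "debris") {
        feats <- draw_debris_features(m, fp)
        ints <- draw_intensities(m, ip[["debris"]])
      } else if (cl == "out_of_focus") {
        # defocused cells: draw an underlying cell class, degrade focus
        sub <- spec$fractions[cell_classes()]
        sub <- if (sum(sub) > 0) sub / sum(sub) else
          setNames(rep(0.25, 4), cell_classes())
        member <- sample(cell_classes(), m, replace = TRUE, prob = sub)
        feats <- draw_cell_features(m, shape, fp)
        feats$gradient_rms <- rnorm2(m, fp$defocus$gradient_rms)
        ints <- do.call(rbind, lapply(seq_len(m), function(i)
          draw_intensities(1L, ip[[member[i]]])))
      } else { # aggregate
        k <- 2L + stats::rpois(m, shape$aggregate_lambda)
        sub <- spec$fractions[cell_classes()]
        sub <- if (sum(sub) > 0) sub / sum(sub) else
          setNames(rep(0.25, 4), cell_classes())
        total <- sum(k)
        member <- sample(cell_classes(), total, replace = TRUE, prob = sub)
        grp <- rep(seq_len(m), times = k)
        mi <- matrix(0, total, 2)
        for (mc in unique(member)) {
          w <- which(member == mc)
          mi[w, ] <- draw_intensities(length(w), ip[[mc]])
        }
        ints <- cbind(rsg = rowsum(mi[, 1], grp)[, 1],
                      pi = rowsum(mi[, 2], grp)[, 1])
        base <- draw_cell_features(total, shape, fp)
        feats <- draw_cell_features(m, shape, fp)
        feats$area_um2 <- rowsum(base$area_um2, grp)[, 1] * stats::runif(m, 0.9, 1.0)
        feats$aspect_ratio <- stats::runif(m, 0.25, 0.70)
        feats$major_axis_um <- sqrt(feats$area_um2 / (pi / 4) /
                                      feats$aspect_ratio)
        feats$major_axis_intensity_um <- feats$major_axis_um *
          stats::rnorm(m, 1.0, 0.05)
      }
      out[[cl]] <- dplyr::bind_cols(
        tibble::tibble(.idx = idx, true_label = cl,
                       rsg_intensity = ints[, 1], pi_intensity = ints[, 2]),
        feats)
    }
    tab <- dplyr::arrange(dplyr::bind_rows(out), .data$.idx)
    tab$.idx <- NULL
    tab <- dplyr::bind_cols(tibble::tibble(event_id = seq_len(n)), tab)
    tab$assigned_label <- "unclassified"
    tab$replicate_id <- as.integer(replicate_id)
    event_table(tab)
  })
}

#' Sample replicate acquisitions
#'
#' Convenience wrapper drawing `spec$n_replicates` independent tables with
#' derived seeds and distinct `replicate_id`s.
#'
#' @inheritParams sample_events
#' @param n Events per replicate.
#' @return A single event table with unique `event_id` across replicates.
#' @export
sample_replicates <- function(spec, shape = shape_spec(), n, seed = 1L) {
  reps <- lapply(seq_len(spec$n_replicates), function(r) {
    tab <- sample_events(spec, shape, n, seed = seed + r - 1L,
                         replicate_id = r)
    tab$event_id <- tab$event_id + (r - 1L) * n
    tab
  })
  event_table(dplyr::bind_rows(reps))
}

#' Simulate a decimal-dilution plate count series
#'
#' Colony counts per plate are Poisson with mean
#' `concentration * efficiency * 10^exponent * plated_volume_ml`, the
#' sampling model of serial decimal dilution followed by pour plating.
#' `efficiency < 1` emulates plate-count underestimation of viable cells.
#'
#' @param viable_concentration Viable concentration (cfu/mL), >= 0.
#' @param dilution_exponents Integer dilution exponents (e.g. `-(1:9)`).
#' @param plated_volume_ml Volume plated per dish (mL).
#' @param seed Integer RNG seed.
#' @param efficiency Plating efficiency in (0, 1].
#' @return A tibble of class `plate_series` with columns
#'   `dilution_exponent`, `colonies`, `plated_volume_ml`.
#' @export
simulate_plating <- function(viable_concentration, dilution_exponents = -(1:9),
                             plated_volume_ml = 1, seed = 1L, efficiency = 1) {
  if (viable_concentration < 0) abort("Concentration must be >= 0.")
  if (efficiency <= 0 || efficiency > 1) abort("`efficiency` must be in (0, 1].")
  stopifnot_scalar_number(plated_volume_ml, "plated_volume_ml", positive = TRUE)
  lambda <- viable_concentration * efficiency * 10^dilution_exponents *
    plated_volume_ml
  counts <- with_seed(seed, stats::rpois(length(lambda), lambda))
  out <- tibble::tibble(dilution_exponent = as.integer(dilution_exponents),
                        colonies = as.integer(counts),
                        plated_volume_ml = plated_volume_ml)
  class(out) <- c("plate_series", class(out))
  out
}

#' Simulate single-cell sorting growth outcomes
#'
#' Each of `n_cells` sorted cells per subpopulation and medium grows with its
#' subpopulation's probability. Growing broth wells follow a logistic OD600
#' trajectory after a random exponential lag, so some wells cross the
#' detection threshold only between the 48 h and 72 h reads; colonies on agar
#' become countable under the same lag model. Measured OD600 includes the
#' sterile-medium blank, which [growth_percentages()] subtracts before
#' thresholding.
#'
#' @param growth_prob Named per-subpopulation growth probabilities (applied
#'   to both media), or a data frame with columns `subpopulation`, `medium`,
#'   `prob`.
#' @param n_cells Cells sorted per subpopulation and medium (default 24).
#' @param od_model Logistic growth parameters: carrying capacity `K`, rate
#'   `r` (1/h), initial OD `od0`, mean lag `lag_mean` (h), sterile blank
#'   `blank`.
#' @param seed Integer RNG seed.
#' @return An object of class `sorting_outcome`: list with the per-cell
#'   tibble `cells`, `n_sorted`, `od_blank` and `od_threshold`.
#' @export
simulate_sorting <- function(growth_prob, n_cells = 24L,
                             od_model = list(K = 1.2, r = 0.25, od0 = 0.005,
                                             lag_mean = 20, blank = 0.04),
                             seed = 1L) {
  if (is.data.frame(growth_prob)) {
    gp <- tibble::as_tibble(growth_prob)
    stopifnot(all(c("subpopulation", "medium", "prob") %in% names(gp)))
  } else {
    if (is.null(names(growth_prob))) abort("`growth_prob` must be named.")
    gp <- tidyr::expand_grid(subpopulation = names(growth_prob),
                             medium = c("agar", "broth"))
    gp$prob <- growth_prob[gp$subpopulation]
  }
  if (any(gp$prob < 0 | gp$prob > 1)) {
    abort("Growth probabilities must lie in [0, 1].",
          class = "ifcgate_validation_error")
  }
  od_at <- function(t, lag) {
    grown <- pmax(t - lag, 0)
    od <- od_model$K /
      (1 + (od_model$K - od_model$od0) / od_model$od0 * exp(-od_model$r * grown))
    ifelse(t > lag, od, od_model$od0)
  }
  with_seed(seed, {
    cells <- gp[rep(seq_len(nrow(gp)), each = n_cells), ]
    cells$cell <- rep(seq_len(n_cells), times = nrow(gp))
    m <- nrow(cells)
    cells$grew <- stats::rbinom(m, 1L, cells$prob) == 1L
    cells$lag_h <- 10 + stats::rexp(m, 1 / od_model$lag_mean)
    noise <- function(n) stats::rnorm(n, 0, 0.003)
    od48 <- ifelse(cells$grew, od_at(48, cells$lag_h), 0)
    od72 <- ifelse(cells$grew, od_at(72, cells$lag_h), 0)
    cells$od600_48h <- ifelse(cells$medium == "broth",
                              od_model$blank + od48 + noise(m), NA_real_)
    cells$od600_72h <- ifelse(cells$medium == "broth",
                              od_model$blank + od72 + noise(m), NA_real_)
    # a colony is countable once its virtual OD would exceed the threshold
    cells$colony_48h <- cells$medium == "agar" & cells$grew & od48 > 0.1
    cells$colony_72h <- cells$medium == "agar" & cells$grew & od72 > 0.1
    cells$prob <- NULL
    structure(list(cells = cells, n_sorted = as.integer(n_cells),
                   od_blank = od_model$blank, od_threshold = 0.1),
              class = "sorting_outcome")
  })
}
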