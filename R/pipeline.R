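#' Sample truth populations for classifier training
#'
#' Draws exemplar cells (the mixture's cell classes, debris-free) and
#' exemplar debris from the generator, emulating the manual tagging of small
#' truth populations on real data.
#'
#' @param spec A [mixture_spec()]; its cell-class proportions condition the
#'   cell truth draw.
#' @param shape A [shape_spec()].
#' @param n_per_class Events per truth class (default 32).
#' @param seed Integer RNG seed.
#' @return A [truth_set()].
#' @export
sample_truth_set <- function(spec, shape = shape_spec(), n_per_class = 32L,
                             seed = 1L) {
  cf <- spec$fractions[cell_classes()]
  cf <- if (sum(cf) > 0) cf / sum(cf) else
    setNames(rep(0.25, 4), cell_classes())
  cell_spec <- mixture_spec(fractions = cf,
                            intensity_params = spec$intensity_params,
                            feature_params = spec$feature_params)
  debris_spec <- mixture_spec(fractions = c(debris = 1),
                              intensity_params = spec$intensity_params,
                              feature_params = spec$feature_params)
  truth_set(
    cells = sample_events(cell_spec, shape, n_per_class, seed = seed),
    debris = sample_events(debris_spec, shape, n_per_class, seed = seed + 1L)
  )
}

#' End-to-end recovery of a mixture composition
#'
#' The standard synthetic benchmark: simulate an acquisition from a mixture
#' spec, train the cells-vs-debris classifier on freshly drawn truth
#' populations, run the full gate chain with histogram-calibrated quadrant
#' thresholds, and summarize the recovered subpopulation percentages of all
#' acquired events.
#'
#' @param spec A [mixture_spec()].
#' @param n_events Number of events to simulate.
#' @param seed Integer RNG seed (truth-set and classifier seeds are derived
#'   from it).
#' @param shape A [shape_spec()].
#' @param config A [gate_config()] starting point.
#' @param calibrate Recalibrate quadrant thresholds from the data.
#' @return A list with the labelled `table`, the `summary`
#'   (all-events denominator), the calibrated `config`, the trained
#'   `model`, and `recovered`, the named percentages of the four
#'   subpopulations.
#' @export
recover_composition <- function(spec, n_events = 20000L, seed = 1L,
                                shape = shape_spec(),
                                config = gate_config(), calibrate = TRUE) {
  truth <- sample_truth_set(spec, shape, seed = seed + 1000L)
  model <- train_classifier(truth, classifier_features(), k = 7L)
  tab <- sample_events(spec, shape, n_events, seed = seed)
  tab <- apply_gates(tab, config, model, calibrate = calibrate)
  summ <- summarize_subpopulations(tab, denominator = "all_events")
  rec <- summ$summary
  recovered <- setNames(rec$mean_percent, rec$label)[
    c("active", "mid_active_1", "mid_active_2", "dead")]
  list(table = tab, summary = summ, config = attr(tab, "gate_config"),
       model = model, recovered = recovered)
}

#' Recovery benchmark against a published composition
#'
#' Convenience wrapper: build the mixture from
#' [composition_mixture_spec()], run [recover_composition()], and return
#' the recovered percentages next to the configured (published) ones.
#'
#' @inheritParams composition_mixture_spec
#' @inheritParams recover_composition
#' @return A list as in [recover_composition()], plus `configured`, the
#'   published percentages used as simulation ground truth.
#' @export
recover_reference_composition <- function(strain, treatment,
                                          n_events = 20000L, seed = 1L, ...) {
  spec <- composition_mixture_spec(strain, treatment)
  out <- recover_composition(spec, n_events = n_events, seed = seed, ...)
  comp <- reference_compositions()
  comp <- comp[comp$strain == strain & comp$treatment == treatment, ]
  out$configured <- setNames(comp$percent, comp$subpopulation)[
    names(out$recovered)]
  out
}
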