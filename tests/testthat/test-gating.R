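test_that("the focus gate flags defocused events and is monotone", {
  spec <- mixture_spec(fractions = c(active = 0.9, out_of_focus = 0.1))
  tab <- sample_events(spec, shape_spec(), 5000L, seed = 51L)

  # vacuous gate
  g0 <- gate_focus(tab, gate_config(gradient_rms_min = 0))
  expect_true(!any(g0$assigned_label == "out_of_focus"))

  # Otsu-calibrated threshold catches >= 90% of truly defocused events
  cfg <- calibrate_gates(tab, gate_config(), focus = TRUE)
  g1 <- gate_focus(tab, cfg)
  oof <- tab$true_label == "out_of_focus"
  expect_gt(mean(g1$assigned_label[oof] == "out_of_focus"), 0.9)
  # and spares nearly all in-focus cells
  expect_lt(mean(g1$assigned_label[!oof] == "out_of_focus"), 0.02)

  # flagged fraction is non-decreasing in the threshold
  counts <- vapply(c(0, 0.05, 0.1, 0.3, 0.6, 1),
                   function(t) sum(gate_focus(tab,
                     gate_config(gradient_rms_min = t))$assigned_label ==
                       "out_of_focus"),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))

  expect_error(gate_focus(minimal_table(), gate_config()),
               class = "ifcgate_schema_error")
})

test_that("the singles gate separates single cells from aggregates", {
  singles <- sample_events(mixture_spec(fractions = c(active = 1)),
                           shape_spec(), 5000L, seed = 61L)
  # an area window at the generator's own 1st/99th percentiles flags ~2%
  cfg <- gate_config(area_min_um2 = quantile(singles$area_um2, 0.01),
                     area_max_um2 = quantile(singles$area_um2, 0.99),
                     aspect_ratio_min = 0)
  g <- gate_singles(singles, cfg)
  expect_lte(mean(g$assigned_label %in% c("aggregate", "debris")), 0.02)

  # true aggregates are flagged at >= 80% by the default gates
  mixed <- sample_events(mixture_spec(fractions = c(active = 0.5,
                                                    aggregate = 0.5)),
                         shape_spec(), 5000L, seed = 62L)
  g2 <- gate_singles(mixed, gate_config())
  agg <- mixed$true_label == "aggregate"
  expect_gt(mean(g2$assigned_label[agg] == "aggregate"), 0.8)

  # flagged set grows monotonically as area_max decreases
  flagged <- vapply(c(3, 2, 1.4, 1.0, 0.7), function(amax)
    sum(gate_singles(mixed, gate_config(area_max_um2 = amax))$assigned_label
        == "aggregate"), numeric(1))
  expect_true(all(diff(flagged) >= 0))
})

test_that("the classifier gate removes debris and its ablation hurts purity", {
  spec <- mixture_spec(fractions = c(active = 0.6, dead = 0.1, debris = 0.3))
  tab <- sample_events(spec, shape_spec(), 8000L, seed = 71L)
  model <- train_classifier(sample_truth_set(spec, seed = 72L))

  # vacuous morphological gates isolate the classifier's own contribution
  open_cfg <- gate_config(gradient_rms_min = 0, area_min_um2 = 1e-6,
                          area_max_um2 = 1e6, aspect_ratio_min = 0)
  g <- gate_cells(gate_singles(gate_focus(tab, open_cfg), open_cfg), model)
  is_cell <- tab$true_label %in% c("active", "dead")
  flagged_debris <- g$assigned_label == "debris"
  expect_gt(mean(flagged_debris[tab$true_label == "debris"]), 0.9)
  expect_lt(mean(flagged_debris[is_cell]), 0.02)

  # ablation: dropping the classifier stage increases debris contamination
  with_clf <- apply_gates(tab, gate_config(), model)
  without_clf <- apply_gates(tab, gate_config(), model = NULL)
  contamination <- function(t) {
    gated <- t$assigned_label %in% c("active", "mid_active_1",
                                     "mid_active_2", "dead")
    sum(gated & t$true_label == "debris")
  }
  expect_gt(contamination(without_clf), contamination(with_clf))

  # empty table passes through
  empty <- event_table(minimal_table(0L))
  empty[feature_columns()] <- lapply(feature_columns(), \(x) numeric(0))
  expect_equal(nrow(gate_cells(empty, model)), 0L)
})

test_that("quadrant assignment follows the four-group geometry", {
  cfg <- gate_config()
  mk <- function(rsg, pi) {
    t <- minimal_table(1L)
    t$rsg_intensity <- rsg
    t$pi_intensity <- pi
    event_table(t)
  }
  expect_equal(assign_subpopulations(mk(10 * cfg$t_rsg, 0.01),
                                     cfg)$assigned_label, "active")
  expect_equal(assign_subpopulations(mk(0.01, 10 * cfg$t_pi),
                                     cfg)$assigned_label, "dead")
  expect_equal(assign_subpopulations(mk(10 * cfg$t_mid, 10 * cfg$t_pi),
                                     cfg)$assigned_label, "mid_active_2")
  expect_equal(assign_subpopulations(mk(0.9 * cfg$t_mid, 10 * cfg$t_pi),
                                     cfg)$assigned_label, "mid_active_1")
  expect_equal(assign_subpopulations(mk(0.01, 0.01), cfg)$assigned_label,
               "unclassified")
})

test_that("gated subpopulations agree with generator ground truth", {
  spec <- mixture_spec(fractions = c(active = 0.4, mid_active_1 = 0.1,
                                     mid_active_2 = 0.25, dead = 0.15,
                                     debris = 0.1))
  out <- recover_composition(spec, n_events = 10000L, seed = 81L)
  tab <- out$table
  cells <- tab$true_label %in% c("active", "mid_active_1", "mid_active_2",
                                 "dead")
  gated <- cells & tab$assigned_label %in% c("active", "mid_active_1",
                                             "mid_active_2", "dead")
  expect_gt(mean(tab$assigned_label[gated] == tab$true_label[gated]), 0.95)
})

test_that("every event receives exactly one label and percentages conserve counts", {
  spec <- mixture_spec(fractions = c(active = 0.5, mid_active_1 = 0.05,
                                     mid_active_2 = 0.2, dead = 0.1,
                                     debris = 0.05, aggregate = 0.05,
                                     out_of_focus = 0.05))
  out <- recover_composition(spec, n_events = 8000L, seed = 91L)
  tab <- out$table
  expect_true(all(tab$assigned_label %in% event_labels()))

  summ <- summarize_subpopulations(tab, denominator = "all_events")
  expect_equal(sum(summ$per_replicate$percent), 100, tolerance = 1e-9)
  # percent x denominator = counts exactly
  expect_equal(unname(summ$per_replicate$percent * summ$per_replicate$denom
                      / 100),
               as.numeric(summ$per_replicate$count), tolerance = 1e-9)
})

test_that("summaries handle uniform, replicate and degenerate cases", {
  t4 <- minimal_table(4L)
  t4$rsg_intensity <- c(1000, 80, 2000, 1)
  t4$pi_intensity <- c(1, 500, 600, 800)
  lab <- assign_subpopulations(event_table(t4), gate_config())
  expect_setequal(lab$assigned_label,
                  c("active", "mid_active_1", "mid_active_2", "dead"))
  summ <- summarize_subpopulations(lab, denominator = "gated_cells")
  expect_true(all(summ$summary$mean_percent[summ$summary$label %in%
    c("active", "mid_active_1", "mid_active_2", "dead")] == 25))
  expect_true(all(is.na(summ$summary$sd_percent)))  # single replicate

  # two identical replicates -> SD 0
  lab2 <- lab
  lab2$replicate_id <- 2L
  lab2$event_id <- lab2$event_id + 4L
  both <- summarize_subpopulations(event_table(rbind(lab, lab2)))
  expect_true(all(both$summary$sd_percent == 0))
})

test_that("tightening any threshold never increases the gated-cell count", {
  spec <- mixture_spec()
  tab <- sample_events(spec, shape_spec(), 5000L, seed = 95L)
  model <- train_classifier(sample_truth_set(spec, seed = 96L))
  n_cells <- function(cfg) {
    t <- apply_gates(tab, cfg, model, calibrate = FALSE)
    sum(t$assigned_label %in% c("active", "mid_active_1", "mid_active_2",
                                "dead"))
  }
  base <- gate_config()
  n0 <- n_cells(base)
  expect_lte(n_cells(gate_config(gradient_rms_min = 0.4)), n0)
  expect_lte(n_cells(gate_config(area_max_um2 = 1.0)), n0)
  expect_lte(n_cells(gate_config(aspect_ratio_min = 0.55)), n0)
  expect_lte(n_cells(gate_config(t_rsg = 10^2, t_pi = 10^2.2)), n0)
})

test_that("the standard 20k-event benchmark recovers fractions within 1 point", {
  spec <- mixture_spec(fractions = c(active = 0.55, mid_active_1 = 0.04,
                                     mid_active_2 = 0.2, dead = 0.12))
  out <- recover_composition(spec, n_events = 20000L, seed = 42L)
  truth <- 100 * prop.table(table(factor(out$table$true_label,
                                         levels = event_labels())))
  for (cl in c("active", "mid_active_1", "mid_active_2", "dead")) {
    expect_lt(abs(out$recovered[cl] - truth[cl]), 1.0)
  }
})

test_that("gate plots build without error", {
  spec <- mixture_spec()
  out <- recover_composition(spec, n_events = 1000L, seed = 43L)
  p <- plot_gates(out$table)
  expect_s3_class(p, "ggplot")
})
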