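#' Truth set for classifier training
#'
#' Two small, manually curated event collections: exemplar cells and
#' exemplar debris. Sizes around 31-32 events per class are typical for
#' training the cells-vs-debris discriminant.
#'
#' @param cells,debris Data frames (event tables) holding the feature
#'   columns of the two classes; at least 2 events each.
#' @return An object of class `truth_set`.
#' @export
truth_set <- function(cells, debris) {
  cells <- tibble::as_tibble(cells)
  debris <- tibble::as_tibble(debris)
  if (nrow(cells) < 2L || nrow(debris) < 2L) {
    abort("Each truth class needs at least 2 events.",
          class = "ifcgate_validation_error")
  }
  structure(list(cells = cells, debris = debris), class = "truth_set")
}

truth_feature_matrix <- function(truth, features) {
  for (nm in c("cells", "debris")) {
    missing_cols <- setdiff(features, names(truth[[nm]]))
    if (length(missing_cols)) {
      abort(paste0("Truth set `", nm, "` lacks feature column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "ifcgate_schema_error")
    }
  }
  x <- rbind(as.matrix(truth$cells[features]), as.matrix(truth$debris[features]))
  y <- rep(c("cell", "debris"), c(nrow(truth$cells), nrow(truth$debris)))
  list(x = x, y = y)
}

fisher_direction <- function(z, y, ridge = 0) {
  m1 <- colMeans(z[y == "cell", , drop = FALSE])
  m0 <- colMeans(z[y == "debris", , drop = FALSE])
  s1 <- stats::cov(z[y == "cell", , drop = FALSE])
  s0 <- stats::cov(z[y == "debris", , drop = FALSE])
  n1 <- sum(y == "cell"); n0 <- sum(y == "debris")
  sw <- ((n1 - 1) * s1 + (n0 - 1) * s0) / (n1 + n0 - 2)
  if (ridge > 0) sw <- sw + diag(ridge, ncol(sw))
  w <- tryCatch(solve(sw, m1 - m0), error = function(e) NULL)
  if (is.null(w)) {
    warn("Within-class scatter is singular; using ridge-regularized fit.")
    sw <- sw + diag(1e-4 * mean(diag(sw)) + 1e-12, ncol(sw))
    w <- solve(sw, m1 - m0)
  }
  list(w = w, m1 = m1, m0 = m0)
}

#' Train the cells-vs-debris linear classifier
#'
#' Standardizes the candidate features by training mean and SD, computes the
#' Fisher linear-discriminant direction that maximally separates the two
#' truth populations, retains the `k` features with largest absolute
#' standardized weight, and refits the discriminant on those. The score
#' offset is set so that the midpoint between the two standardized class
#' means scores exactly 0; events scoring above 0 belong to the positive
#' (cell) class.
#'
#' @param truth A [truth_set()].
#' @param candidate_features Feature names to consider (default
#'   [classifier_features()]).
#' @param k Number of features to retain (default 7).
#' @return An object of class `ifc_classifier`: ordered feature names,
#'   signed weights, per-feature standardization constants, score offset,
#'   positive-class orientation and the fixed zero decision threshold.
#' @export
train_classifier <- function(truth, candidate_features = classifier_features(),
                             k = 7L) {
  stopifnot(inherits(truth, "truth_set"))
  if (k > length(candidate_features)) {
    abort("`k` cannot exceed the number of candidate features.")
  }
  xy <- truth_feature_matrix(truth, candidate_features)
  mu <- colMeans(xy$x)
  sdv <- apply(xy$x, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warn(paste0("Dropping zero-variance feature(s): ",
                paste(candidate_features[!keep], collapse = ", ")))
  }
  feats <- candidate_features[keep]
  if (k > length(feats)) {
    abort("`k` exceeds the number of usable (non-constant) features.")
  }
  z <- scale(xy$x[, feats, drop = FALSE], mu[feats], sdv[feats])
  fd <- fisher_direction(z, xy$y)
  ord <- order(-abs(fd$w), seq_along(fd$w))
  sel <- feats[sort(ord[seq_len(k)])]  # keep original feature order
  z2 <- z[, sel, drop = FALSE]
  fd2 <- fisher_direction(z2, xy$y)
  w <- fd2$w
  offset <- -sum(w * (fd2$m1 + fd2$m0) / 2)
  if (sum(w * fd2$m1) + offset <= 0) {
    w <- -w
    offset <- -offset
  }
  structure(list(features = sel,
                 weights = setNames(as.numeric(w), sel),
                 center = mu[sel], scale = sdv[sel],
                 offset = offset,
                 positive_class = "cell",
                 threshold = 0),
            class = "ifc_classifier")
}

#' @export
print.ifc_classifier <- function(x, ...) {
  cat("<ifc_classifier> score > 0 =>", x$positive_class, "\n")
  print(round(x$weights, 3))
  invisible(x)
}

classifier_scores <- function(model, table) {
  missing_cols <- setdiff(model$features, names(table))
  if (length(missing_cols)) {
    abort(paste0("Event table lacks classifier feature(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ifcgate_schema_error")
  }
  x <- as.matrix(as.data.frame(table[model$features]))
  z <- scale(x, model$center, model$scale)
  as.numeric(z %*% model$weights + model$offset)
}

#' @export
predict.ifc_classifier <- function(object, newdata, ...) {
  classifier_scores(object, newdata)
}

#' Score events with a trained classifier
#'
#' Appends a `classifier_score` column and a `classifier_class` column:
#' `"cell"` for score > 0, `"debris"` for score < 0, `"unclassified"` for a
#' score on the decision boundary (zero within numerical tolerance) or for
#' events with undefined (sentinel) features.
#'
#' @param model An `ifc_classifier`.
#' @param table An event table containing the model's features.
#' @return The table with score and class columns appended.
#' @export
score_events <- function(model, table) {
  stopifnot(inherits(model, "ifc_classifier"))
  s <- classifier_scores(model, table)
  s[!is.na(s) & abs(s) < 1e-9] <- 0
  table$classifier_score <- s
  table$classifier_class <- dplyr::case_when(
    is.na(s) ~ "unclassified",
    s > 0 ~ "cell",
    s < 0 ~ "debris",
    .default = "unclassified"
  )
  table
}

#' Serialize a classifier to a structured text file
#'
#' Writes feature names, weights, standardization constants, offset and
#' orientation as YAML so a trained model can be reused across runs.
#'
#' @param model An `ifc_classifier`.
#' @param path Output file path.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "ifc_classifier"))
  yaml::write_yaml(list(
    features = model$features,
    weights = as.list(model$weights),
    center = as.list(model$center),
    scale = as.list(model$scale),
    offset = model$offset,
    positive_class = model$positive_class,
    threshold = model$threshold
  ), path, precision = 15L)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  y <- yaml::read_yaml(path)
  structure(list(features = unlist(y$features),
                 weights = unlist(y$weights),
                 center = unlist(y$center),
                 scale = unlist(y$scale),
                 offset = y$offset,
                 positive_class = y$positive_class,
                 threshold = y$threshold),
            class = "ifc_classifier")
}
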