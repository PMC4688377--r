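#' Discretize GI50 drug response into equiprobable bins
#'
#' Median split into equal-occupancy sensitive/insensitive bins, the binning
#' used to avoid class-imbalance bias in the random-forest classifier. GI50
#' is the concentration inhibiting growth by 50%, so by default low values
#' are labelled sensitive. Ties at the median are resolved by stable input
#' order; bin sizes differ by at most one. Missing values propagate.
#'
#' @param values numeric GI50 vector (NA allowed).
#' @param low_is_sensitive if `TRUE` (default) the lower half is labelled
#'   `sensitive`.
#' @return Factor with levels `c("sensitive", "insensitive")`, same length
#'   as `values`.
#' @export
discretize_gi50 <- function(values, low_is_sensitive = TRUE) {
  obs <- which(!is.na(values))
  if (length(obs) < 4)
    stop("need at least 4 non-missing GI50 values to discretize")
  ord <- obs[order(values[obs])]          # stable: ties keep input order
  n_low <- ceiling(length(obs) / 2)
  labels <- rep(NA_character_, length(values))
  low_lab <- if (low_is_sensitive) "sensitive" else "insensitive"
  high_lab <- if (low_is_sensitive) "insensitive" else "sensitive"
  labels[ord[seq_len(n_low)]] <- low_lab
  labels[ord[-seq_len(n_low)]] <- high_lab
  factor(labels, levels = c("sensitive", "insensitive"))
}

#' Fit a drug-sensitivity random forest with importance-based refinement
#'
#' Trains a random forest on binary genomic features, ranks features by mean
#' decrease in Gini impurity, refits on the top `refine_fraction` of
#' features, and reports the out-of-bag (OOB) error of both fits. OOB error
#' is the ensemble's internal cross-validation estimate.
#'
#' @param features sample x feature matrix (binary 0/1 or numeric).
#' @param labels binary class vector/factor, one per sample.
#' @param seed RNG seed; required for a reproducible report.
#' @param refine_fraction fraction of top-ranked features kept in the
#'   refined fit (default 0.10); at least one feature is always kept.
#' @param ntree trees per forest (default 500).
#' @param drug optional drug name carried into the report.
#' @return Object of class `drug_classifier`: feature lists, initial and
#'   refined OOB errors, Gini importances, and the refined forest (used by
#'   `predict`).
#' @export
fit_drug_classifier <- function(features, labels, seed,
                                refine_fraction = 0.10, ntree = 500,
                                drug = NA_character_) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (ncol(features) < 1L) stop("need at least one feature")
  keep <- !is.na(labels)
  features <- features[keep, , drop = FALSE]
  y <- factor(labels[keep])
  if (nlevels(y) < 2L) stop("labels contain a single class")
  if (any(table(y) < 2L)) stop("need at least 2 samples per class")
  set.seed(seed)
  rf1 <- randomForest::randomForest(x = as.data.frame(features), y = y,
                                    ntree = ntree, importance = FALSE)
  oob1 <- unname(rf1$err.rate[ntree, "OOB"])
  imp <- rf1$importance[, "MeanDecreaseGini"]
  n_keep <- max(1L, round(refine_fraction * ncol(features)))
  top <- names(sort(imp, decreasing = TRUE))[seq_len(n_keep)]
  rf2 <- randomForest::randomForest(
    x = as.data.frame(features[, top, drop = FALSE]), y = y,
    ntree = ntree, importance = FALSE)
  oob2 <- unname(rf2$err.rate[ntree, "OOB"])
  structure(list(drug = drug,
                 features_initial = colnames(features),
                 features_refined = top,
                 oob_error_initial = oob1,
                 oob_error_refined = oob2,
                 importances = imp,
                 refine_fraction = refine_fraction,
                 ntree = ntree, seed = seed, forest = rf2),
            class = "drug_classifier")
}

#' @export
print.drug_classifier <- function(x, ...) {
  cat(sprintf("drug_classifier%s: %d -> %d features (top %.0f%% by Gini importance)\n",
              if (is.na(x$drug)) "" else paste0(" [", x$drug, "]"),
              length(x$features_initial), length(x$features_refined),
              100 * x$refine_fraction))
  cat(sprintf("  OOB error: %.3f initial, %.3f refined (%d trees, seed %s)\n",
              x$oob_error_initial, x$oob_error_refined, x$ntree,
              format(x$seed)))
  invisible(x)
}

#' @export
predict.drug_classifier <- function(object, newdata, ...) {
  newdata <- as.data.frame(as.matrix(newdata))
  stats::predict(object$forest,
                 newdata[, object$features_refined, drop = FALSE], ...)
}

#' Classify sensitivity for a panel of drugs
#'
#' Discretizes each drug's GI50 column and fits the refined random-forest
#' classifier per drug, collecting OOB errors across the panel.
#'
#' @param features sample x feature binary matrix (see
#'   [surrogate_features()]); row names are sample ids.
#' @param gi50 data frame or matrix of GI50 values, samples in rows (row
#'   names or a `sample` column), one column per drug.
#' @param seed RNG seed; drug d uses `seed + position(d)` so per-drug fits
#'   are independent but reproducible.
#' @param refine_fraction,ntree passed to [fit_drug_classifier()].
#' @param low_is_sensitive passed to [discretize_gi50()].
#' @return List with `report` (data frame: drug, n, oob_error_initial,
#'   oob_error_refined) and `fits` (named list of `drug_classifier`
#'   objects); drugs whose labels cannot be fit (too few samples) are
#'   skipped with a message.
#' @export
drug_sensitivity_report <- function(features, gi50, seed,
                                    refine_fraction = 0.10, ntree = 500,
                                    low_is_sensitive = TRUE) {
  gi50 <- as.data.frame(gi50)
  if ("sample" %in% names(gi50)) {
    rownames(gi50) <- gi50$sample
    gi50$sample <- NULL
  }
  common <- intersect(rownames(features), rownames(gi50))
  if (length(common) < 4L)
    stop("fewer than 4 samples shared between features and GI50 table")
  fits <- list()
  rows <- list()
  for (i in seq_along(names(gi50))) {
    d <- names(gi50)[i]
    v <- gi50[common, d]
    fit <- tryCatch({
      lab <- discretize_gi50(v, low_is_sensitive = low_is_sensitive)
      fit_drug_classifier(features[common, , drop = FALSE], lab,
                          seed = seed + i,
                          refine_fraction = refine_fraction,
                          ntree = ntree, drug = d)
    }, error = function(e) {
      message(sprintf("drug_sensitivity_report: skipping %s (%s)",
                      d, conditionMessage(e)))
      NULL
    })
    if (is.null(fit)) next
    fits[[d]] <- fit
    rows[[d]] <- data.frame(drug = d, n = sum(!is.na(v)),
                            oob_error_initial = fit$oob_error_initial,
                            oob_error_refined = fit$oob_error_refined,
                            stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(drug = character(0), n = integer(0),
                  oob_error_initial = numeric(0),
                  oob_error_refined = numeric(0))
  list(report = report, fits = fits)
}

#' Convex combination of two classifiers' class probabilities
#'
#' Sweeps a weight grid over `w * p1 + (1 - w) * p2` and reports the OOB
#' misclassification error of each mixture, for comparing a genomic-feature
#' model against an expression-based model.
#'
#' @param prob1,prob2 numeric vectors of OOB class-1 probabilities from two
#'   classifiers, same samples in the same order.
#' @param labels true class factor (first level is class 1).
#' @param weights weight grid for the first model (default `seq(0, 1, 0.1)`).
#' @return Data frame with columns `weight` and `error`.
#' @export
blend_classifiers <- function(prob1, prob2, labels,
                              weights = seq(0, 1, by = 0.1)) {
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labels must have exactly two classes")
  truth <- y == levels(y)[1L]
  data.frame(weight = weights,
             error = vapply(weights, function(w) {
               p <- w * prob1 + (1 - w) * prob2
               mean((p >= 0.5) != truth)
             }, 1.0))
}
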