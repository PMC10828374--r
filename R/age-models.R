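# Metabolic-age and laying-efficiency models: reference-set z-scoring, a
# PCA age axis oriented by control age medians, and control-trained
# random-forest regressors with leave-one-out evaluation and an optional
# LASSO feature screen.

#' Z-score a metabolite table against a reference sample set
#'
#' Each feature is centered and scaled by its mean and SD over the
#' reference samples only, and the same constants are applied to every
#' other sample — held-out or transferred samples are therefore always
#' normalized with training-time statistics.
#'
#' @param table A [metabolite_table()].
#' @param reference Sample ids defining the normalization constants
#'   (default: all samples).
#' @param features Optional feature ids to restrict to.
#' @return A `normalized_table`: list with `z` (feature x sample matrix),
#'   `center`, `scale`, `reference`, `samples` (metadata tibble).
#' @export
zscore_normalize <- function(table, reference = NULL, features = NULL) {
  stopifnot(inherits(table, "metabolite_table"))
  if (!is.null(features)) table <- filter_table(table, features = features)
  x <- table$intensities
  reference <- reference %||% colnames(x)
  if (!all(reference %in% colnames(x))) {
    abort("Some reference sample ids are not in the table.")
  }
  ref <- x[, reference, drop = FALSE]
  center <- rowMeans(ref)
  scale <- apply(ref, 1, sd)
  if (any(scale == 0)) {
    abort(paste0("Zero variance over the reference set for feature(s): ",
                 paste(head(rownames(x)[scale == 0], 5), collapse = ", ")))
  }
  structure(
    list(z = (x - center) / scale, center = center, scale = scale,
         reference = reference, samples = table$samples),
    class = "normalized_table"
  )
}

#' @export
print.normalized_table <- function(x, ...) {
  cat("<normalized_table> ", nrow(x$z), " features x ", ncol(x$z),
      " samples (", length(x$reference), " reference samples)\n", sep = "")
  invisible(x)
}

#' PCA age axis from aging biomarkers
#'
#' Fits principal components on the control samples of the z-scored
#' biomarker submatrix and projects every sample (including molted ones)
#' onto the control-derived axes. PC1 is oriented deterministically so
#' that the control median coordinate at the oldest reference age exceeds
#' the one at the youngest — older is always to the right.
#'
#' @param normalized A `normalized_table` restricted to an aging biomarker
#'   set (see [zscore_normalize()]).
#' @param ages Reference ages used for the orientation convention
#'   (default `c(21, 27, 33)`).
#' @return An `age_axis`: `scores` tibble (`sample_id`, metadata, `PC1`,
#'   `PC2`), `var_explained` (fractions for all control PCs), `rotation`.
#' @export
pca_age_axis <- function(normalized, ages = c(21, 27, 33)) {
  stopifnot(inherits(normalized, "normalized_table"))
  meta <- normalized$samples
  ctrl <- meta$sample_id[meta$group == "control" & meta$age_months %in% ages]
  if (length(ctrl) < 3) abort("Need at least 3 control samples.")
  xc <- t(normalized$z[, ctrl, drop = FALSE])
  if (all(abs(xc - mean(xc)) < 1e-12)) abort("Degenerate (rank-0) matrix.")
  fit <- prcomp(xc, center = TRUE, scale. = FALSE)
  all_scores <- scale(t(normalized$z), center = fit$center, scale = FALSE) %*%
    fit$rotation
  scores <- bind_cols(meta,
                      tibble(PC1 = all_scores[, 1], PC2 = all_scores[, 2]))
  med <- function(a) {
    median(scores$PC1[scores$group == "control" & scores$age_months == a])
  }
  flipped <- med(max(ages)) < med(min(ages))
  if (flipped) {
    scores$PC1 <- -scores$PC1
    fit$rotation[, 1] <- -fit$rotation[, 1]
  }
  structure(
    list(scores = scores,
         var_explained = fit$sdev^2 / sum(fit$sdev^2),
         rotation = fit$rotation[, 1:2, drop = FALSE],
         flipped = flipped, ages = ages),
    class = "age_axis"
  )
}

#' @export
print.age_axis <- function(x, ...) {
  cat("<age_axis> PC1 ", round(100 * x$var_explained[1]), "%, PC2 ",
      round(100 * x$var_explained[2]), "% of variance; ",
      nrow(x$scores), " samples projected\n", sep = "")
  invisible(x)
}

#' @export
tidy.age_axis <- function(x, ...) x$scores

#' @export
glance.age_axis <- function(x, ...) {
  tibble(pc1_var = x$var_explained[1], pc2_var = x$var_explained[2],
         n_samples = nrow(x$scores), flipped = x$flipped)
}

#' Metabolic aging distance along the PCA axis
#'
#' The group's median PC1 coordinate at `to_age` minus the median at
#' `from_age`: how far along the metabolic-age axis the group moved.
#'
#' @param axis An `age_axis`.
#' @param group `"control"` or `"molted"`.
#' @param from_age,to_age Ages in months.
#' @return Scalar distance (axis units).
#' @export
median_axis_aging <- function(axis, group, from_age, to_age) {
  stopifnot(inherits(axis, "age_axis"))
  s <- axis$scores
  med_at <- function(a) {
    v <- s$PC1[s$group == group & s$age_months == a]
    if (length(v) == 0) {
      abort(paste0("No samples for group ", group, " at age ", a, "."))
    }
    median(v)
  }
  med_at(to_age) - med_at(from_age)
}

#' Permutation contrast of control vs molted axis aging
#'
#' Statistic: control aging distance minus molted aging distance along
#' PC1 between `from_age` and `to_age` (a difference of median
#' differences). The null permutes group labels among the samples within
#' each age, recomputes the statistic, and counts permutations at least as
#' extreme as the observed absolute value.
#'
#' @inheritParams median_axis_aging
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed.
#' @return A `perm_test`.
#' @export
axis_aging_contrast <- function(axis, from_age, to_age, n_perm = 1000L,
                                seed = NULL) {
  stopifnot(inherits(axis, "age_axis"))
  s <- filter(axis$scores, .data$age_months %in% c(from_age, to_age))
  stat <- function(groups) {
    m <- function(g, a) {
      median(s$PC1[groups == g & s$age_months == a])
    }
    (m("control", to_age) - m("control", from_age)) -
      (m("molted", to_age) - m("molted", from_age))
  }
  obs <- abs(stat(s$group))
  n_extreme <- with_rng_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      g <- s$group
      for (a in c(from_age, to_age)) {
        idx <- which(s$age_months == a)
        g[idx] <- g[sample(idx)]
      }
      abs(stat(g)) >= obs - 1e-12
    }, logical(1)))
  })
  new_perm_test(obs, n_extreme, n_perm, method = "axis-aging-contrast")
}

# Shared forest trainer over a z-scored matrix.
fit_forest <- function(z, y, seed, ntree) {
  with_rng_seed(seed, {
    # regression on a few distinct ages is intentional; silence the
    # forest's classification hint
    suppressWarnings(randomForest::randomForest(
      x = t(z), y = y, ntree = ntree,
      mtry = max(1L, floor(nrow(z) / 3))
    ))
  })
}

#' Train a metabolic-age regressor on control hens
#'
#' Random-forest regression of chronological age on z-scored aging
#' biomarkers, trained exclusively on control samples at the reference
#' ages. Hyperparameters are frozen (500 trees, one third of the features
#' tried per split, unlimited depth); the seed is mandatory for
#' reproducibility.
#'
#' @param table A [metabolite_table()].
#' @param markers Feature ids (e.g. an aging biomarker set's
#'   `feature_id`s).
#' @param seed RNG seed for the forest.
#' @param ages Training ages (default `c(21, 27, 33)`).
#' @param ntree Number of trees (default 500).
#' @return An `age_model` wrapping the forest plus the training-time
#'   normalization constants.
#' @export
train_age_regressor <- function(table, markers, seed, ages = c(21, 27, 33),
                                ntree = 500L) {
  stopifnot(inherits(table, "metabolite_table"))
  sub <- filter_table(table, features = markers, group = "control",
                      ages = ages)
  if (length(unique(sub$samples$age_months)) < 2) {
    abort("Training data must contain at least two distinct ages.")
  }
  norm <- zscore_normalize(sub)
  forest <- fit_forest(norm$z, as.numeric(sub$samples$age_months), seed, ntree)
  structure(
    list(forest = forest, center = norm$center, scale = norm$scale,
         features = rownames(norm$z), response = "age_months",
         training_ages = sort(unique(sub$samples$age_months)),
         seed = seed, ntree = ntree),
    class = "age_model"
  )
}

#' @export
print.age_model <- function(x, ...) {
  cat("<age_model> random forest (", x$ntree, " trees) on ",
      length(x$features), " markers; trained at ages ",
      paste(x$training_ages, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' @export
glance.age_model <- function(x, ...) {
  tibble(n_features = length(x$features), ntree = x$ntree,
         oob_mse = tail(x$forest$mse, 1),
         training_ages = paste(x$training_ages, collapse = "/"))
}

#' Predict metabolic age (or efficiency) for new samples
#'
#' New samples are normalized with the model's training constants before
#' prediction, so no information flows from the prediction set into the
#' model.
#'
#' @param object An `age_model` (or `efficiency_model`).
#' @param table A [metabolite_table()] sharing the model's feature
#'   universe.
#' @param ... Unused.
#' @return Tibble: sample metadata plus `predicted`.
#' @export
predict.age_model <- function(object, table, ...) {
  stopifnot(inherits(table, "metabolite_table"))
  if (!all(object$features %in% table$features$feature_id)) {
    abort("Table is missing model features.")
  }
  if (ncol(table$intensities) == 0) return(bind_cols(table$samples, tibble(predicted = numeric())))
  x <- table$intensities[object$features, , drop = FALSE]
  z <- (x - object$center) / object$scale
  bind_cols(table$samples,
            tibble(predicted = as.numeric(predict(object$forest, t(z)))))
}

#' Median predicted age per group and age
#'
#' @param predictions Output of [predict.age_model()].
#' @return Tibble `group`, `age_months`, `median_predicted`, `n`.
#' @export
median_predicted_ages <- function(predictions) {
  predictions |>
    group_by(.data$group, .data$age_months) |>
    summarise(median_predicted = median(.data$predicted), n = n(),
              .groups = "drop")
}

#' Predicted metabolic-age span of a group
#'
#' @param predictions Output of [predict.age_model()].
#' @param group Group name.
#' @param from_age,to_age Chronological endpoints.
#' @return Median predicted age at `to_age` minus at `from_age` (months).
#' @export
predicted_age_span <- function(predictions, group, from_age, to_age) {
  m <- median_predicted_ages(predictions)
  pick <- function(a) {
    v <- m$median_predicted[m$group == group & m$age_months == a]
    if (length(v) != 1) abort(paste0("No cell for ", group, " at ", a, "."))
    v
  }
  pick(to_age) - pick(from_age)
}

lasso_screen <- function(z, y, seed) {
  with_rng_seed(seed, {
    cv <- glmnet::cv.glmnet(t(z), y, alpha = 1, nfolds = 5)
    co <- coef(cv, s = "lambda.min")
    keep <- rownames(co)[-1][as.numeric(co)[-1] != 0]
    if (length(keep) < 2) {
      # degenerate screen: fall back to the strongest marginal features
      r <- abs(apply(z, 1, function(f) cor(f, y)))
      keep <- names(sort(r, decreasing = TRUE))[seq_len(min(10, nrow(z)))]
    }
    keep
  })
}

#' Train a laying-efficiency regressor on control hens
#'
#' @param table A [metabolite_table()].
#' @param efficiency Monthly efficiency tibble (`hen_id`, `month`,
#'   `efficiency`).
#' @param markers Feature ids to model on.
#' @param seed RNG seed.
#' @param mode `"rfr"` (random forest on all markers) or
#'   `"lasso_rfr"` (LASSO feature screen at the cross-validated penalty
#'   feeding the forest).
#' @param ntree Trees (default 500).
#' @param group Training group (default `"control"`).
#' @return An `efficiency_model` (same interface as `age_model`).
#' @export
train_efficiency_regressor <- function(table, efficiency, markers, seed,
                                       mode = c("rfr", "lasso_rfr"),
                                       ntree = 500L, group = "control") {
  mode <- match.arg(mode)
  sub <- filter_table(table, features = markers, group = group)
  y <- sample_efficiencies(sub, efficiency)
  norm <- zscore_normalize(sub)
  z <- norm$z
  feats <- rownames(z)
  if (mode == "lasso_rfr") {
    feats <- lasso_screen(z, y, child_seed(seed, "lasso"))
    z <- z[feats, , drop = FALSE]
  }
  forest <- fit_forest(z, y, child_seed(seed, "forest"), ntree)
  structure(
    list(forest = forest, center = norm$center[feats],
         scale = norm$scale[feats], features = feats,
         response = "efficiency", mode = mode, seed = seed, ntree = ntree),
    class = c("efficiency_model", "age_model")
  )
}

sample_efficiencies <- function(table, efficiency) {
  eff <- table$samples |>
    left_join(efficiency, by = c("hen_id", "sampling_month" = "month"))
  if (anyNA(eff$efficiency)) {
    abort(paste0("Missing efficiency for sample(s): ",
                 paste(head(eff$sample_id[is.na(eff$efficiency)], 5),
                       collapse = ", ")))
  }
  eff$efficiency
}

#' Leave-one-out efficiency prediction on control hens
#'
#' For every control sample in turn: normalize all features by the
#' remaining samples' constants, (optionally) run the LASSO screen, train
#' the forest, and predict the held-out sample. The held-out sample never
#' touches the normalization constants, the screen, or the forest.
#'
#' @inheritParams train_efficiency_regressor
#' @return A `prediction_eval` tibble (`sample_id`, `hen_id`,
#'   `age_months`, `true_efficiency`, `predicted_efficiency`) with the
#'   Pearson correlation, its p-value, and the capture rate of
#'   true-efficiency > 0.5 samples among predicted > 0.5 as attributes
#'   (see [glance.prediction_eval()]).
#' @export
loo_predict_efficiency <- function(table, efficiency, markers, seed,
                                   mode = c("rfr", "lasso_rfr"),
                                   ntree = 500L, group = "control") {
  mode <- match.arg(mode)
  sub <- filter_table(table, features = markers, group = group)
  y <- sample_efficiencies(sub, efficiency)
  ids <- sub$samples$sample_id
  preds <- vapply(seq_along(ids), function(i) {
    train <- filter_table(sub, samples = ids[-i])
    norm <- zscore_normalize(train)
    z <- norm$z
    feats <- rownames(z)
    fold_seed <- child_seed(seed, paste0("fold", i))
    if (mode == "lasso_rfr") {
      feats <- lasso_screen(z, y[-i], child_seed(fold_seed, "lasso"))
      z <- z[feats, , drop = FALSE]
    }
    forest <- fit_forest(z, y[-i], child_seed(fold_seed, "forest"), ntree)
    held <- (sub$intensities[feats, i] - norm$center[feats]) / norm$scale[feats]
    as.numeric(predict(forest, t(as.matrix(held))))
  }, numeric(1))
  new_prediction_eval(
    bind_cols(sub$samples,
              tibble(true_efficiency = y, predicted_efficiency = preds)),
    mode = mode
  )
}

new_prediction_eval <- function(records, mode) {
  ct <- cor.test(records$true_efficiency, records$predicted_efficiency)
  high <- records$true_efficiency > 0.5
  capture <- if (any(high)) {
    mean(records$predicted_efficiency[high] > 0.5)
  } else {
    NA_real_
  }
  structure(records,
            r = unname(ct$estimate), p_value = ct$p.value,
            capture_rate = capture, mode = mode,
            class = c("prediction_eval", class(records)))
}

#' @export
print.prediction_eval <- function(x, ...) {
  cat("<prediction_eval> R = ", signif(attr(x, "r"), 3),
      " (Pearson), p = ", signif(attr(x, "p_value"), 3),
      ", capture rate = ", signif(attr(x, "capture_rate"), 3), "\n", sep = "")
  NextMethod()
}

#' Summary statistics of an efficiency-prediction evaluation
#'
#' @param x A `prediction_eval`.
#' @param ... Unused.
#' @return One-row tibble: `r`, `p_value`, `capture_rate`, `n`, `mode`.
#' @export
glance.prediction_eval <- function(x, ...) {
  tibble(r = attr(x, "r"), p_value = attr(x, "p_value"),
         capture_rate = attr(x, "capture_rate"), n = nrow(x),
         mode = attr(x, "mode"))
}

#' Transfer a control-trained efficiency model to molted hens
#'
#' @param model An `efficiency_model` trained on controls.
#' @param table A [metabolite_table()] containing the target samples.
#' @param efficiency Monthly efficiency tibble for the true values.
#' @param group Target group (default `"molted"`).
#' @return A `prediction_eval` for the target samples; attribute
#'   `range_capture` gives the fraction of predictions inside the true
#'   efficiency range widened by 0.05 on each side (the claim such a
#'   transfer supports is range-level, not pointwise).
#' @export
predict_efficiency_transfer <- function(model, table, efficiency,
                                        group = "molted") {
  stopifnot(inherits(model, "efficiency_model"))
  keep <- table$samples$group == group
  if (!any(keep)) {
    out <- bind_cols(table$samples[0, ],
                     tibble(true_efficiency = numeric(),
                            predicted_efficiency = numeric()))
    return(structure(out, r = NA_real_, p_value = NA_real_,
                     capture_rate = NA_real_, range_capture = NA_real_,
                     mode = model$mode,
                     class = c("prediction_eval", class(out))))
  }
  sub <- filter_table(table, group = group)
  y <- sample_efficiencies(sub, efficiency)
  preds <- predict(model, sub)
  out <- new_prediction_eval(
    bind_cols(sub$samples,
              tibble(true_efficiency = y, predicted_efficiency = preds$predicted)),
    mode = model$mode
  )
  attr(out, "range_capture") <-
    mean(out$predicted_efficiency >= min(y) - 0.05 &
           out$predicted_efficiency <= max(y) + 0.05)
  out
}
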