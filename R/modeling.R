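# Group-wise random-forest models, sequential backward feature-group
# selection, weighted ensembles of energy- and nonenergy-based predictions,
# leave-one-complex-out cross-validation (LOCOV), and evaluation metrics.

RF_DEFAULT_NTREE <- 500
RF_DEFAULT_SEED <- 2021

# dataset ------------------------------------------------------------------

#' Construct a mutation dataset for modeling
#'
#' @param features Tibble with one row per mutation: `mutation_id`,
#'   `complex_id`, `ddg` (experimental ddG, kcal/mol) and one column per
#'   feature.
#' @param manifest Tibble mapping feature columns to groups: columns `group`,
#'   `feature`.
#' @param hotspot_threshold Class threshold in kcal/mol; the class flag is
#'   `ddg >= threshold` (default 1).
#' @return A `mutation_dataset`.
#' @export
mutation_dataset <- function(features, manifest, hotspot_threshold = 1) {
  features <- as_tibble(features)
  manifest <- as_tibble(manifest)
  missing <- setdiff(manifest$feature, names(features))
  if (length(missing) > 0) {
    abort(paste0("manifest features absent from table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  structure(
    list(
      features = features %>%
        mutate(hotspot = label_hotspot(.data$ddg, hotspot_threshold)),
      manifest = manifest,
      groups = unique(manifest$group),
      hotspot_threshold = hotspot_threshold
    ),
    class = "mutation_dataset"
  )
}

#' @export
print.mutation_dataset <- function(x, ...) {
  cat("<mutation_dataset> ", nrow(x$features), " mutations, ",
      length(unique(x$features$complex_id)), " complexes, ",
      length(x$groups), " feature groups\n", sep = "")
  invisible(x)
}

group_columns <- function(ds, groups) {
  unknown <- setdiff(groups, ds$groups)
  if (length(unknown) > 0) {
    abort(paste0("unregistered feature group(s): ",
                 paste(unknown, collapse = ", ")))
  }
  ds$manifest$feature[ds$manifest$group %in% groups]
}

feature_matrix <- function(ds, groups) {
  cols <- group_columns(ds, groups)
  as.matrix(ds$features[, cols, drop = FALSE])
}

#' Leave-one-complex-out folds
#'
#' One fold per complex: the fold's test set is all mutations of that complex
#' and its training set is everything else. Folds are ordered by complex id.
#'
#' @param ds A `mutation_dataset`.
#' @return Tibble with `complex_id`, `test` and `train` list-columns of row
#'   indices into `ds$features`.
#' @export
locov_splits <- function(ds) {
  ids <- sort(unique(ds$features$complex_id))
  if (length(ids) < 2) abort("LOCOV needs at least 2 complexes")
  tibble(
    complex_id = ids,
    test = lapply(ids, function(cid) which(ds$features$complex_id == cid)),
    train = lapply(ids, function(cid) which(ds$features$complex_id != cid))
  )
}

# models -------------------------------------------------------------------

#' Fit a random-forest model on a set of feature groups
#'
#' @param ds A `mutation_dataset`.
#' @param groups Character vector of feature-group names.
#' @param task `"regression"` (target `ddg`) or `"classification"` (target
#'   `hotspot`).
#' @param seed RNG seed; the same seed and data give identical forests.
#' @param ntree Number of trees (default 500).
#' @param rows Optional row subset to train on.
#' @return A `group_model`.
#' @export
fit_group_model <- function(ds, groups, task = "regression",
                            seed = RF_DEFAULT_SEED, ntree = RF_DEFAULT_NTREE,
                            rows = NULL) {
  if (length(groups) == 0) abort("empty feature-group set")
  stopifnot(task %in% c("regression", "classification"))
  x <- feature_matrix(ds, groups)
  y <- if (task == "regression") ds$features$ddg else
    factor(ds$features$hotspot, levels = c(FALSE, TRUE))
  if (!is.null(rows)) {
    x <- x[rows, , drop = FALSE]
    y <- y[rows]
  }
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = ntree)
  fit$call <- NULL  # environments in calls break byte-identical serialization
  structure(
    list(fit = fit, groups = groups, task = task, seed = seed,
         ntree = ntree, features = colnames(x)),
    class = "group_model"
  )
}

#' @export
predict.group_model <- function(object, newdata, ...) {
  if (inherits(newdata, "mutation_dataset")) {
    newdata <- newdata$features
  }
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("prediction input lacks feature(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  if (object$task == "regression") {
    unname(predict(object$fit, x))
  } else {
    unname(predict(object$fit, x, type = "prob")[, "TRUE"])
  }
}

#' Pooled out-of-fold LOCOV predictions for a group set
#'
#' @inheritParams fit_group_model
#' @return Tibble with `mutation_id`, `complex_id`, `obs` and `pred` (score =
#'   positive-class probability for classification), in dataset row order.
#' @export
locov_predict <- function(ds, groups, task = "regression",
                          seed = RF_DEFAULT_SEED, ntree = RF_DEFAULT_NTREE) {
  folds <- locov_splits(ds)
  pred <- rep(NA_real_, nrow(ds$features))
  for (i in seq_len(nrow(folds))) {
    m <- fit_group_model(ds, groups, task, seed, ntree,
                         rows = folds$train[[i]])
    pred[folds$test[[i]]] <- predict(
      m, ds$features[folds$test[[i]], , drop = FALSE])
  }
  tibble(
    mutation_id = ds$features$mutation_id,
    complex_id = ds$features$complex_id,
    obs = if (task == "regression") ds$features$ddg else
      as.numeric(ds$features$hotspot),
    pred = pred
  )
}

# metrics ------------------------------------------------------------------

#' Hotspot labeling: does a mutation significantly decrease binding affinity?
#'
#' @param ddg ddG values, kcal/mol.
#' @param threshold Threshold, kcal/mol (default 1; boundary inclusive).
#' @return Logical vector, `TRUE` when `ddg >= threshold`.
#' @export
label_hotspot <- function(ddg, threshold = 1) {
  ddg >= threshold
}

metric_pcc <- function(pred, obs) {
  if (sd(obs) == 0 || sd(pred) == 0) return(NA_real_)
  cor(pred, obs)
}

metric_rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))

metric_mcc <- function(pred_class, obs_class) {
  tp <- sum(pred_class & obs_class)
  tn <- sum(!pred_class & !obs_class)
  fp <- sum(pred_class & !obs_class)
  fn <- sum(!pred_class & obs_class)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# rank-based (Mann-Whitney) AUC; ties get half credit
metric_auc <- function(score, obs_class) {
  pos <- score[obs_class]
  neg <- score[!obs_class]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("AUC undefined: only one class present")
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Regression or classification evaluation metrics
#'
#' Regression: Pearson correlation (PCC) and RMSE. Classification: Matthews
#' correlation coefficient at probability threshold 0.5 and rank-based
#' (Mann-Whitney) AUC with half credit for ties.
#'
#' @param pred Predictions (scores/probabilities for classification).
#' @param obs Observed ddG (regression) or class flags (classification).
#' @param task `"regression"` or `"classification"`.
#' @param prob_threshold Score threshold for the MCC 2x2 table.
#' @return Named list of metrics.
#' @export
metrics <- function(pred, obs, task = "regression", prob_threshold = 0.5) {
  if (length(pred) != length(obs)) abort("pred/obs length mismatch")
  if (length(pred) < 2) abort("need at least 2 observations")
  if (task == "regression") {
    list(pcc = metric_pcc(pred, obs), rmse = metric_rmse(pred, obs))
  } else {
    obs <- as.logical(obs)
    list(mcc = metric_mcc(pred >= prob_threshold, obs),
         auc = metric_auc(pred, obs))
  }
}

# feature-group selection ---------------------------------------------------

#' Sequential backward selection over feature groups
#'
#' Starts from all candidate groups and iteratively deletes the group whose
#' removal improves the LOCOV criterion the most (PCC for regression, AUC for
#' classification); halts when no removal increases the criterion. Removal
#' ties break to the lexicographically smallest group name.
#'
#' @inheritParams fit_group_model
#' @param candidates Candidate group names.
#' @return List with `selected` (surviving groups) and `trace` tibble
#'   (`round`, `removed`, `criterion`).
#' @export
sbs_select <- function(ds, candidates, task = "regression",
                       seed = RF_DEFAULT_SEED, ntree = RF_DEFAULT_NTREE) {
  if (length(candidates) == 0) abort("no candidate groups")
  crit <- function(groups) {
    p <- locov_predict(ds, groups, task, seed, ntree)
    if (task == "regression") metric_pcc(p$pred, p$obs)
    else metric_auc(p$pred, as.logical(p$obs))
  }
  current <- sort(candidates)
  best <- crit(current)
  trace <- tibble(round = 0L, removed = NA_character_, criterion = best)
  round_i <- 0L
  while (length(current) > 1) {
    round_i <- round_i + 1L
    scores <- vapply(current, function(g) crit(setdiff(current, g)),
                     numeric(1))
    top <- max(scores)
    if (!is.finite(top) || top <= best) break
    removed <- sort(names(scores)[scores == top])[1]
    current <- setdiff(current, removed)
    best <- top
    trace <- bind_rows(trace, tibble(round = round_i, removed = removed,
                                     criterion = best))
  }
  list(selected = current, trace = trace)
}

#' Grid search for a convex combination weight
#'
#' Evaluates `w * a + (1 - w) * b` over the 11 weights 0, 0.1, ..., 1 and
#' returns the weight maximizing the criterion (PCC against `labels` for
#' regression, AUC for classification). Ties break to the smaller weight.
#'
#' @param pred_a,pred_b Aligned prediction vectors.
#' @param labels Observed values (or class flags).
#' @param metric `"pcc"` or `"auc"`.
#' @return List with `weight` and the 11-row `grid` tibble.
#' @export
grid_search_weight <- function(pred_a, pred_b, labels, metric = "pcc") {
  if (length(pred_a) != length(pred_b) || length(pred_a) != length(labels)) {
    abort("misaligned prediction/label lengths")
  }
  if (length(labels) < 3) abort("need at least 3 labels")
  if (metric == "pcc" && sd(labels) == 0) abort("zero-variance labels")
  weights <- seq(0, 1, by = 0.1)
  score <- vapply(weights, function(w) {
    combo <- w * pred_a + (1 - w) * pred_b
    if (metric == "pcc") metric_pcc(combo, labels)
    else metric_auc(combo, as.logical(labels))
  }, numeric(1))
  best <- max(score, na.rm = TRUE)
  w <- weights[which(score >= best - 1e-12)[1]]
  list(weight = w, grid = tibble(weight = weights, score = score))
}

# ensemble -----------------------------------------------------------------

#' Ensemble specification for a mutation class
#'
#' Defaults follow the final model configuration for each class: for
#' protein-DNA mutations (MPD) the energy score is
#' `alpha * ETOR + (1 - alpha) * EPI` with `alpha = 0.4` (GB-HCT tables) and
#' the integrative score weights energy by `beta = 0.6`; for protein-RNA
#' mutations (MPR) the energy score is the EWC prediction alone (alpha
#' unused) and `beta = 0.5` (GB-OBC1 tables).
#'
#' @param mutation_class `"MPD"` or `"MPR"`.
#' @param alpha Energy-combination weight (MPD only).
#' @param beta Energy-vs-nonenergy weight.
#' @param gb_model_tag GB model tag of the energy tables.
#' @param energy_groups,nonenergy_groups Feature-group overrides.
#' @return An `ensemble_spec`.
#' @export
ensemble_spec <- function(mutation_class = c("MPD", "MPR"),
                          alpha = NULL, beta = NULL, gb_model_tag = NULL,
                          energy_groups = NULL, nonenergy_groups = NULL) {
  mutation_class <- match.arg(mutation_class)
  defaults <- if (mutation_class == "MPD") {
    list(alpha = 0.4, beta = 0.6, gb_model_tag = "HCT",
         energy_groups = c("ETOR", "EPI"),
         nonenergy_groups = c("dASA", "NHB", "CFAA", "CFNA", "IR-CFAA"))
  } else {
    list(alpha = NA_real_, beta = 0.5, gb_model_tag = "OBC1",
         energy_groups = "EWC",
         nonenergy_groups = c("bRSA", "uRSA", "dASA", "IR-dASA", "NHB",
                              "ENDES", "JSD"))
  }
  spec <- list(
    mutation_class = mutation_class,
    alpha = alpha %||% defaults$alpha,
    beta = beta %||% defaults$beta,
    gb_model_tag = gb_model_tag %||% defaults$gb_model_tag,
    energy_groups = energy_groups %||% defaults$energy_groups,
    nonenergy_groups = nonenergy_groups %||% defaults$nonenergy_groups
  )
  if (mutation_class == "MPD" &&
      (is.na(spec$alpha) || spec$alpha < 0 || spec$alpha > 1)) {
    abort("alpha must be in [0, 1] for MPD")
  }
  if (spec$beta < 0 || spec$beta > 1) abort("beta must be in [0, 1]")
  structure(spec, class = "ensemble_spec")
}

#' Energy-model score combination
#'
#' MPD: `alpha * ETOR + (1 - alpha) * EPI` on aligned model predictions
#' (weighted-output form). MPR: the EWC prediction passed through.
#'
#' @param spec An `ensemble_spec`.
#' @param etor_pred,epi_pred MPD component predictions.
#' @param ewc_pred MPR component predictions.
#' @param alpha Optional override of `spec$alpha`.
#' @return Numeric score vector.
#' @export
energy_score <- function(spec, etor_pred = NULL, epi_pred = NULL,
                         ewc_pred = NULL, alpha = NULL) {
  if (spec$mutation_class == "MPD") {
    if (is.null(etor_pred) || is.null(epi_pred)) {
      abort("MPD energy score needs both ETOR and EPI predictions")
    }
    if (length(etor_pred) != length(epi_pred)) {
      abort("misaligned prediction lengths")
    }
    a <- alpha %||% spec$alpha
    a * etor_pred + (1 - a) * epi_pred
  } else {
    if (is.null(ewc_pred)) abort("MPR energy score needs the EWC prediction")
    ewc_pred
  }
}

#' Integrative score: weighted energy and nonenergy predictions
#'
#' `beta * energy + (1 - beta) * nonenergy`.
#'
#' @param spec An `ensemble_spec`.
#' @param energy_pred,nonenergy_pred Aligned prediction vectors.
#' @param beta Optional override of `spec$beta`.
#' @return Numeric score vector.
#' @export
ensemble_score <- function(spec, energy_pred, nonenergy_pred, beta = NULL) {
  if (length(energy_pred) != length(nonenergy_pred)) {
    abort("misaligned prediction lengths")
  }
  b <- beta %||% spec$beta
  b * energy_pred + (1 - b) * nonenergy_pred
}

ensemble_component_groups <- function(spec) {
  if (spec$mutation_class == "MPD") {
    if (length(spec$energy_groups) != 2) {
      abort("MPD ensembles combine exactly two energy groups")
    }
    list(etor = spec$energy_groups[1], epi = spec$energy_groups[2],
         nonenergy = spec$nonenergy_groups)
  } else {
    list(ewc = spec$energy_groups, nonenergy = spec$nonenergy_groups)
  }
}

#' Train the weighted ensemble on a full dataset
#'
#' Fits the energy component models (ETOR and EPI for MPD; EWC for MPR) and
#' the joint nonenergy model on all mutations. Optionally tunes alpha then
#' beta by [grid_search_weight()] on LOCOV predictions (sequential tuning).
#'
#' @param ds A `mutation_dataset`.
#' @param spec An `ensemble_spec`.
#' @param task `"regression"` or `"classification"`.
#' @param seed,ntree Forest parameters.
#' @param tune_weights Tune alpha/beta on LOCOV predictions instead of using
#'   the spec's fixed values.
#' @return An `ensemble_fit` with component `group_model`s and resolved
#'   weights.
#' @export
train_ensemble <- function(ds, spec, task = "regression",
                           seed = RF_DEFAULT_SEED, ntree = RF_DEFAULT_NTREE,
                           tune_weights = FALSE) {
  comps <- ensemble_component_groups(spec)
  models <- lapply(comps, function(g) fit_group_model(ds, g, task, seed, ntree))
  alpha <- spec$alpha
  beta <- spec$beta
  if (tune_weights) {
    cv <- lapply(comps, function(g) locov_predict(ds, g, task, seed, ntree))
    labels <- if (task == "regression") ds$features$ddg else
      ds$features$hotspot
    met <- if (task == "regression") "pcc" else "auc"
    if (spec$mutation_class == "MPD") {
      alpha <- grid_search_weight(cv$etor$pred, cv$epi$pred, labels,
                                  met)$weight
      en <- alpha * cv$etor$pred + (1 - alpha) * cv$epi$pred
    } else {
      en <- cv$ewc$pred
    }
    beta <- grid_search_weight(en, cv$nonenergy$pred, labels, met)$weight
  }
  structure(
    list(spec = spec, task = task, models = models, alpha = alpha,
         beta = beta, seed = seed, ntree = ntree,
         feature_manifest = ds$manifest[
           ds$manifest$group %in% unlist(comps), ]),
    class = "ensemble_fit"
  )
}

#' @export
predict.ensemble_fit <- function(object, newdata, alpha = NULL, beta = NULL,
                                 ...) {
  if (inherits(newdata, "mutation_dataset")) newdata <- newdata$features
  preds <- lapply(object$models, function(m) predict(m, newdata))
  en <- if (object$spec$mutation_class == "MPD") {
    a <- alpha %||% object$alpha
    a * preds$etor + (1 - a) * preds$epi
  } else {
    preds$ewc
  }
  b <- beta %||% object$beta
  tibble(
    pred_energy = en,
    pred_nonenergy = preds$nonenergy,
    pred = b * en + (1 - b) * preds$nonenergy
  )
}

#' LOCOV evaluation of the ensemble
#'
#' Runs leave-one-complex-out validation: for each fold the component models
#' are refitted on the training complexes and applied to the held-out
#' complex; pooled out-of-fold predictions are combined with the spec's
#' weights and scored.
#'
#' @inheritParams train_ensemble
#' @return An `evaluation_report`: pooled predictions, per-model and ensemble
#'   metrics, and fold assignments.
#' @export
evaluate_ensemble <- function(ds, spec, task = "regression",
                              seed = RF_DEFAULT_SEED,
                              ntree = RF_DEFAULT_NTREE) {
  comps <- ensemble_component_groups(spec)
  cv <- lapply(comps, function(g) locov_predict(ds, g, task, seed, ntree))
  en <- if (spec$mutation_class == "MPD") {
    energy_score(spec, etor_pred = cv$etor$pred, epi_pred = cv$epi$pred)
  } else {
    energy_score(spec, ewc_pred = cv$ewc$pred)
  }
  final <- ensemble_score(spec, en, cv$nonenergy$pred)
  obs <- cv[[1]]$obs
  preds <- tibble(
    mutation_id = ds$features$mutation_id,
    complex_id = ds$features$complex_id,
    obs = obs,
    pred_energy = en,
    pred_nonenergy = cv$nonenergy$pred,
    pred = final
  )
  per_model <- lapply(cv, function(p) metrics(p$pred, p$obs, task))
  structure(
    list(
      predictions = preds,
      metrics = metrics(final, obs, task),
      component_metrics = c(per_model,
                            list(energy = metrics(en, obs, task))),
      task = task,
      spec = spec,
      seed = seed
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$spec$mutation_class, " ", x$task,
      ", LOCOV over ", length(unique(x$predictions$complex_id)),
      " complexes\n", sep = "")
  m <- unlist(x$metrics)
  cat("  ensemble: ",
      paste(names(m), sprintf("%.3f", m), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
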