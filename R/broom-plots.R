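# broom-style tidiers and ggplot2 autoplot methods for fitted objects and
# reports.

#' @export
tidy.evaluation_report <- function(x, ...) {
  x$predictions %>%
    group_by(.data$complex_id) %>%
    summarise(
      n = dplyr::n(),
      rmse = if (x$task == "regression")
        metric_rmse(.data$pred, .data$obs) else NA_real_,
      mean_obs = mean(.data$obs),
      mean_pred = mean(.data$pred),
      .groups = "drop"
    )
}

#' @export
glance.evaluation_report <- function(x, ...) {
  bind_cols(
    tibble(mutation_class = x$spec$mutation_class, task = x$task,
           n = nrow(x$predictions),
           n_complexes = length(unique(x$predictions$complex_id))),
    as_tibble(x$metrics)
  )
}

#' @export
tidy.group_model <- function(x, ...) {
  imp <- randomForest::importance(x$fit)
  tibble(feature = rownames(imp), importance = imp[, 1]) %>%
    arrange(dplyr::desc(.data$importance))
}

#' @export
glance.group_model <- function(x, ...) {
  tibble(task = x$task, ntree = x$ntree, seed = x$seed,
         n_features = length(x$features),
         groups = paste(x$groups, collapse = "+"))
}

#' @export
tidy.ensemble_fit <- function(x, ...) {
  purrr::map_dfr(names(x$models), function(nm) {
    glance(x$models[[nm]]) %>% mutate(component = nm, .before = 1)
  })
}

#' @export
glance.ensemble_fit <- function(x, ...) {
  tibble(mutation_class = x$spec$mutation_class, task = x$task,
         alpha = x$alpha, beta = x$beta,
         gb_model_tag = x$spec$gb_model_tag)
}

#' Observed-versus-predicted plot for a LOCOV evaluation
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object: scatter of pooled out-of-fold predictions against
#'   observations (regression) or score distributions per class
#'   (classification).
#' @export
autoplot.evaluation_report <- function(object, ...) {
  p <- object$predictions
  if (object$task == "regression") {
    ggplot2::ggplot(p, ggplot2::aes(x = .data$obs, y = .data$pred)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::labs(
        x = "observed ddG (kcal/mol)", y = "predicted ddG (kcal/mol)",
        title = sprintf("LOCOV %s: PCC %.3f, RMSE %.3f",
                        object$spec$mutation_class, object$metrics$pcc,
                        object$metrics$rmse)
      )
  } else {
    ggplot2::ggplot(p, ggplot2::aes(x = factor(.data$obs == 1),
                                    y = .data$pred)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(
        x = "affinity-decreasing (ddG >= threshold)",
        y = "predicted score",
        title = sprintf("LOCOV %s: AUC %.3f, MCC %.3f",
                        object$spec$mutation_class, object$metrics$auc,
                        object$metrics$mcc)
      )
  }
}

#' Bar plot of a grouped ddG summary
#'
#' @param object A `group_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object with group means and standard-deviation bars.
#' @export
autoplot.group_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$mean_ddg)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_ddg - .data$sd_ddg,
                   ymax = .data$mean_ddg + .data$sd_ddg),
      width = 0.3) +
    ggplot2::labs(x = NULL, y = "mean ddG (kcal/mol)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
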