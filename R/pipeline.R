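# Reproducible end-to-end runs: resolved configuration, feature extraction
# from a bundle directory, training, LOCOV evaluation, prediction with a
# saved model bundle, and comparison summaries. Each stage writes its
# artifacts plus the resolved config and seed under the run directory. A thin
# command-line front end over these functions ships in inst/scripts/pnimut.

#' Resolved run configuration
#'
#' Defaults equal the final model configuration per mutation class
#' (alpha 0.4 / unused, beta 0.6 / 0.5, interface cutoff 5 Angstrom, hotspot
#' threshold 1 kcal/mol, GB tag HCT / OBC1).
#'
#' @param mutation_class `"MPD"` or `"MPR"`.
#' @param input_dir Bundle directory (structures/, tables/, profiles/,
#'   mutations.tsv).
#' @param out_dir Output/run directory.
#' @param alpha,beta,gb_model_tag,cutoff,hotspot_threshold Overrides of the
#'   class defaults.
#' @param groups Feature groups to compute in the features stage.
#' @param energy_groups,nonenergy_groups Group overrides for the ensemble
#'   spec.
#' @param seed RNG seed for model fitting.
#' @param n_points SASA sphere points.
#' @param ntree Forest size.
#' @return A `run_config` list.
#' @export
run_config <- function(mutation_class = "MPD", input_dir = NULL,
                       out_dir = tempfile("pnimut_run"), alpha = NULL,
                       beta = NULL, gb_model_tag = NULL, cutoff = 5,
                       hotspot_threshold = 1, groups = ALL_GROUPS,
                       energy_groups = NULL, nonenergy_groups = NULL,
                       seed = RF_DEFAULT_SEED, n_points = 240,
                       ntree = RF_DEFAULT_NTREE) {
  spec <- ensemble_spec(mutation_class, alpha = alpha, beta = beta,
                        gb_model_tag = gb_model_tag,
                        energy_groups = energy_groups,
                        nonenergy_groups = nonenergy_groups)
  structure(
    list(mutation_class = mutation_class, input_dir = input_dir,
         out_dir = out_dir, spec = spec, cutoff = cutoff,
         hotspot_threshold = hotspot_threshold, groups = groups,
         seed = as.integer(seed), n_points = n_points, ntree = ntree),
    class = "run_config"
  )
}

write_resolved_config <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  cfg$spec <- unclass(cfg$spec)
  jsonlite::write_json(
    c(cfg, list(package_version = as.character(utils::packageVersion("pnimut")))),
    file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
}

#' Generate a synthetic fixture bundle on disk
#'
#' @param spec A `synthetic_spec`.
#' @param out_dir Output directory.
#' @return The bundle directory, invisibly; also writes `truth.tsv` and the
#'   resolved spec.
#' @export
run_simulate <- function(spec, out_dir = tempfile("pnimut_sim")) {
  bundle <- make_dataset(spec, dir = out_dir)
  readr::write_tsv(bundle$truth, file.path(out_dir, "truth.tsv"),
                   progress = FALSE)
  jsonlite::write_json(unclass(spec), file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

read_bundle_dir <- function(dir, gb_model_tag = "synthetic") {
  muts <- read_mutations(file.path(dir, "mutations.tsv"))
  ids <- unique(muts$complex_id)
  complexes <- lapply(ids, function(id) {
    cs_wt <- read_structure(file.path(dir, "structures",
                                      paste0(id, "_wt.pdb")), id = id)
    ppath <- file.path(dir, "profiles", paste0(id, ".pssm"))
    profile <- if (file.exists(ppath)) read_pssm(ppath) else NULL
    rows <- which(muts$complex_id == id)
    per_mutation <- lapply(seq_along(rows), function(mi) {
      r <- muts[rows[mi], ]
      stem <- paste0(id, "_m", mi)
      cs_mut <- read_structure(
        file.path(dir, "structures", paste0(stem, "_mut.pdb")), id = id)
      list(
        cs_mut = cs_mut,
        target = monomer_key(r$chain, r$position),
        tab_wt = read_pair_energy_table(
          file.path(dir, "tables", paste0(stem, "_wt.csv")), cs_wt,
          state = "wild_type", gb_model_tag = gb_model_tag),
        tab_mut = read_pair_energy_table(
          file.path(dir, "tables", paste0(stem, "_mut.csv")), cs_wt,
          state = "mutant", gb_model_tag = gb_model_tag),
        row = r
      )
    })
    list(id = id, cs_wt = cs_wt, profile = profile,
         per_mutation = per_mutation)
  })
  list(complexes = complexes, mutations = muts)
}

#' Compute the per-mutation feature matrix for a bundle directory
#'
#' Validates every mutation against its wild-type structure (records failing
#' the wild-type-code check are dropped with a message), computes the
#' configured feature groups, and writes `features.tsv` plus a group manifest
#' under the run directory.
#'
#' @param config A `run_config` with `input_dir` set.
#' @return A `mutation_dataset`, invisibly; artifacts under
#'   `config$out_dir/features`.
#' @export
run_features <- function(config) {
  if (is.null(config$input_dir)) abort("config$input_dir is not set")
  needs_profile <- any(c("JSD") %in% config$groups)
  b <- read_bundle_dir(config$input_dir)
  blocks <- list()
  meta <- list()
  acc_groups <- c("bASA", "uASA", "dASA", "bRSA", "uRSA", "dRSA",
                  "IR-dASA", "IR-dRSA")
  for (cx in b$complexes) {
    if (needs_profile && is.null(cx$profile)) {
      abort(paste0("JSD group requires a conservation profile; none found ",
                   "for complex ", cx$id))
    }
    checked <- bind_mutation(
      bind_rows(lapply(cx$per_mutation, function(pm) pm$row)), cx$cs_wt)
    acc_wt <- if (any(config$groups %in% acc_groups)) {
      accessibility_table(cx$cs_wt, n_points = config$n_points)
    } else NULL
    for (mi in seq_along(cx$per_mutation)) {
      if (!checked$bound[mi]) {
        message("dropping mutation ", cx$id, " ", checked$chain[mi], ":",
                checked$position[mi], " (", checked$reason[mi], ")")
        next
      }
      pm <- cx$per_mutation[[mi]]
      blocks[[length(blocks) + 1]] <- compute_mutation_features(
        cs_wt = cx$cs_wt, cs_mut = pm$cs_mut, tab_wt = pm$tab_wt,
        tab_mut = pm$tab_mut, target = pm$target, profile = cx$profile,
        groups = config$groups, cutoff = config$cutoff,
        n_points = config$n_points, acc_wt = acc_wt
      )
      meta[[length(meta) + 1]] <- checked[mi, c("complex_id", "chain",
                                                "position", "wt", "mut",
                                                "ddg_exp", "key")]
    }
  }
  if (length(blocks) == 0) abort("no valid mutations after binding checks")
  ds <- build_dataset(
    blocks,
    bind_rows(meta) %>% mutate(mutation_id = dplyr::row_number()),
    config$hotspot_threshold
  )
  fdir <- file.path(config$out_dir, "features")
  dir.create(fdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(ds$features, file.path(fdir, "features.tsv"),
                   progress = FALSE)
  readr::write_tsv(ds$manifest, file.path(fdir, "manifest.tsv"),
                   progress = FALSE)
  write_resolved_config(config, fdir)
  invisible(ds)
}

#' Train the ensemble and save a model bundle
#'
#' @param config A `run_config`.
#' @param ds A `mutation_dataset` (e.g. from [run_features()]).
#' @param task `"regression"` or `"classification"`.
#' @param sbs Optionally run group-wise sequential backward selection over
#'   the spec's nonenergy groups before fitting.
#' @param tune_weights Tune alpha/beta by grid search on LOCOV predictions.
#' @return An `ensemble_fit`, invisibly; bundle at
#'   `config$out_dir/model/bundle.rds`.
#' @export
run_train <- function(config, ds, task = "regression", sbs = FALSE,
                      tune_weights = FALSE) {
  spec <- config$spec
  if (sbs) {
    sel <- sbs_select(ds, spec$nonenergy_groups, task, config$seed,
                      config$ntree)
    spec <- ensemble_spec(spec$mutation_class, alpha = spec$alpha,
                          beta = spec$beta, gb_model_tag = spec$gb_model_tag,
                          energy_groups = spec$energy_groups,
                          nonenergy_groups = sel$selected)
  }
  fit <- train_ensemble(ds, spec, task, config$seed, config$ntree,
                        tune_weights = tune_weights)
  mdir <- file.path(config$out_dir, "model")
  dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(fit, file.path(mdir, "bundle.rds"), version = 3)
  write_resolved_config(config, mdir)
  invisible(fit)
}

#' LOCOV-evaluate the configured ensemble
#'
#' @inheritParams run_train
#' @return An `evaluation_report`, invisibly; `report.json` and
#'   `predictions.tsv` under `config$out_dir/evaluate`.
#' @export
run_evaluate <- function(config, ds, task = "regression") {
  rep_ <- evaluate_ensemble(ds, config$spec, task, config$seed, config$ntree)
  edir <- file.path(config$out_dir, "evaluate")
  dir.create(edir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(rep_$predictions, file.path(edir, "predictions.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(task = task, metrics = rep_$metrics,
         component_metrics = rep_$component_metrics, seed = config$seed),
    file.path(edir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  write_resolved_config(config, edir)
  invisible(rep_)
}

#' Predict new mutations with a saved model bundle
#'
#' Emits both the ddG estimate (regression bundle) or affinity-decreasing
#' probability (classification bundle) and the component scores.
#'
#' @param bundle_path Path to a saved `bundle.rds`, or an `ensemble_fit`.
#' @param ds A `mutation_dataset` with the bundle's feature groups.
#' @param alpha,beta Optional weight overrides.
#' @return Tibble: mutation ids plus `pred_energy`, `pred_nonenergy`, `pred`.
#' @export
run_predict <- function(bundle_path, ds, alpha = NULL, beta = NULL) {
  fit <- if (inherits(bundle_path, "ensemble_fit")) bundle_path else
    readRDS(bundle_path)
  missing <- setdiff(fit$feature_manifest$feature, names(ds$features))
  if (length(missing) > 0) {
    abort(paste0("feature manifest mismatch; dataset lacks: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  bind_cols(
    ds$features %>% select(dplyr::any_of(c("mutation_id", "complex_id",
                                           "position", "wt", "mut"))),
    predict(fit, ds, alpha = alpha, beta = beta)
  )
}

#' Comparison summaries for a dataset
#'
#' Per-residue-type ddG summary plus (when two datasets are given) the
#' between-group distance over the 20 residue types and a rank-sum test of
#' the pooled ddG distributions.
#'
#' @param ds A `mutation_dataset` (grouping on the wild-type residue `wt`).
#' @param ds2 Optional second dataset to compare against.
#' @return List with `summary` (and `summary2`, `distance`, `test` when
#'   `ds2` is given).
#' @export
run_compare <- function(ds, ds2 = NULL) {
  out <- list(summary = group_summary(ds, "wt"))
  if (!is.null(ds2)) {
    out$summary2 <- group_summary(ds2, "wt")
    out$distance <- suppressWarnings(
      group_distance(out$summary, out$summary2))
    out$test <- compare_distributions(ds$features$ddg, ds2$features$ddg)
  }
  out
}
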