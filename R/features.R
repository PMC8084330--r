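# Assembling per-mutation feature blocks (5 energy + 17 nonenergy groups)
# into the tabular dataset consumed by the modeling layer. Every group vector
# concatenates wild-type values with mutant-minus-wild-type differences.

flatten_group <- function(group, wt, mut) {
  nm <- names(wt) %||% "value"
  v <- c(wt, mut - wt)
  names(v) <- c(paste(group, "wt", nm, sep = "."),
                paste(group, "diff", nm, sep = "."))
  v
}

state_nonenergy_values <- function(cs, iface, target, profile = NULL,
                                   acc = NULL, cutoff = 5, n_points = 960,
                                   groups = NONENERGY_GROUPS) {
  out <- list()
  acc_groups <- c("bASA", "uASA", "dASA", "bRSA", "uRSA", "dRSA",
                  "IR-dASA", "IR-dRSA")
  if (any(acc_groups %in% groups)) {
    if (is.null(acc)) acc <- accessibility_table(cs, n_points = n_points)
    out <- c(out, accessibility_features(acc, target, iface))
  }
  if ("NHB" %in% groups) out$NHB <- c(NHB = hydrogen_bonds(cs, target))
  if ("IR-NHB" %in% groups) {
    out[["IR-NHB"]] <- c(NHB = ir_hydrogen_bonds(cs, iface))
  }
  if (any(c("CFAA", "CFNA") %in% groups)) {
    out <- c(out, contact_features(cs, target, cutoff))
  }
  if (any(c("IR-CFAA", "IR-CFNA") %in% groups)) {
    out <- c(out, ir_contact_features(cs, iface, cutoff))
  }
  if (any(c("ENDES", "IR-ENDES") %in% groups)) {
    out <- c(out, endes_scores(cs, target, iface, profile))
  }
  if ("JSD" %in% groups) {
    if (is.null(profile)) {
      abort("JSD group requires a conservation profile")
    }
    resno <- cs$monomers$resno[match(target, cs$monomers$key)]
    out$JSD <- c(JSD = jsd_conservation(profile, resno))
  }
  out[intersect(groups, names(out))]
}

#' Compute the full feature block for one mutation
#'
#' Produces the registered energy and nonenergy feature groups for a mutation,
#' each as wild-type values concatenated with mutant-minus-wild-type
#' differences. Interface membership is computed on the wild-type structure
#' and reused for the mutant state unless `interface_per_state = TRUE`.
#'
#' @param cs_wt,cs_mut Wild-type and mutant `complex_structure`s.
#' @param tab_wt,tab_mut Matching `pair_energy_table`s (needed for energy
#'   groups).
#' @param target Monomer key of the mutated residue.
#' @param profile Optional `conservation_profile` (needed for JSD and the
#'   default interface-score provider's conservation component).
#' @param groups Feature groups to compute (default: all 22).
#' @param cutoff Interface/contact cutoff, Angstrom.
#' @param n_points SASA sphere points.
#' @param interface_per_state Recompute interface on the mutant structure for
#'   mutant-state values.
#' @param acc_wt,acc_mut Optional precomputed [accessibility_table()]s (reuse
#'   across mutations of the same complex).
#' @return Named list of named feature vectors, one per group.
#' @export
compute_mutation_features <- function(cs_wt, cs_mut, tab_wt = NULL,
                                      tab_mut = NULL, target,
                                      profile = NULL, groups = ALL_GROUPS,
                                      cutoff = 5, n_points = 960,
                                      interface_per_state = FALSE,
                                      acc_wt = NULL, acc_mut = NULL) {
  groups <- match.arg(groups, ALL_GROUPS, several.ok = TRUE)
  out <- list()
  if (any(groups %in% ENERGY_GROUPS)) {
    if (is.null(tab_wt) || is.null(tab_mut)) {
      abort("energy groups require wild-type and mutant energy tables")
    }
    eb <- assemble_energy_block(tab_wt, tab_mut, cs_wt, cs_mut, target,
                                interface_per_state, cutoff,
                                groups = intersect(groups, ENERGY_GROUPS))
    out <- c(out, eb)
  }
  ne_groups <- intersect(groups, NONENERGY_GROUPS)
  if (length(ne_groups) > 0) {
    iface_wt <- detect_interface(cs_wt, cutoff)
    iface_mut <- if (interface_per_state) detect_interface(cs_mut, cutoff)
      else iface_wt
    wt_vals <- state_nonenergy_values(cs_wt, iface_wt, target, profile,
                                      acc_wt, cutoff, n_points, ne_groups)
    mut_vals <- state_nonenergy_values(cs_mut, iface_mut, target, profile,
                                       acc_mut, cutoff, n_points, ne_groups)
    for (g in ne_groups) {
      out[[g]] <- flatten_group(g, wt_vals[[g]], mut_vals[[g]])
    }
  }
  out
}

#' Assemble a mutation dataset from per-mutation feature blocks
#'
#' @param blocks Named list (one element per mutation) of feature-block lists
#'   as returned by [compute_mutation_features()].
#' @param mutations Tibble aligned with `blocks`: `mutation_id`, `complex_id`,
#'   `ddg_exp` and any annotation columns.
#' @param hotspot_threshold Class threshold, kcal/mol.
#' @return A `mutation_dataset`.
#' @export
build_dataset <- function(blocks, mutations, hotspot_threshold = 1) {
  mutations <- as_tibble(mutations)
  stopifnot(length(blocks) == nrow(mutations))
  rows <- purrr::map(blocks, function(b) {
    v <- unlist(unname(lapply(names(b), function(g) b[[g]])))
    as_tibble(as.list(v))
  })
  feat <- bind_rows(rows)
  manifest <- purrr::map_dfr(names(blocks[[1]]), function(g) {
    tibble(group = g, feature = names(blocks[[1]][[g]]))
  })
  features <- bind_cols(
    mutations %>% mutate(ddg = .data$ddg_exp),
    feat
  )
  if (!"mutation_id" %in% names(features)) {
    features$mutation_id <- seq_len(nrow(features))
  }
  mutation_dataset(features, manifest, hotspot_threshold)
}

#' Add a pure-noise feature group to a dataset
#'
#' Useful for benchmarking feature-group selection: the group carries `p`
#' standard-normal columns independent of the labels.
#'
#' @param ds A `mutation_dataset`.
#' @param name Group name.
#' @param p Number of noise features.
#' @param seed RNG seed.
#' @return The dataset with the extra group registered.
#' @export
add_noise_group <- function(ds, name, p = 5, seed = 1) {
  set.seed(seed)
  cols <- paste(name, "wt", seq_len(p), sep = ".")
  noise <- matrix(rnorm(nrow(ds$features) * p), ncol = p,
                  dimnames = list(NULL, cols))
  ds$features <- bind_cols(ds$features, as_tibble(noise))
  ds$manifest <- bind_rows(ds$manifest, tibble(group = name, feature = cols))
  ds$groups <- unique(ds$manifest$group)
  ds
}
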