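# Comparison statistics between mutation classes: grouped ddG summaries, the
# between-group mean-distance formula, major-binding-mode dissection of a
# mutated residue, and rank-based significance tests with star tiers.

#' Grouped ddG summary
#'
#' @param ds A `mutation_dataset`, or a tibble with a `ddg` column.
#' @param grouping Name of the grouping column (e.g. wild-type residue type,
#'   location class, binding-mode class), or a vector of group labels aligned
#'   with the rows.
#' @return Tibble with `group`, `n`, `mean_ddg`, `sd_ddg`.
#' @export
group_summary <- function(ds, grouping) {
  d <- if (inherits(ds, "mutation_dataset")) ds$features else as_tibble(ds)
  if (nrow(d) == 0) abort("empty dataset")
  g <- if (length(grouping) == 1 && is.character(grouping) &&
           grouping %in% names(d)) d[[grouping]] else grouping
  if (length(g) != nrow(d)) abort("grouping does not resolve for every mutation")
  if (anyNA(g)) abort("grouping has missing values")
  out <- tibble(group = as.character(g), ddg = d$ddg) %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(), mean_ddg = mean(.data$ddg),
              sd_ddg = sd(.data$ddg), .groups = "drop") %>%
    arrange(.data$group)
  class(out) <- c("group_summary", class(out))
  out
}

#' Distance between two per-residue-type mean ddG vectors
#'
#' `dd = sqrt( (1/20) * sum_i (mean_i - mean'_i)^2 )` over the 20 amino-acid
#' types. Types missing from a summary are imputed (default 0) with a
#' warning.
#'
#' @param means_a,means_b Named numeric vectors of per-type mean ddG, or
#'   `group_summary` tibbles (using `group`/`mean_ddg`).
#' @param impute Value used for residue types absent from a vector.
#' @return The distance (kcal/mol).
#' @export
group_distance <- function(means_a, means_b, impute = 0) {
  as_vec <- function(m) {
    if (inherits(m, "data.frame")) {
      setNames(m$mean_ddg, m$group)
    } else m
  }
  types <- unname(AA3)
  fill <- function(v) {
    miss <- setdiff(types, names(v))
    if (length(miss) > 0) {
      warn(paste0("residue type(s) missing, imputed ", impute, ": ",
                  paste(miss, collapse = ", ")))
      v[miss] <- impute
    }
    v[types]
  }
  a <- fill(as_vec(means_a))
  b <- fill(as_vec(means_b))
  sqrt(mean((a - b)^2))
}

#' Major binding mode of a mutated residue
#'
#' Tallies heavy-atom contacts (< `cutoff`) between the target residue and
#' nucleotides, then reports the dominant categories: the nucleotide type
#' with the greatest share of contacts, the dominant nucleotide subunit
#' (phosphate, sugar or nucleobase by contacted atom class), and the dominant
#' contact class (residue sidechain/backbone x nucleotide nucleobase/backbone,
#' where sugar and phosphate count as backbone). Ties break lexicographically;
#' a residue with no nucleic contact gets mode `"none"`.
#'
#' @param cs A `complex_structure`.
#' @param target Monomer key.
#' @param cutoff Heavy-atom cutoff, Angstrom.
#' @return Tibble with `major_nucleotide`, `major_subunit`,
#'   `major_contact_class` and `n_contacts`.
#' @export
major_binding_mode <- function(cs, target, cutoff = 5) {
  atoms <- cs$atoms
  t_at <- atoms[atoms$key == target & atoms$is_heavy, , drop = FALSE]
  n_at <- atoms[atoms$kind != "amino_acid" & atoms$is_heavy, , drop = FALSE]
  if (nrow(n_at) == 0 || nrow(t_at) == 0) {
    return(tibble(major_nucleotide = "none", major_subunit = "none",
                  major_contact_class = "none", n_contacts = 0L))
  }
  tm <- as.matrix(t_at[, c("x", "y", "z")])
  nm <- as.matrix(n_at[, c("x", "y", "z")])
  d2 <- outer(rowSums(tm^2), rowSums(nm^2), "+") - 2 * tcrossprod(tm, nm)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble(major_nucleotide = "none", major_subunit = "none",
                  major_contact_class = "none", n_contacts = 0L))
  }
  res_cls <- ifelse(t_at$record_class[hit[, 1]] == "sidechain",
                    "sidechain", "backbone")
  nuc_code <- n_at$code[hit[, 2]]
  nuc_sub <- n_at$record_class[hit[, 2]]
  nuc_cls <- ifelse(nuc_sub == "nucleobase", "nucleobase", "backbone")
  major <- function(v) {
    tb <- sort(table(v), decreasing = TRUE)
    sort(names(tb)[tb == tb[1]])[1]
  }
  tibble(
    major_nucleotide = major(nuc_code),
    major_subunit = major(nuc_sub),
    major_contact_class = major(paste(res_cls, nuc_cls, sep = "-")),
    n_contacts = nrow(hit)
  )
}

#' Compare two ddG distributions (Mann-Whitney U, star tiers)
#'
#' Two-sided Wilcoxon rank-sum test with significance tiers at the
#' conventional thresholds: `***` P < 0.001, `**` 0.001 <= P < 0.01, `*`
#' 0.01 <= P < 0.05, `ns` otherwise (half-open intervals).
#'
#' @param values_a,values_b Numeric samples, each n >= 3.
#' @return Tibble with `p_value` and `tier`.
#' @export
compare_distributions <- function(values_a, values_b) {
  if (length(values_a) < 3 || length(values_b) < 3) {
    abort("each sample needs at least 3 values")
  }
  p <- suppressWarnings(
    wilcox.test(values_a, values_b, alternative = "two.sided")$p.value
  )
  tier <- dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
  tibble(p_value = p, tier = tier)
}
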