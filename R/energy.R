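# Per-residue-pair energy decomposition tables and the five geometric
# partition-based energy feature groups: EWC (whole complex), ETOR (target vs
# others by distance shell), EPP (partitioned-protein residue-energy sums),
# EINI (interface vs noninterface pair sums), EPI (interface split into
# residue-residue / residue-nucleotide / nucleotide-nucleotide pair sums).
#
# Each table entry carries five terms per unordered monomer pair: the total
# free-energy contribution and its electrostatic, van der Waals, polar
# solvation (GB) and nonpolar solvation (SA) components, in kcal/mol.

#' Construct a pair-energy table from a tidy entry tibble
#'
#' @param entries Tibble with columns `key_i`, `key_j` (monomer keys) and the
#'   five term columns `total`, `ele`, `vdw`, `gb`, `sa` (kcal/mol). Pairs are
#'   canonicalized to unordered form (monomer order of the structure); rows
#'   duplicated across directions are summed.
#' @param cs The `complex_structure` the keys resolve against.
#' @param state `"wild_type"` or `"mutant"`.
#' @param gb_model_tag GB model tag; one of HCT, OBC1, OBC2, GBn1, GBn2 or
#'   `"synthetic"`.
#' @param check_closure Check `|total - (ele+vdw+gb+sa)| <= closure_tol`.
#' @param closure_tol Term-closure tolerance, kcal/mol.
#' @return A `pair_energy_table`.
#' @export
pair_energy_table <- function(entries, cs, state = "wild_type",
                              gb_model_tag = "synthetic",
                              check_closure = TRUE, closure_tol = 1e-3) {
  stopifnot(state %in% c("wild_type", "mutant"))
  if (!gb_model_tag %in% GB_MODELS) {
    abort(paste0("unknown gb_model_tag: ", gb_model_tag))
  }
  entries <- as_tibble(entries)
  req <- c("key_i", "key_j", ENERGY_TERMS)
  if (!all(req %in% names(entries))) {
    abort(paste0("entries must have columns: ", paste(req, collapse = ", ")))
  }
  order_i <- match(entries$key_i, cs$monomers$key)
  order_j <- match(entries$key_j, cs$monomers$key)
  bad <- which(is.na(order_i) | is.na(order_j))
  if (length(bad) > 0) {
    abort(paste0("row ", bad[1], ": key not in structure (",
                 entries$key_i[bad[1]], ", ", entries$key_j[bad[1]], ")"))
  }
  if (any(!is.finite(as.matrix(entries[ENERGY_TERMS])))) {
    abort("non-finite energy terms")
  }
  # canonical unordered orientation: i precedes j in structure monomer order
  swap <- order_i > order_j
  ki <- ifelse(swap, entries$key_j, entries$key_i)
  kj <- ifelse(swap, entries$key_i, entries$key_j)
  entries <- entries %>%
    mutate(key_i = ki, key_j = kj) %>%
    group_by(.data$key_i, .data$key_j) %>%
    summarise(across(all_of(ENERGY_TERMS), sum), .groups = "drop") %>%
    arrange(match(.data$key_i, cs$monomers$key),
            match(.data$key_j, cs$monomers$key))
  selfs <- entries$key_i[entries$key_i == entries$key_j]
  missing_self <- setdiff(cs$monomers$key, selfs)
  if (length(missing_self) > 0) {
    abort(paste0("missing self entries for: ",
                 paste(head(missing_self, 5), collapse = ", ")))
  }
  if (check_closure) {
    gap <- abs(entries$total -
                 (entries$ele + entries$vdw + entries$gb + entries$sa))
    if (any(gap > closure_tol)) {
      abort(paste0("term closure violated (max gap ",
                   format(max(gap)), " kcal/mol)"))
    }
  }
  structure(
    list(entries = entries, complex_id = cs$id, state = state,
         gb_model_tag = gb_model_tag),
    class = "pair_energy_table"
  )
}

#' Read a per-residue-pair energy decomposition CSV
#'
#' Expected header:
#' `chain_i,seq_i,icode_i,chain_j,seq_j,icode_j,total,ele,vdw,gb,sa`, one row
#' per unordered pair or per direction (directions are summed). Units
#' kcal/mol. This dialect mirrors per-residue-pair MM/GBSA decomposition
#' output; [convert_mmgbsa_stub()] documents the mapping.
#'
#' @inheritParams pair_energy_table
#' @param path CSV file path.
#' @return A `pair_energy_table`.
#' @export
read_pair_energy_table <- function(path, cs, state = "wild_type",
                                   gb_model_tag = "synthetic",
                                   check_closure = TRUE, closure_tol = 1e-3) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("chain_i", "seq_i", "icode_i", "chain_j", "seq_j", "icode_j",
           ENERGY_TERMS)
  if (!all(req %in% names(d))) {
    abort(paste0("decomposition CSV must have columns: ",
                 paste(req, collapse = ",")))
  }
  entries <- tibble(
    key_i = monomer_key(d$chain_i, d$seq_i,
                        ifelse(is.na(d$icode_i), "", d$icode_i)),
    key_j = monomer_key(d$chain_j, d$seq_j,
                        ifelse(is.na(d$icode_j), "", d$icode_j))
  ) %>% bind_cols(d[ENERGY_TERMS])
  pair_energy_table(entries, cs, state = state, gb_model_tag = gb_model_tag,
                    check_closure = check_closure, closure_tol = closure_tol)
}

#' Documented stub for converting MM/GBSA decomposition output
#'
#' Maps the columns of a per-residue-pair MM/GBSA decomposition data frame
#' (as produced by free-energy decomposition tools: resid 1, resid 2, internal,
#' van der Waals, electrostatic, polar solvation, non-polar solvation, total)
#' to the decomposition CSV dialect this package reads. Supplied as a helper
#' for users with an external energy engine; the synthetic generator emits the
#' dialect directly.
#'
#' @param decomp Data frame with columns `chain_i`, `seq_i`, `chain_j`,
#'   `seq_j`, `vdw`, `ele`, `gb`, `sa` and optionally `total` (recomputed as
#'   the term sum when absent) per pair direction.
#' @return A tibble in the package's decomposition CSV column layout.
#' @export
convert_mmgbsa_stub <- function(decomp) {
  d <- as_tibble(decomp)
  if (!"total" %in% names(d)) d$total <- d$ele + d$vdw + d$gb + d$sa
  if (!"icode_i" %in% names(d)) d$icode_i <- ""
  if (!"icode_j" %in% names(d)) d$icode_j <- ""
  d %>% select(all_of(c("chain_i", "seq_i", "icode_i", "chain_j", "seq_j",
                        "icode_j", ENERGY_TERMS)))
}

term_sums <- function(entries) {
  vapply(ENERGY_TERMS, function(tm) sum(entries[[tm]]), numeric(1))
}

zero_terms <- function() setNames(numeric(5), ENERGY_TERMS)

#' Whole-complex energies (EWC)
#'
#' Term-wise sum over every table entry (self plus pairwise).
#'
#' @param tab A `pair_energy_table`.
#' @return Named numeric vector of the five terms, kcal/mol.
#' @export
ewc <- function(tab) {
  if (nrow(tab$entries) == 0) abort("empty energy table")
  term_sums(tab$entries)
}

#' Residue energy: self entry plus all pairwise entries involving a monomer
#'
#' @param tab A `pair_energy_table`.
#' @param key Monomer key.
#' @return Named numeric vector of the five terms.
#' @export
residue_energy <- function(tab, key) {
  e <- tab$entries
  sel <- e$key_i == key | e$key_j == key
  if (!any(e$key_i == key & e$key_j == key)) {
    abort(paste0("missing self entry for ", key))
  }
  term_sums(e[sel, , drop = FALSE])
}

pairwise_energy <- function(tab, key_a, key_b) {
  e <- tab$entries
  sel <- (e$key_i == key_a & e$key_j == key_b) |
    (e$key_i == key_b & e$key_j == key_a)
  if (!any(sel)) return(zero_terms())
  term_sums(e[sel, , drop = FALSE])
}

shell_of <- function(d) {
  # half-open (lo, hi] shells over SHELL_BREAKS; shell index 2..6 of labels
  findInterval(d, SHELL_BREAKS, left.open = TRUE) + 1L
}

shells_to_target <- function(cs, target) {
  others <- setdiff(protein_keys(cs), target)
  if (length(others) == 0) {
    return(tibble(key = character(), shell = integer()))
  }
  dt <- min_distance_table(cs, target, others)
  tibble(key = dt$key_b, shell = shell_of(dt$d))
}

shell_matrix <- function(values_by_shell) {
  m <- matrix(0, nrow = 6, ncol = 5,
              dimnames = list(SHELL_LABELS, ENERGY_TERMS))
  for (s in names(values_by_shell)) m[as.integer(s), ] <- values_by_shell[[s]]
  m
}

#' Target-vs-others shell energies (ETOR)
#'
#' Partitions pairwise energies between the target residue and every other
#' protein residue into distance shells 0 (the target's self entry), (0,3],
#' (3,4], (4,5], (5,6] and (6, Inf) Angstrom by minimum heavy-atom distance.
#'
#' @param tab A `pair_energy_table`.
#' @param cs The bound `complex_structure`.
#' @param target Monomer key of the target (mutated) protein residue.
#' @return 6 x 5 matrix (shells x terms), kcal/mol.
#' @export
etor <- function(tab, cs, target) {
  if (!isTRUE(is_protein_key(cs, target))) {
    abort(paste0("target is not a protein residue: ", target))
  }
  sh <- shells_to_target(cs, target)
  vals <- list("1" = pairwise_energy(tab, target, target))
  if (nrow(sh) > 0) {
    for (s in sort(unique(sh$shell))) {
      keys <- sh$key[sh$shell == s]
      acc <- zero_terms()
      for (k in keys) acc <- acc + pairwise_energy(tab, target, k)
      vals[[as.character(s)]] <- acc
    }
  }
  shell_matrix(vals)
}

#' Partitioned-protein residue-energy sums (EPP)
#'
#' Same shells as [etor()], but shell values are sums of residue energies
#' (self + all interactions with every residue and nucleotide) of the protein
#' residues in each shell; shell 0 holds the target's own residue energy.
#'
#' @inheritParams etor
#' @return 6 x 5 matrix (shells x terms), kcal/mol.
#' @export
epp <- function(tab, cs, target) {
  if (!isTRUE(is_protein_key(cs, target))) {
    abort(paste0("target is not a protein residue: ", target))
  }
  sh <- shells_to_target(cs, target)
  vals <- list("1" = residue_energy(tab, target))
  if (nrow(sh) > 0) {
    for (s in sort(unique(sh$shell))) {
      keys <- sh$key[sh$shell == s]
      acc <- zero_terms()
      for (k in keys) acc <- acc + residue_energy(tab, k)
      vals[[as.character(s)]] <- acc
    }
  }
  shell_matrix(vals)
}

iface_members <- function(iface) {
  c(iface$interface_residues, iface$interface_nucleotides)
}

#' Interface/noninterface pair-energy sums (EINI)
#'
#' The interface partition sums entries over all pairwise combinations among
#' interface residues and nucleotides (their self entries included); every
#' remaining entry belongs to the noninterface partition, so the two
#' partitions sum to [ewc()] term-wise.
#'
#' @param tab A `pair_energy_table`.
#' @param iface An `interface_set` computed on the matching structure/state.
#' @return 2 x 5 matrix (`interface`, `noninterface` x terms), kcal/mol.
#' @export
eini <- function(tab, iface) {
  members <- iface_members(iface)
  if (length(members) == 0) {
    warn("empty interface: interface partition is all-zero")
  }
  e <- tab$entries
  in_if <- e$key_i %in% members & e$key_j %in% members
  m <- rbind(
    interface = if (any(in_if)) term_sums(e[in_if, ]) else zero_terms(),
    noninterface = if (any(!in_if)) term_sums(e[!in_if, ]) else zero_terms()
  )
  colnames(m) <- ENERGY_TERMS
  m
}

#' Partitioned-interface pair-energy sums (EPI)
#'
#' Splits the interface entries of [eini()] into residue-residue,
#' residue-nucleotide and nucleotide-nucleotide pair sums. Self entries join
#' the same-kind partition (residue self -> residue-residue; nucleotide self
#' -> nucleotide-nucleotide).
#'
#' @param tab A `pair_energy_table`.
#' @param iface An `interface_set`.
#' @param cs The `complex_structure` (for monomer kinds).
#' @return 3 x 5 matrix (`res_res`, `res_nuc`, `nuc_nuc` x terms), kcal/mol.
#' @export
epi <- function(tab, iface, cs) {
  members <- iface_members(iface)
  if (length(members) == 0) {
    warn("empty interface: all partitions are zero")
  }
  e <- tab$entries
  in_if <- e$key_i %in% members & e$key_j %in% members
  ei <- e[in_if, , drop = FALSE]
  pi_ <- is_protein_key(cs, ei$key_i)
  pj <- is_protein_key(cs, ei$key_j)
  cls <- ifelse(pi_ & pj, "res_res", ifelse(!pi_ & !pj, "nuc_nuc", "res_nuc"))
  m <- matrix(0, nrow = 3, ncol = 5,
              dimnames = list(c("res_res", "res_nuc", "nuc_nuc"), ENERGY_TERMS))
  for (cl in unique(cls)) m[cl, ] <- term_sums(ei[cls == cl, , drop = FALSE])
  m
}

flatten_named <- function(m, prefix) {
  if (is.matrix(m)) {
    v <- as.vector(t(m))
    names(v) <- paste(prefix, rep(rownames(m), each = ncol(m)),
                      rep(colnames(m), nrow(m)), sep = ".")
  } else {
    v <- m
    names(v) <- paste(prefix, names(m), sep = ".")
  }
  v
}

energy_group_values <- function(tab, cs, iface, target,
                                groups = ENERGY_GROUPS) {
  vals <- list()
  if ("EWC" %in% groups) vals$EWC <- ewc(tab)
  if ("ETOR" %in% groups) vals$ETOR <- etor(tab, cs, target)
  if ("EPP" %in% groups) vals$EPP <- epp(tab, cs, target)
  if ("EINI" %in% groups) vals$EINI <- eini(tab, iface)
  if ("EPI" %in% groups) vals$EPI <- epi(tab, iface, cs)
  vals
}

#' Assemble the five energy feature blocks for one mutation
#'
#' For each group the feature vector concatenates the wild-type values with
#' the mutant-minus-wild-type differences (positive differences destabilize,
#' matching ddG = dG_mut - dG_wt). The target key in the mutant state is the
#' mutated position. Vector lengths: EWC 10, ETOR 60, EPP 60, EINI 20, EPI 30.
#'
#' @param wt_tab,mut_tab `pair_energy_table`s sharing a `gb_model_tag`.
#' @param cs_wt,cs_mut Wild-type and mutant `complex_structure`s.
#' @param target Monomer key of the mutated residue.
#' @param interface_per_state If `TRUE`, recompute interface membership on the
#'   mutant structure for the mutant-state partitions; default uses wild-type
#'   membership for both states.
#' @param cutoff Interface cutoff, Angstrom.
#' @param groups Which of the five groups to compute.
#' @return Named list of named numeric feature vectors (one per group).
#' @export
assemble_energy_block <- function(wt_tab, mut_tab, cs_wt, cs_mut, target,
                                  interface_per_state = FALSE, cutoff = 5,
                                  groups = ENERGY_GROUPS) {
  if (wt_tab$gb_model_tag != mut_tab$gb_model_tag) {
    abort("gb_model_tag mismatch between wild-type and mutant tables")
  }
  groups <- intersect(ENERGY_GROUPS, groups)
  iface_wt <- detect_interface(cs_wt, cutoff)
  iface_mut <- if (interface_per_state) detect_interface(cs_mut, cutoff) else iface_wt
  wt <- energy_group_values(wt_tab, cs_wt, iface_wt, target, groups)
  mt <- energy_group_values(mut_tab, cs_mut, iface_mut, target, groups)
  out <- lapply(groups, function(g) {
    w <- flatten_named(wt[[g]], paste0(g, ".wt"))
    d <- flatten_named(mt[[g]], paste0(g, ".diff"))
    dw <- flatten_named(wt[[g]], paste0(g, ".diff"))
    c(w, d - dw)
  })
  setNames(out, groups)
}
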