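# Synthetic-fixture generation: structurally valid toy complexes (idealized
# peptide against an idealized nucleic strand), planted-signal per-pair
# energy tables with exact term closure, conservation profiles, and full
# mutation datasets with ddG labels that are a planted linear function of
# energy-feature differences plus Gaussian noise. Everything is reproducible
# from (spec, seed).

#' Specification for synthetic fixtures
#'
#' Defaults define the package's synthetic benchmark: 40 complexes with 6
#' mutations each, ddG equal to a planted whole-complex energy perturbation
#' plus Gaussian noise of 0.3 kcal/mol, protein-DNA chains with 4 designated
#' interface residues per complex.
#'
#' @param seed Master RNG seed (all generation derives from it).
#' @param n_complexes Number of complexes.
#' @param mutations_per_complex Mutations per complex.
#' @param nucleic `"DNA"` or `"RNA"`.
#' @param n_residues Protein residues per toy complex.
#' @param noise_sd Gaussian label noise sigma, kcal/mol (>= 0).
#' @param effect_range Uniform range of the planted per-mutation energy
#'   effect, kcal/mol.
#' @param effect_weight Weight of the planted effect in the ddG linear model.
#' @param table_noise Sigma of the per-term noise in the energy tables.
#' @param ca_spacing Residue spacing along the chain axis, Angstrom.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, n_complexes = 40,
                           mutations_per_complex = 6, nucleic = c("DNA", "RNA"),
                           n_residues = 10, noise_sd = 0.3,
                           effect_range = c(-1, 3), effect_weight = 1,
                           table_noise = 0.05, ca_spacing = 3.8) {
  nucleic <- match.arg(nucleic)
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (table_noise < 0) abort("table_noise must be >= 0")
  if (n_residues < 6) abort("need at least 6 residues")
  structure(
    list(seed = as.integer(seed), n_complexes = as.integer(n_complexes),
         mutations_per_complex = as.integer(mutations_per_complex),
         nucleic = nucleic, n_residues = as.integer(n_residues),
         noise_sd = noise_sd, effect_range = effect_range,
         effect_weight = effect_weight, table_noise = table_noise,
         ca_spacing = ca_spacing),
    class = "synthetic_spec"
  )
}

# residues with >= 3 sidechain pseudo-atoms can reach the interface
INTERFACE_CODES <- names(AA_SIDECHAIN_N)[AA_SIDECHAIN_N >= 3]

interface_positions <- function(spec) {
  seq(2, spec$n_residues - 1, by = 2)
}

derive_seed <- function(spec, ...) {
  parts <- c(spec$seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p)) %% 2147483647
  as.integer(s) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic smooth jitter (no RNG) so wild-type and mutant share
# coordinates everywhere except the mutated sidechain
det_jitter <- function(i, k, ci, phase) {
  0.15 * sin(1.7 * i + 2.3 * k + 0.9 * ci + phase)
}

protein_atoms_for <- function(codes, ci, spacing, iface_pos = integer()) {
  purrr::map_dfr(seq_along(codes), function(i) {
    x0 <- i * spacing
    code <- codes[i]
    nside <- AA_SIDECHAIN_N[[code]]
    zc <- 0.02 * (utf8ToInt(code) - 65)
    bb <- tibble(
      atom = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = x0 + c(-1.2, 0, 1.2, 1.4),
      y = c(0.2, 0, 0.3, -0.9),
      z = c(-0.4, 0, 0.4, 0.8)
    )
    sc <- NULL
    if (nside > 0) {
      k <- seq_len(nside)
      polar_tip <- code %in% c("R", "N", "D", "C", "Q", "E", "H", "K", "M",
                               "S", "T", "W", "Y")
      el <- rep("C", nside)
      if (polar_tip) el[nside] <- "N"
      nm <- paste0(ifelse(el == "C", "CS", "NS"), k)
      sc <- tibble(
        atom = nm, element = el,
        x = x0 + 0.5 * ((k - 1) %/% 3),
        y = 1.0 + 0.8 * ((k - 1) %% 3),
        z = 0.6 * (-1)^k + zc
      )
      if (i %in% iface_pos) {
        # interface residues extend their terminal sidechain atom toward the
        # nucleic strand so that they (and only they) fall under the 5 A rule
        sc$x[nside] <- x0
        sc$y[nside] <- 4.2
        sc$z[nside] <- 0.3 + zc
      }
    }
    at <- bind_rows(bb, sc)
    at %>% mutate(
      x = .data$x + det_jitter(i, dplyr::row_number(), ci, 0),
      y = .data$y + det_jitter(i, dplyr::row_number(), ci, 1.1),
      z = .data$z + det_jitter(i, dplyr::row_number(), ci, 2.2),
      chain = "A", resno = i, icode = "",
      resname = AA1[[code]], kind = "amino_acid", code = code
    )
  })
}

NUC_TEMPLATE <- data.frame(
  atom = c("P", "OP1", "OP2", "C5'", "C4'", "O4'", "C3'", "C2'", "C1'",
           "N1", "C2", "N3", "C4"),
  element = c("P", "O", "O", "C", "C", "O", "C", "C", "C", "N", "C", "N", "C"),
  dx = c(0, -0.9, 0.9, 0, 0.7, -0.5, 0.6, 0, -0.7, 0, 0.8, 0.7, -0.1),
  dy = c(2.0, 2.6, 2.6, 1.2, 0.6, 0.4, -0.2, -0.8, -0.5, -1.6, -2.2, -3.2,
         -3.5),
  dz = c(0, 0, 0, 0.5, 0, 0.3, 0.7, 0, 0.5, 0, 0, 0.3, 0.5)
)

nucleic_atoms_for <- function(nuc_codes, iface_pos, ci, spacing, nucleic) {
  y0 <- 11.7
  resnames <- if (nucleic == "DNA") paste0("D", nuc_codes) else nuc_codes
  kind <- if (nucleic == "DNA") "dna_nucleotide" else "rna_nucleotide"
  purrr::map_dfr(seq_along(nuc_codes), function(j) {
    xn <- iface_pos[j] * spacing
    NUC_TEMPLATE %>%
      mutate(
        x = xn + .data$dx + det_jitter(100 + j, dplyr::row_number(), ci, 0.5),
        y = y0 + .data$dy + det_jitter(100 + j, dplyr::row_number(), ci, 1.6),
        z = .data$dz + det_jitter(100 + j, dplyr::row_number(), ci, 2.7),
        chain = "B", resno = j, icode = "",
        resname = resnames[j], kind = kind, code = nuc_codes[j]
      ) %>%
      select(-"dx", -"dy", -"dz")
  })
}

assemble_toy_structure <- function(id, codes, nuc_codes, iface_pos, ci, spec) {
  pa <- protein_atoms_for(codes, ci, spec$ca_spacing, iface_pos)
  na_ <- nucleic_atoms_for(nuc_codes, iface_pos, ci, spec$ca_spacing,
                           spec$nucleic)
  atoms <- bind_rows(pa, na_) %>%
    mutate(key = monomer_key(.data$chain, .data$resno, .data$icode),
           is_heavy = TRUE,
           record_class = atom_record_class(.data$atom, .data$kind))
  cs <- new_complex_structure(id, atoms)
  dmin <- min(min_distance_table(cs, protein_keys(cs), nucleic_keys(cs))$d)
  if (dmin < 0.5) {
    abort(paste0("steric coincidence across chains (min distance ",
                 format(dmin), " A)"))
  }
  cs
}

# the full generation plan (sequences, mutations, effects, labels) under one
# seeded stream
dataset_plan <- function(spec) {
  with_seed(derive_seed(spec, 1), {
    iface_pos <- interface_positions(spec)
    nuc_alpha <- if (spec$nucleic == "DNA") c("A", "C", "G", "T") else
      c("A", "C", "G", "U")
    complexes <- purrr::map(seq_len(spec$n_complexes), function(ci) {
      codes <- sample(names(AA_SIDECHAIN_N), spec$n_residues, replace = TRUE)
      codes[iface_pos] <- sample(INTERFACE_CODES, length(iface_pos),
                                 replace = TRUE)
      nuc_codes <- sample(nuc_alpha, length(iface_pos), replace = TRUE)
      muts <- tibble(
        position = sample(iface_pos, spec$mutations_per_complex,
                          replace = TRUE),
        effect = runif(spec$mutations_per_complex, spec$effect_range[1],
                       spec$effect_range[2]),
        noise = rnorm(spec$mutations_per_complex, 0, spec$noise_sd)
      ) %>%
        mutate(
          wt = codes[.data$position],
          mut = purrr::map_chr(.data$wt, function(w) {
            sample(setdiff(INTERFACE_CODES, w), 1)
          }),
          ddg = spec$effect_weight * .data$effect + .data$noise
        ) %>%
        distinct(.data$position, .data$mut, .keep_all = TRUE)
      list(ci = ci, codes = codes, nuc_codes = nuc_codes,
           iface_pos = iface_pos, mutations = muts)
    })
    complexes
  })
}

#' Generate one toy wild-type/mutant complex pair as PDB files
#'
#' Builds an idealized peptide placed against an idealized nucleic strand so
#' that the designated interface residues (and only those) fall within 5
#' Angstrom of a nucleotide; the mutant file differs from the wild type only
#' at the mutated residue's sidechain composition.
#'
#' @param spec A `synthetic_spec`.
#' @param complex_index Which complex of the plan to build.
#' @param mutation_index Which of its mutations to apply.
#' @param dir Output directory (created if needed).
#' @return List with `wt_path`, `mut_path`, the `complex_structure`s
#'   (`cs_wt`, `cs_mut`), the `target` key and the mutation row.
#' @export
make_toy_complex <- function(spec, complex_index = 1, mutation_index = 1,
                             dir = tempfile("toycomplex")) {
  plan <- dataset_plan(spec)
  if (complex_index > length(plan)) abort("complex_index out of range")
  built <- build_complex_pair(spec, plan[[complex_index]], mutation_index)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt_path <- file.path(dir, paste0(built$cs_wt$id, "_wt.pdb"))
  mut_path <- file.path(dir, paste0(built$cs_wt$id, "_mut",
                                    mutation_index, ".pdb"))
  write_structure_pdb(built$cs_wt, wt_path)
  write_structure_pdb(built$cs_mut, mut_path)
  c(built, list(wt_path = wt_path, mut_path = mut_path))
}

build_complex_pair <- function(spec, cplan, mutation_index, cs_wt = NULL) {
  if (mutation_index > nrow(cplan$mutations)) {
    abort("mutation_index out of range")
  }
  mrow <- cplan$mutations[mutation_index, ]
  id <- sprintf("TOY%03d", cplan$ci)
  if (is.null(cs_wt)) {
    cs_wt <- assemble_toy_structure(id, cplan$codes, cplan$nuc_codes,
                                    cplan$iface_pos, cplan$ci, spec)
  }
  mut_codes <- cplan$codes
  mut_codes[mrow$position] <- mrow$mut
  cs_mut <- assemble_toy_structure(id, mut_codes, cplan$nuc_codes,
                                   cplan$iface_pos, cplan$ci, spec)
  list(cs_wt = cs_wt, cs_mut = cs_mut,
       target = monomer_key("A", mrow$position), mutation = mrow)
}

#' Write a complex structure as a PDB file
#'
#' @param cs A `complex_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(cs, path) {
  a <- cs$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resname, chain = a$chain,
    insert = ifelse(a$icode == "", "", a$icode),
    eleno = seq_len(nrow(a)), elety = a$atom, elesy = a$element,
    o = rep(1, nrow(a)), b = rep(0, nrow(a))
  )
  invisible(path)
}

#' Generate wild-type and mutant pair-energy tables for a toy complex
#'
#' Pair energies follow a distance-decaying kernel with per-term noise; the
#' total term is the exact sum of the four components (term closure holds by
#' construction). The mutant table equals the wild-type table except that the
#' mutated residue's self entry is perturbed by the planted effect (added to
#' the electrostatic component and the total), so the whole-complex energy
#' difference equals the effect exactly.
#'
#' @param cs_wt Wild-type `complex_structure`.
#' @param target Mutated residue key.
#' @param effect Planted energy effect, kcal/mol.
#' @param spec A `synthetic_spec` (noise level).
#' @param seed Seed for the table noise stream.
#' @return List with `wt` and `mut` `pair_energy_table`s (gb tag
#'   `"synthetic"`).
#' @export
wt_energy_table <- function(cs_wt, spec, seed) {
  keys <- cs_wt$monomers$key
  n <- length(keys)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  dmat <- matrix(0, n, n)
  dt <- min_distance_table(cs_wt, keys, keys)
  dmat[cbind(match(dt$key_a, keys), match(dt$key_b, keys))] <- dt$d
  entries <- with_seed(seed, {
    base <- -2 * exp(-dmat[idx] / 3)
    base[idx[, 1] == idx[, 2]] <- -3 + runif(sum(idx[, 1] == idx[, 2]), 0, 1)
    comp <- outer(base, c(0.4, 0.3, 0.2, 0.1)) +
      matrix(rnorm(length(base) * 4, 0, spec$table_noise), ncol = 4)
    tibble(
      key_i = keys[idx[, 1]], key_j = keys[idx[, 2]],
      ele = comp[, 1], vdw = comp[, 2], gb = comp[, 3], sa = comp[, 4]
    ) %>% mutate(total = .data$ele + .data$vdw + .data$gb + .data$sa)
  })
  pair_energy_table(entries, cs_wt, state = "wild_type",
                    gb_model_tag = "synthetic")
}

apply_planted_effect <- function(wt_tab, cs_wt, target, effect) {
  mut_entries <- wt_tab$entries
  sel <- mut_entries$key_i == target & mut_entries$key_j == target
  mut_entries$ele[sel] <- mut_entries$ele[sel] + effect
  mut_entries$total[sel] <- mut_entries$total[sel] + effect
  pair_energy_table(mut_entries, cs_wt, state = "mutant",
                    gb_model_tag = "synthetic")
}

make_pair_energy_tables <- function(cs_wt, target, effect, spec,
                                    seed = derive_seed(spec, 2)) {
  wt <- wt_energy_table(cs_wt, spec, seed)
  list(wt = wt, mut = apply_planted_effect(wt, cs_wt, target, effect))
}

# synthetic conservation profile: Dirichlet-like rows, sharpened at the
# designated conserved (interface) positions
make_profile <- function(spec, cplan) {
  with_seed(derive_seed(spec, 3, cplan$ci), {
    n <- spec$n_residues
    p <- matrix(stats::rgamma(n * 20, 0.5), nrow = n)
    p <- p / rowSums(p)
    for (i in cplan$iface_pos) {
      j <- match(cplan$codes[i], names(BLOSUM62_BG))
      row <- rep(0.2 / 19, 20)
      row[j] <- 0.8
      p[i, ] <- row
    }
    out <- as_tibble(as.data.frame(p)) %>%
      setNames(paste0("p.", names(BLOSUM62_BG))) %>%
      mutate(position = seq_len(n), aa = cplan$codes, .before = 1)
    class(out) <- c("conservation_profile", class(out))
    out
  })
}

#' Write a conservation profile in PSI-BLAST ASCII PSSM layout
#'
#' @param profile A `conservation_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  aa <- names(BLOSUM62_BG)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", c(aa, aa)), collapse = " "))
  ), con)
  p <- as.matrix(profile[, paste0("p.", aa)])
  for (i in seq_len(nrow(profile))) {
    pct <- round(p[i, ] * 100)
    writeLines(paste0(
      sprintf("%5d %s  ", profile$position[i], profile$aa[i]),
      paste(sprintf("%3d", rep(0L, 20)), collapse = " "), " ",
      paste(sprintf("%3d", pct), collapse = " "),
      sprintf("  %5.2f %9.2f", 0, 0)
    ), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Generate a full synthetic mutation dataset bundle
#'
#' Produces, for every complex of the plan: wild-type structure, conservation
#' profile, and per-mutation mutant structures and wild-type/mutant energy
#' tables; the mutation table carries ddG labels equal to the planted linear
#' effect plus Gaussian noise. The bundle feeds [dataset_features()] and the
#' `run_*()` pipeline directly; `truth` records the planted effects.
#'
#' @param spec A `synthetic_spec`.
#' @param dir Optional directory: when given, all artifacts are also written
#'   as PDB / decomposition-CSV / PSSM / mutation-TSV files.
#' @return A `synthetic_bundle`: list with `spec`, `complexes` (per-complex
#'   structures, profile, tables, mutations) and `truth` tibble.
#' @export
make_dataset <- function(spec, dir = NULL) {
  plan <- dataset_plan(spec)
  complexes <- purrr::map(plan, function(cp) {
    id <- sprintf("TOY%03d", cp$ci)
    cs_wt <- assemble_toy_structure(id, cp$codes, cp$nuc_codes, cp$iface_pos,
                                    cp$ci, spec)
    profile <- make_profile(spec, cp)
    tab_wt <- wt_energy_table(cs_wt, spec, derive_seed(spec, 2, cp$ci))
    muts <- purrr::map(seq_len(nrow(cp$mutations)), function(mi) {
      b <- build_complex_pair(spec, cp, mi, cs_wt = cs_wt)
      tab_mut <- apply_planted_effect(tab_wt, cs_wt, b$target,
                                      cp$mutations$effect[mi])
      list(cs_mut = b$cs_mut, target = b$target, tab_wt = tab_wt,
           tab_mut = tab_mut, row = cp$mutations[mi, ])
    })
    list(id = id, cs_wt = cs_wt, profile = profile, mutations = cp$mutations,
         per_mutation = muts)
  })
  truth <- purrr::map_dfr(complexes, function(cx) {
    cx$mutations %>%
      mutate(complex_id = cx$id, chain = "A", .before = 1)
  }) %>%
    mutate(mutation_id = dplyr::row_number())
  bundle <- structure(
    list(spec = spec, complexes = complexes, truth = truth),
    class = "synthetic_bundle"
  )
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' Write a synthetic bundle to disk in the pipeline's file dialects
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "structures"), showWarnings = FALSE,
             recursive = TRUE)
  dir.create(file.path(dir, "tables"), showWarnings = FALSE)
  dir.create(file.path(dir, "profiles"), showWarnings = FALSE)
  rows <- list()
  for (cx in bundle$complexes) {
    write_structure_pdb(cx$cs_wt,
                        file.path(dir, "structures",
                                  paste0(cx$id, "_wt.pdb")))
    write_pssm(cx$profile, file.path(dir, "profiles", paste0(cx$id, ".pssm")))
    for (mi in seq_along(cx$per_mutation)) {
      pm <- cx$per_mutation[[mi]]
      stem <- paste0(cx$id, "_m", mi)
      write_structure_pdb(pm$cs_mut,
                          file.path(dir, "structures",
                                    paste0(stem, "_mut.pdb")))
      write_energy_csv(pm$tab_wt, cx$cs_wt,
                       file.path(dir, "tables", paste0(stem, "_wt.csv")))
      write_energy_csv(pm$tab_mut, cx$cs_wt,
                       file.path(dir, "tables", paste0(stem, "_mut.csv")))
      rows[[length(rows) + 1]] <- tibble(
        complex_id = cx$id, chain = "A",
        position = pm$row$position, wt = pm$row$wt, mut = pm$row$mut,
        ddg_exp = pm$row$ddg
      )
    }
  }
  readr::write_tsv(bind_rows(rows), file.path(dir, "mutations.tsv"),
                   progress = FALSE)
  invisible(dir)
}

write_energy_csv <- function(tab, cs, path) {
  e <- tab$entries
  mi <- match(e$key_i, cs$monomers$key)
  mj <- match(e$key_j, cs$monomers$key)
  out <- tibble(
    chain_i = cs$monomers$chain[mi], seq_i = cs$monomers$resno[mi],
    icode_i = cs$monomers$icode[mi],
    chain_j = cs$monomers$chain[mj], seq_j = cs$monomers$resno[mj],
    icode_j = cs$monomers$icode[mj]
  ) %>% bind_cols(e[ENERGY_TERMS])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Compute the feature dataset for a synthetic bundle
#'
#' @param bundle A `synthetic_bundle`.
#' @param groups Feature groups to compute (default: the five energy groups;
#'   pass `c(ENERGY_GROUPS, NONENERGY_GROUPS)` names for the full set).
#' @param n_points SASA sphere points (only used for accessibility groups).
#' @param hotspot_threshold Class threshold, kcal/mol.
#' @return A `mutation_dataset`.
#' @export
dataset_features <- function(bundle, groups = ENERGY_GROUPS, n_points = 240,
                             hotspot_threshold = 1) {
  acc_groups <- c("bASA", "uASA", "dASA", "bRSA", "uRSA", "dRSA",
                  "IR-dASA", "IR-dRSA")
  blocks <- list()
  meta <- list()
  for (cx in bundle$complexes) {
    acc_wt <- NULL
    if (any(groups %in% acc_groups)) {
      acc_wt <- accessibility_table(cx$cs_wt, n_points = n_points)
    }
    for (mi in seq_along(cx$per_mutation)) {
      pm <- cx$per_mutation[[mi]]
      blocks[[length(blocks) + 1]] <- compute_mutation_features(
        cs_wt = cx$cs_wt, cs_mut = pm$cs_mut, tab_wt = pm$tab_wt,
        tab_mut = pm$tab_mut, target = pm$target, profile = cx$profile,
        groups = groups, n_points = n_points, acc_wt = acc_wt
      )
      meta[[length(meta) + 1]] <- tibble(
        complex_id = cx$id, chain = "A", position = pm$row$position,
        wt = pm$row$wt, mut = pm$row$mut, ddg_exp = pm$row$ddg
      )
    }
  }
  mutations <- bind_rows(meta) %>% mutate(mutation_id = dplyr::row_number())
  build_dataset(blocks, mutations, hotspot_threshold)
}
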