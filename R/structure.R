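# Reading protein-nucleic-acid complex structures and inter-monomer geometry.
#
# A complex structure is represented as a tidy atom table plus derived monomer
# and chain-type tables. Monomer keys are "chain:resno[icode]" strings using
# author numbering, so "A:52" and "A:52A" are distinct monomers.

#' Build a monomer key from chain, residue number and insertion code
#'
#' @param chain Chain identifier(s).
#' @param resno Author residue number(s).
#' @param icode Insertion code(s), `""` when absent.
#' @return Character vector of keys of the form `"A:52"` or `"A:52A"`.
#' @export
monomer_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resno, icode)
}

aa_kind <- function(resname) {
  dplyr::case_when(
    resname %in% names(AA3) ~ "amino_acid",
    resname %in% names(DNA_RES) ~ "dna_nucleotide",
    resname %in% names(RNA_RES) ~ "rna_nucleotide",
    TRUE ~ NA_character_
  )
}

one_letter_code <- function(resname, kind) {
  dplyr::case_when(
    kind == "amino_acid" ~ unname(AA3[resname]),
    kind == "dna_nucleotide" ~ unname(DNA_RES[resname]),
    kind == "rna_nucleotide" ~ unname(RNA_RES[resname]),
    TRUE ~ NA_character_
  )
}

# backbone/sidechain for protein atoms; phosphate/sugar/nucleobase for nucleic
atom_record_class <- function(atom_name, kind) {
  bb <- c("N", "CA", "C", "O", "OXT")
  phos <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P")
  dplyr::case_when(
    kind == "amino_acid" & atom_name %in% bb ~ "backbone",
    kind == "amino_acid" ~ "sidechain",
    atom_name %in% phos ~ "phosphate",
    grepl("'", atom_name, fixed = TRUE) ~ "sugar",
    TRUE ~ "nucleobase"
  )
}

infer_element <- function(atom_name, elesy = NULL) {
  el <- if (!is.null(elesy)) stringr::str_trim(elesy) else rep("", length(atom_name))
  miss <- is.na(el) | el == ""
  guess <- toupper(substr(gsub("[0-9']", "", atom_name), 1, 1))
  el[miss] <- guess[miss]
  toupper(el)
}

new_complex_structure <- function(id, atoms) {
  atoms <- as_tibble(atoms)
  monomers <- atoms %>%
    distinct(.data$key, .data$chain, .data$resno, .data$icode, .data$resname,
             .data$kind, .data$code)
  chain_types <- monomers %>%
    group_by(.data$chain) %>%
    summarise(kinds = list(unique(.data$kind)), .groups = "drop")
  mixed <- chain_types %>% filter(lengths(.data$kinds) > 1)
  if (nrow(mixed) > 0) {
    abort(paste0("chain(s) with mixed monomer kinds: ",
                 paste(mixed$chain, collapse = ", ")))
  }
  types <- vapply(chain_types$kinds, function(k) {
    switch(k[[1]], amino_acid = "protein", dna_nucleotide = "DNA",
           rna_nucleotide = "RNA")
  }, character(1))
  no_heavy <- atoms %>%
    group_by(.data$key) %>%
    summarise(nh = sum(.data$is_heavy), .groups = "drop") %>%
    filter(.data$nh == 0)
  if (nrow(no_heavy) > 0) {
    abort(paste0("monomer(s) with no heavy atoms: ",
                 paste(no_heavy$key, collapse = ", ")))
  }
  structure(
    list(
      id = id,
      atoms = atoms,
      monomers = monomers,
      chain_types = setNames(types, chain_types$chain)
    ),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure> ", x$id, "\n", sep = "")
  cat("  chains: ",
      paste0(names(x$chain_types), " (", x$chain_types, ")", collapse = ", "),
      "\n", sep = "")
  cat("  ", nrow(x$monomers), " monomers, ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Read a protein-nucleic-acid complex structure from a PDB file
#'
#' Parses the first model of a PDB file, keeps the highest-occupancy alternate
#' conformer per atom, drops all HETATM records (waters, ions, ligands), and
#' types every chain as protein, DNA or RNA from its residue-name vocabulary.
#' Hydrogens are retained but flagged `is_heavy = FALSE`; all geometry
#' downstream uses heavy atoms only.
#'
#' @param path Path to a PDB file.
#' @param id Complex identifier; defaults to the file name without extension.
#' @return A `complex_structure`: a list with an `atoms` tibble (one row per
#'   atom, with monomer `key`, `kind`, `record_class`, coordinates), a
#'   `monomers` tibble and a `chain_types` named vector.
#' @examples
#' pdb <- make_toy_complex(synthetic_spec(seed = 1))
#' cs <- read_structure(pdb$wt_path)
#' cs$chain_types
#' @export
read_structure <- function(path, id = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read PDB file: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) abort(paste0("PDB parse error for ", path, ": ",
                                     conditionMessage(e)))
  )
  at <- as_tibble(pdb$atom)
  at <- at %>% filter(.data$type == "ATOM")
  if (nrow(at) == 0) abort(paste0("no ATOM records in ", path))
  at <- at %>%
    mutate(
      icode = ifelse(is.na(.data$insert) | .data$insert == "", "", .data$insert),
      alt = ifelse(is.na(.data$alt) | .data$alt == "", "", .data$alt),
      o = ifelse(is.na(.data$o), 1, .data$o),
      rowid = dplyr::row_number()
    )
  # altloc: keep highest occupancy per (monomer, atom name); ties -> first seen
  at <- at %>%
    group_by(.data$chain, .data$resno, .data$icode, .data$elety) %>%
    arrange(dplyr::desc(.data$o), .data$rowid, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$rowid)
  kind <- aa_kind(at$resid)
  if (anyNA(kind)) {
    bad <- unique(at$resid[is.na(kind)])
    abort(paste0("unrecognized residue name(s): ", paste(bad, collapse = ", "),
                 " (only standard amino acids and DA/DC/DG/DT vs A/C/G/U are supported)"))
  }
  atoms <- tibble(
    chain = at$chain,
    resno = as.integer(at$resno),
    icode = at$icode,
    resname = at$resid,
    kind = kind,
    code = one_letter_code(at$resid, kind),
    key = monomer_key(at$chain, at$resno, at$icode),
    atom = at$elety,
    element = infer_element(at$elety, at$elesy),
    x = at$x, y = at$y, z = at$z
  ) %>%
    mutate(
      is_heavy = !(.data$element %in% c("H", "D")),
      record_class = atom_record_class(.data$atom, .data$kind)
    )
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort(paste0("non-finite coordinates in ", path))
  }
  new_complex_structure(id %||% tools::file_path_sans_ext(basename(path)), atoms)
}

is_protein_key <- function(cs, key) {
  cs$monomers$kind[match(key, cs$monomers$key)] == "amino_acid"
}

is_nucleic_key <- function(cs, key) {
  cs$monomers$kind[match(key, cs$monomers$key)] %in%
    c("dna_nucleotide", "rna_nucleotide")
}

protein_keys <- function(cs) {
  cs$monomers$key[cs$monomers$kind == "amino_acid"]
}

nucleic_keys <- function(cs) {
  cs$monomers$key[cs$monomers$kind != "amino_acid"]
}

heavy_coords <- function(cs, key) {
  a <- cs$atoms[cs$atoms$key == key & cs$atoms$is_heavy, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Minimum heavy-atom distance between two monomers
#'
#' @param cs A `complex_structure`.
#' @param key_a,key_b Monomer keys (see [monomer_key()]).
#' @return Minimum Euclidean distance in Angstrom over all heavy-atom pairs.
#' @export
min_heavy_distance <- function(cs, key_a, key_b) {
  ca <- heavy_coords(cs, key_a)
  cb <- heavy_coords(cs, key_b)
  if (nrow(ca) == 0 || nrow(cb) == 0) {
    abort("monomer with no heavy atoms")
  }
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * tcrossprod(ca, cb)
  sqrt(max(min(d2), 0))
}

# all-pairs min heavy-atom distance matrix between two key sets (vectorized)
min_distance_table <- function(cs, keys_a, keys_b) {
  ha <- cs$atoms %>% filter(.data$is_heavy, .data$key %in% keys_a)
  hb <- cs$atoms %>% filter(.data$is_heavy, .data$key %in% keys_b)
  ma <- as.matrix(ha[, c("x", "y", "z")])
  mb <- as.matrix(hb[, c("x", "y", "z")])
  d2 <- outer(rowSums(ma^2), rowSums(mb^2), "+") - 2 * tcrossprod(ma, mb)
  d2[d2 < 0] <- 0
  fa <- factor(ha$key)
  fb <- factor(hb$key)
  mins <- tapply(as.vector(d2),
                 list(fa[row(d2)], fb[col(d2)]), min)
  out <- expand.grid(key_a = rownames(mins), key_b = colnames(mins),
                     stringsAsFactors = FALSE)
  out$d <- sqrt(as.vector(mins))
  as_tibble(out[!is.na(out$d), , drop = FALSE])
}

#' Detect the protein-nucleic-acid interface
#'
#' A residue-nucleotide contact is formed when any heavy atom of the residue
#' lies strictly closer than `cutoff` to any heavy atom of the nucleotide.
#' Interface residues/nucleotides are the projections of the contact pairs.
#'
#' @param cs A `complex_structure` with at least one protein and one nucleic
#'   chain.
#' @param cutoff Contact cutoff in Angstrom (default 5, strict `<`).
#' @return An `interface_set`: list with `contact_pairs` tibble
#'   (`residue`, `nucleotide`, `distance`), `interface_residues`,
#'   `interface_nucleotides`, and `cutoff`.
#' @export
detect_interface <- function(cs, cutoff = 5) {
  stopifnot(cutoff > 0)
  pk <- protein_keys(cs)
  nk <- nucleic_keys(cs)
  if (length(nk) == 0) abort("structure has no nucleic-acid chain")
  if (length(pk) == 0) abort("structure has no protein chain")
  dt <- min_distance_table(cs, pk, nk) %>%
    filter(.data$d < cutoff) %>%
    rename(residue = "key_a", nucleotide = "key_b", distance = "d") %>%
    arrange(match(.data$residue, pk), match(.data$nucleotide, nk))
  structure(
    list(
      contact_pairs = dt,
      interface_residues = intersect(pk, dt$residue),
      interface_nucleotides = intersect(nk, dt$nucleotide),
      cutoff = cutoff
    ),
    class = "interface_set"
  )
}

#' @export
print.interface_set <- function(x, ...) {
  cat("<interface_set> cutoff ", x$cutoff, " A: ",
      nrow(x$contact_pairs), " contact pairs, ",
      length(x$interface_residues), " residues, ",
      length(x$interface_nucleotides), " nucleotides\n", sep = "")
  invisible(x)
}

#' Classify residue geometric locations (interior/surface/support/rim/core)
#'
#' Five-class residue location scheme based on relative solvent accessibility
#' in the bound (`bRSA`) and unbound (`uRSA`) states, using a 25% exposure
#' threshold: interior (buried, untouched by binding), surface (exposed,
#' untouched), support (buried, loses area), rim (exposed in both states,
#' loses area), core (exposed unbound, buried bound).
#'
#' @param rsa A data frame with columns `key`, `uRSA`, `bRSA` (percent, total
#'   atom category), one row per residue.
#' @param exposure_cutoff rASA exposure threshold in percent (default 25).
#' @param eps Numerical tolerance on `dRSA = uRSA - bRSA` being zero.
#' @return The input tibble with an added `location` factor column.
#' @export
classify_location <- function(rsa, exposure_cutoff = 25, eps = 1e-6) {
  rsa <- as_tibble(rsa)
  if (!all(c("key", "uRSA", "bRSA") %in% names(rsa))) {
    abort("rsa must have columns key, uRSA, bRSA")
  }
  if (anyNA(rsa$uRSA) || anyNA(rsa$bRSA)) abort("missing RSA values")
  u <- rsa$uRSA
  b <- rsa$bRSA
  d <- u - b
  loc <- dplyr::case_when(
    d <= eps & u < exposure_cutoff ~ "interior",
    d <= eps ~ "surface",
    u < exposure_cutoff ~ "support",
    b < exposure_cutoff ~ "core",
    TRUE ~ "rim"
  )
  rsa %>% mutate(location = factor(loc, levels = c(
    "interior", "surface", "support", "rim", "core"
  )))
}

#' Read a mutation table
#'
#' @param path TSV file with header
#'   `complex_id chain position wt mut ddg_exp`; `ddg_exp` (kcal/mol) optional.
#' @return A tibble of mutation records.
#' @export
read_mutations <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("complex_id", "chain", "position", "wt", "mut")
  if (!all(req %in% names(m))) {
    abort(paste0("mutation table must have columns: ", paste(req, collapse = " ")))
  }
  if (!"ddg_exp" %in% names(m)) m$ddg_exp <- NA_real_
  if (any(m$wt == m$mut)) abort("mutation with wt == mut code")
  m %>% mutate(position = as.integer(.data$position),
               ddg_exp = as.numeric(.data$ddg_exp))
}

#' Validate mutation records against a structure
#'
#' Resolves each record's `(chain, position)` to a monomer of the structure and
#' checks that its one-letter code matches the stated wild-type residue.
#' Records that cannot be matched are rejected with a reason rather than
#' raising, mirroring dataset-curation practice of eliminating unmatched
#' mutations.
#'
#' @param mutations Tibble as returned by [read_mutations()] (rows for one
#'   complex).
#' @param cs The wild-type `complex_structure`.
#' @return The input tibble with added `key`, `bound` (logical) and `reason`
#'   columns; `bound` records have a resolved monomer key.
#' @export
bind_mutation <- function(mutations, cs) {
  mutations <- as_tibble(mutations)
  key <- monomer_key(mutations$chain, mutations$position)
  idx <- match(key, cs$monomers$key)
  found <- !is.na(idx)
  code_ok <- found & cs$monomers$code[idx] == mutations$wt
  is_prot <- found & cs$monomers$kind[idx] == "amino_acid"
  reason <- dplyr::case_when(
    !found ~ "position not found in structure",
    !is_prot ~ "position is not a protein residue",
    !code_ok ~ paste0("wild-type code mismatch: structure has ",
                      cs$monomers$code[idx]),
    TRUE ~ NA_character_
  )
  mutations %>%
    mutate(key = ifelse(found & is_prot & code_ok, key, NA_character_),
           bound = found & is_prot & code_ok,
           reason = reason)
}
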