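# The 17 structural/sequence (nonenergy) feature groups: solvent
# accessibilities (bASA/uASA/dASA/bRSA/uRSA/dRSA over 5 atom categories,
# IR-dASA/IR-dRSA), hydrogen bonds (NHB, IR-NHB), contact features
# (CFAA/CFNA/IR-CFAA/IR-CFNA), knowledge-based interface scores
# (ENDES/IR-ENDES via a pluggable provider), and evolutionary conservation
# (JSD against a background distribution).

# solvent accessibility ---------------------------------------------------

#' Per-residue accessibility table in bound and unbound states
#'
#' Bound-state areas come from the full complex; the unbound state extracts
#' the protein chains in place (no re-minimization), so `dASA = uASA - bASA`
#' is the surface buried by nucleic-acid binding. RSA is the percentage of
#' the residue's isolated-residue reference area per category (glycine's
#' sidechain categories are 0 by convention, not an error).
#'
#' @param cs A `complex_structure`.
#' @param probe,n_points Passed to [sasa()].
#' @return Tibble, one row per protein residue x category with `bASA`, `uASA`,
#'   `dASA` (A^2) and `bRSA`, `uRSA`, `dRSA` (percent).
#' @export
accessibility_table <- function(cs, probe = 1.4, n_points = 960) {
  prot_atoms <- cs$atoms[cs$atoms$kind == "amino_acid", , drop = FALSE]
  b_area <- sasa(cs, probe, n_points)
  bound <- residue_category_asa(cs$atoms, b_area) %>%
    filter(.data$key %in% unique(prot_atoms$key))
  u_area <- sasa(prot_atoms, probe, n_points)
  unbound <- residue_category_asa(prot_atoms, u_area)
  prot_cs <- list(atoms = prot_atoms)
  class(prot_cs) <- "complex_structure"
  ref <- reference_asa(prot_cs, probe, n_points)
  long <- function(d, val) {
    tidyr::pivot_longer(d, all_of(SASA_CATEGORIES),
                        names_to = "category", values_to = val)
  }
  out <- long(bound, "bASA") %>%
    left_join(long(unbound, "uASA"), by = c("key", "category")) %>%
    left_join(long(ref, "refASA"), by = c("key", "category")) %>%
    mutate(
      dASA = .data$uASA - .data$bASA,
      bRSA = ifelse(.data$refASA > 0, .data$bASA / .data$refASA * 100, 0),
      uRSA = ifelse(.data$refASA > 0, .data$uASA / .data$refASA * 100, 0),
      dRSA = .data$uRSA - .data$bRSA
    )
  out
}

#' Accessibility feature groups for one target residue
#'
#' @param acc Accessibility table from [accessibility_table()].
#' @param target Monomer key of the target residue.
#' @param iface An `interface_set` (for the cumulative interface features).
#' @return Named list of eight named numeric vectors: `bASA`, `uASA`, `dASA`,
#'   `bRSA`, `uRSA`, `dRSA` (5 atom categories each, target residue) and
#'   `IR-dASA`, `IR-dRSA` (5 categories, summed over interface residues).
#' @export
accessibility_features <- function(acc, target, iface) {
  tgt <- acc %>% filter(.data$key == target)
  if (nrow(tgt) == 0) abort(paste0("no accessibility rows for ", target))
  grab <- function(d, col) {
    setNames(d[[col]][match(SASA_CATEGORIES, d$category)], SASA_CATEGORIES)
  }
  ir <- acc %>%
    filter(.data$key %in% iface$interface_residues) %>%
    group_by(.data$category) %>%
    summarise(dASA = sum(.data$dASA), dRSA = sum(.data$dRSA), .groups = "drop")
  out <- lapply(c("bASA", "uASA", "dASA", "bRSA", "uRSA", "dRSA"),
                function(col) grab(tgt, col))
  names(out) <- c("bASA", "uASA", "dASA", "bRSA", "uRSA", "dRSA")
  out[["IR-dASA"]] <- grab(ir, "dASA")
  out[["IR-dRSA"]] <- grab(ir, "dRSA")
  out
}

# hydrogen bonds ----------------------------------------------------------

# curated donor/acceptor atom-name tables for standard residues/nucleotides;
# atoms not in the tables fall back to an element rule (N -> donor,
# O -> acceptor), a deliberate geometric approximation that does not require
# hydrogens.
HB_DONOR_NAMES <- c(
  "N", "NE", "NH1", "NH2", "NZ", "ND2", "NE2", "ND1", "NE1", "OG", "OG1",
  "OH", "SG", "N1", "N2", "N3", "N4", "N6", "O2'"
)
HB_ACCEPTOR_NAMES <- c(
  "O", "OXT", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH", "SD", "ND1",
  "NE2", "N1", "N3", "N7", "O2", "O4", "O6", "OP1", "OP2", "O1P", "O2P",
  "O3'", "O5'", "O4'", "O2'"
)

hb_roles <- function(atoms) {
  donor <- atoms$is_heavy &
    (atoms$atom %in% HB_DONOR_NAMES |
       (!atoms$atom %in% HB_ACCEPTOR_NAMES & atoms$element == "N"))
  acceptor <- atoms$is_heavy &
    (atoms$atom %in% HB_ACCEPTOR_NAMES |
       (!atoms$atom %in% HB_DONOR_NAMES & atoms$element == "O"))
  # proline backbone N has no H to donate
  donor[atoms$atom == "N" & atoms$resname == "PRO"] <- FALSE
  list(donor = donor, acceptor = acceptor)
}

# nearest bonded heavy atom (< 1.8 A) in the same monomer, NA when unresolved
antecedent_coords <- function(atoms, idx) {
  a <- atoms[idx, ]
  same <- which(atoms$key == a$key & atoms$is_heavy)
  same <- setdiff(same, idx)
  if (length(same) == 0) return(NULL)
  d <- sqrt((atoms$x[same] - a$x)^2 + (atoms$y[same] - a$y)^2 +
              (atoms$z[same] - a$z)^2)
  ok <- which(d < 1.8)
  if (length(ok) == 0) return(NULL)
  j <- same[ok[which.min(d[ok])]]
  c(atoms$x[j], atoms$y[j], atoms$z[j])
}

#' Count geometric hydrogen bonds between a residue and the rest of a complex
#'
#' Criteria: donor-acceptor heavy-atom distance <= `da_cutoff` and, when the
#' donor's antecedent (nearest covalently bonded heavy atom) is resolvable,
#' antecedent-donor-acceptor angle >= `min_angle` degrees. Hydrogens are not
#' required. Counts bonds in both directions (target donates or accepts).
#'
#' @param cs A `complex_structure`.
#' @param target Monomer key.
#' @param da_cutoff Donor-acceptor cutoff, Angstrom (default 3.5).
#' @param min_angle Minimum antecedent-donor-acceptor angle, degrees.
#' @return Integer bond count (`NHB`).
#' @export
hydrogen_bonds <- function(cs, target, da_cutoff = 3.5, min_angle = 90) {
  atoms <- cs$atoms
  roles <- hb_roles(atoms)
  in_t <- atoms$key == target
  count <- 0L
  pairs <- rbind(
    expand.grid(d = which(roles$donor & in_t),
                a = which(roles$acceptor & !in_t)),
    expand.grid(d = which(roles$donor & !in_t),
                a = which(roles$acceptor & in_t))
  )
  if (nrow(pairs) == 0) return(0L)
  dx <- atoms$x[pairs$a] - atoms$x[pairs$d]
  dy <- atoms$y[pairs$a] - atoms$y[pairs$d]
  dz <- atoms$z[pairs$a] - atoms$z[pairs$d]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  cand <- which(dist <= da_cutoff & dist > 0.1)
  for (p in cand) {
    di <- pairs$d[p]
    ante <- antecedent_coords(atoms, di)
    if (!is.null(ante)) {
      v1 <- ante - c(atoms$x[di], atoms$y[di], atoms$z[di])
      v2 <- c(dx[p], dy[p], dz[p])
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang < min_angle) next
    }
    count <- count + 1L
  }
  count
}

#' @rdname hydrogen_bonds
#' @param iface An `interface_set`.
#' @return `ir_hydrogen_bonds()`: the cumulative bond count over interface
#'   residues (`IR-NHB`).
#' @export
ir_hydrogen_bonds <- function(cs, iface, da_cutoff = 3.5, min_angle = 90) {
  sum(vapply(iface$interface_residues,
             function(k) hydrogen_bonds(cs, k, da_cutoff, min_angle),
             numeric(1)))
}

# contact features --------------------------------------------------------

#' Residue- and atomic-contact features of a target residue
#'
#' Partner monomers are those with >= 1 heavy-atom pair strictly closer than
#' `cutoff` to the target. Each of `CFAA` (amino-acid partners) and `CFNA`
#' (nucleic-acid partners) is a 2-vector: the residue contact strength (count
#' of interacting monomers) and the average atomic contact strength (atomic
#' contact count divided by partner count; 0 when there is no partner).
#'
#' @param cs A `complex_structure`.
#' @param target Monomer key.
#' @param cutoff Heavy-atom contact cutoff, Angstrom (default 5).
#' @return Named list with `CFAA` and `CFNA` 2-vectors
#'   (`n_partners`, `avg_atomic`).
#' @export
contact_features <- function(cs, target, cutoff = 5) {
  atoms <- cs$atoms
  t_at <- atoms[atoms$key == target & atoms$is_heavy, , drop = FALSE]
  o_at <- atoms[atoms$key != target & atoms$is_heavy, , drop = FALSE]
  tm <- as.matrix(t_at[, c("x", "y", "z")])
  om <- as.matrix(o_at[, c("x", "y", "z")])
  d2 <- outer(rowSums(tm^2), rowSums(om^2), "+") - 2 * tcrossprod(tm, om)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  part <- tibble(key = o_at$key[hit[, 2]],
                 kind = o_at$kind[hit[, 2]])
  f <- function(kinds) {
    sel <- part$kind %in% kinds
    np <- length(unique(part$key[sel]))
    nc <- sum(sel)
    c(n_partners = np, avg_atomic = if (np > 0) nc / np else 0)
  }
  list(CFAA = f("amino_acid"),
       CFNA = f(c("dna_nucleotide", "rna_nucleotide")))
}

#' Cumulative contact features over interface residues
#'
#' @inheritParams contact_features
#' @param iface An `interface_set`.
#' @return Named list with `IR-CFAA` and `IR-CFNA` 2-vectors (component-wise
#'   sums of per-residue [contact_features()] over interface residues).
#' @export
ir_contact_features <- function(cs, iface, cutoff = 5) {
  acc <- list(`IR-CFAA` = c(n_partners = 0, avg_atomic = 0),
              `IR-CFNA` = c(n_partners = 0, avg_atomic = 0))
  for (k in iface$interface_residues) {
    cf <- contact_features(cs, k, cutoff)
    acc[["IR-CFAA"]] <- acc[["IR-CFAA"]] + cf$CFAA
    acc[["IR-CFNA"]] <- acc[["IR-CFNA"]] + cf$CFNA
  }
  acc
}

# conservation ------------------------------------------------------------

#' Read a PSI-BLAST ASCII PSSM (weighted observed percentages)
#'
#' Parses the standard ASCII PSSM layout and extracts the 20 weighted observed
#' percentage columns, normalized to probability rows; all-zero rows are
#' replaced by the background distribution.
#'
#' @param path PSSM file path.
#' @param background Background amino-acid distribution (named, one-letter).
#' @return A `conservation_profile`: tibble with `position`, `aa` and a 20-col
#'   probability matrix in list-column `p` replaced by columns `p.A` .. `p.V`.
#' @export
read_pssm <- function(path, background = BLOSUM62_BG) {
  lines <- readLines(path)
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D", lines)[1]
  if (is.na(hdr)) abort(paste0("not a PSI-BLAST ASCII PSSM: ", path))
  aa_order <- strsplit(stringr::str_squish(lines[hdr]), " ")[[1]][1:20]
  body <- lines[(hdr + 1):length(lines)]
  body <- body[grepl("^\\s*\\d+\\s+[A-Z]", body)]
  rows <- lapply(body, function(l) strsplit(stringr::str_squish(l), " ")[[1]])
  pos <- vapply(rows, function(r) as.integer(r[1]), integer(1))
  aa <- vapply(rows, function(r) r[2], character(1))
  pct <- t(vapply(rows, function(r) as.numeric(r[23:42]), numeric(20)))
  colnames(pct) <- aa_order
  pct <- pct[, names(background), drop = FALSE]
  p <- pct / 100
  zero <- rowSums(p) <= 0
  p[zero, ] <- matrix(rep(background / sum(background), sum(zero)),
                      ncol = 20, byrow = TRUE)
  p <- p / rowSums(p)
  out <- as_tibble(as.data.frame(p)) %>%
    setNames(paste0("p.", names(background))) %>%
    mutate(position = pos, aa = aa, .before = 1)
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Jensen-Shannon divergence conservation score
#'
#' JSD between a position's amino-acid distribution and a background
#' distribution, mixture weight 1/2, log base 2, so the score is bounded in
#' \[0, 1\]; higher means more conserved (further from background).
#'
#' @param profile A `conservation_profile` from [read_pssm()] (or any tibble
#'   with `position` and `p.*` columns).
#' @param position Profile position (1-based).
#' @param background Background distribution (named, sums to 1).
#' @return JSD score in \[0, 1\].
#' @export
jsd_conservation <- function(profile, position, background = BLOSUM62_BG) {
  row <- profile[profile$position == position, , drop = FALSE]
  if (nrow(row) == 0) abort(paste0("position ", position, " not in profile"))
  p <- as.numeric(row[1, paste0("p.", names(background))])
  q <- as.numeric(background / sum(background))
  jsd_divergence(p, q)
}

jsd_divergence <- function(p, q) {
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    sel <- a > 0
    sum(a[sel] * log2(a[sel] / b[sel]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# knowledge-based interface scores (pluggable provider) --------------------

the_endes_provider <- new.env(parent = emptyenv())

#' Register or retrieve the knowledge-based interface score provider
#'
#' The provider is a function `(cs, target, iface, profile)` returning a
#' numeric 7-vector of knowledge-based scores per residue. The built-in
#' default implements three scores (sidechain burial, residue-type interface
#' propensity, conservation) and zero-fills the remaining four; external
#' providers may supply all seven.
#'
#' @param provider A provider function, or `NULL` to reset to the default.
#' @return The active provider (invisibly for the setter).
#' @export
set_endes_provider <- function(provider = NULL) {
  the_endes_provider$fn <- provider %||% default_endes_provider
  invisible(the_endes_provider$fn)
}

get_endes_provider <- function() {
  if (is.null(the_endes_provider$fn)) the_endes_provider$fn <- default_endes_provider
  the_endes_provider$fn
}

# residue-type nucleic-acid interface propensities (positively charged and
# aromatic residues favored); package-defined constants on a log-odds-like
# scale
ENDES_PROPENSITY <- c(
  A = -0.20, R = 1.00, N = 0.30, D = -0.60, C = -0.30, Q = 0.20, E = -0.70,
  G = 0.10, H = 0.55, I = -0.40, L = -0.45, K = 0.85, M = -0.25, F = 0.05,
  P = -0.15, S = 0.25, T = 0.20, W = 0.15, Y = 0.45, V = -0.35
)

#' @rdname set_endes_provider
#' @param cs A `complex_structure`.
#' @param target Monomer key.
#' @param iface An `interface_set`.
#' @param profile Optional `conservation_profile` (position = `resno`).
#' @export
default_endes_provider <- function(cs, target, iface, profile = NULL) {
  atoms <- cs$atoms[cs$atoms$key == target & cs$atoms$is_heavy, , drop = FALSE]
  side <- atoms$record_class == "sidechain"
  # sidechain score: fraction of sidechain heavy atoms contacting nucleic acid
  nuc <- cs$atoms[cs$atoms$kind != "amino_acid" & cs$atoms$is_heavy, ,
                  drop = FALSE]
  sc_score <- 0
  if (any(side) && nrow(nuc) > 0) {
    sm <- as.matrix(atoms[side, c("x", "y", "z")])
    nm <- as.matrix(nuc[, c("x", "y", "z")])
    d2 <- outer(rowSums(sm^2), rowSums(nm^2), "+") - 2 * tcrossprod(sm, nm)
    sc_score <- mean(apply(d2, 1, min) < 25)
  }
  code <- cs$monomers$code[match(target, cs$monomers$key)]
  prop <- unname(ENDES_PROPENSITY[code])
  if (is.na(prop)) prop <- 0
  cons <- 0
  if (!is.null(profile)) {
    resno <- cs$monomers$resno[match(target, cs$monomers$key)]
    if (resno %in% profile$position) {
      cons <- jsd_conservation(profile, resno)
    }
  }
  c(sidechain = sc_score, propensity = prop, conservation = cons,
    reserved1 = 0, reserved2 = 0, reserved3 = 0, reserved4 = 0)
}

#' Knowledge-based interface score features
#'
#' @inheritParams default_endes_provider
#' @return Named list with `ENDES` (7-vector for the target) and `IR-ENDES`
#'   (component-wise sum over interface residues).
#' @export
endes_scores <- function(cs, target, iface, profile = NULL) {
  provider <- get_endes_provider()
  if (is.null(provider)) {
    abort("no interface-score provider registered; see set_endes_provider()")
  }
  check <- function(v) {
    if (!is.numeric(v) || length(v) != 7) {
      abort("interface-score provider must return a numeric 7-vector")
    }
    v
  }
  tgt <- check(provider(cs, target, iface, profile))
  ir <- setNames(numeric(7), names(tgt))
  for (k in iface$interface_residues) {
    ir <- ir + check(provider(cs, k, iface, profile))
  }
  list(ENDES = tgt, `IR-ENDES` = ir)
}
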