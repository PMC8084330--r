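# Shrake-Rupley solvent-accessible surface area.
#
# Deterministic sphere-point sampling (golden-section spiral), probe 1.4 A,
# 960 points by default. Heavy atoms only; hydrogens are ignored. Van der
# Waals radii follow the Chothia-style values used by classic accessibility
# programs.

VDW_RADII <- c(C = 1.76, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# deterministic unit-sphere point set (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' @param cs A `complex_structure`, or any data frame with columns `x`, `y`,
#'   `z`, `element`, `is_heavy`.
#' @param probe Probe radius, Angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 960). Output is
#'   deterministic for a fixed `n_points`.
#' @return Numeric vector of accessible areas (A^2), one per heavy atom, in
#'   atom order (hydrogens receive `NA`). For a `complex_structure` the
#'   vector is named by atom row.
#' @export
sasa <- function(cs, probe = 1.4, n_points = 960) {
  atoms <- if (inherits(cs, "complex_structure")) cs$atoms else as_tibble(cs)
  heavy <- atoms[atoms$is_heavy, , drop = FALSE]
  el <- heavy$element
  unknown <- setdiff(unique(el), names(VDW_RADII))
  if (length(unknown) > 0) {
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(unknown, collapse = ", ")))
  }
  r <- unname(VDW_RADII[el]) + probe
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  if (n == 1) {
    area[1] <- 4 * pi * r[1]^2
  } else {
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
    for (i in seq_len(n)) {
      # neighbors whose expanded spheres can occlude atom i's test sphere
      nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
      if (length(nb) == 0) {
        area[i] <- 4 * pi * r[i]^2
        next
      }
      p <- pts * r[i]
      p <- sweep(p, 2, xyz[i, ], "+")
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        free <- free & dj >= r[j]^2
        if (!any(free)) break
      }
      area[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
    }
  }
  out <- rep(NA_real_, nrow(atoms))
  out[atoms$is_heavy] <- area
  out
}

atom_category_flags <- function(atoms) {
  side <- atoms$record_class == "sidechain"
  polar <- atoms$element %in% c("N", "O", "S", "P")
  cbind(
    total = rep(TRUE, nrow(atoms)),
    mainchain = !side,
    sidechain = side,
    polar_sidechain = side & polar,
    nonpolar_sidechain = side & !polar
  )
}

# per-residue ASA by atom category for a structure (heavy atoms)
residue_category_asa <- function(atoms, areas) {
  flags <- atom_category_flags(atoms)
  a <- ifelse(is.na(areas), 0, areas)
  d <- as_tibble(flags * a) %>%
    mutate(key = atoms$key) %>%
    group_by(.data$key) %>%
    summarise(across(all_of(SASA_CATEGORIES), sum), .groups = "drop")
  d[match(unique(atoms$key), d$key), ]
}

# reference ASA per residue: area of the residue's atoms in isolation.
# Self-consistent for both real residues and pseudo-atom toy residues.
reference_asa <- function(cs, probe = 1.4, n_points = 960) {
  keys <- unique(cs$atoms$key)
  purrr::map_dfr(keys, function(k) {
    a <- cs$atoms[cs$atoms$key == k, , drop = FALSE]
    ar <- sasa(a, probe = probe, n_points = n_points)
    residue_category_asa(a, ar)
  })
}
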