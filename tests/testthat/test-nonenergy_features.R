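# Solvent accessibility, hydrogen bonds, contact features, conservation, and
# the pluggable knowledge-based score provider.

test_that("an isolated atom's area matches the analytic sphere", {
  a <- tibble::tibble(x = 0, y = 0, z = 0, element = "C", is_heavy = TRUE)
  area <- sasa(a)
  r <- pnimut:::VDW_RADII[["C"]] + 1.4
  expect_equal(area, 4 * pi * r^2, tolerance = 0.01)
})

test_that("two-sphere areas match the spherical-cap closed form", {
  d <- 2.0
  a <- tibble::tibble(x = c(0, d), y = 0, z = 0, element = c("C", "O"),
                      is_heavy = TRUE)
  got <- sasa(a, n_points = 2000)
  r1 <- pnimut:::VDW_RADII[["C"]] + 1.4
  r2 <- pnimut:::VDW_RADII[["O"]] + 1.4
  # cap height of sphere 1 buried inside sphere 2
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  expect_equal(got[1], 4 * pi * r1^2 - 2 * pi * r1 * h1, tolerance = 0.01)
  expect_equal(got[2], 4 * pi * r2^2 - 2 * pi * r2 * h2, tolerance = 0.01)
})

test_that("a caged atom is fully buried and output is deterministic", {
  shell <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  shell <- shell[!(shell$x == 0 & shell$y == 0 & shell$z == 0), ]
  a <- tibble::tibble(x = c(0, shell$x), y = c(0, shell$y),
                      z = c(0, shell$z), element = "C", is_heavy = TRUE)
  area <- sasa(a)
  expect_equal(area[1], 0)
  expect_identical(sasa(a), sasa(a))
  expect_error(sasa(tibble::tibble(x = 0, y = 0, z = 0, element = "XX",
                                   is_heavy = TRUE)), "radius")
})

toy_bundle_small <- function(seed = 7) {
  spec <- synthetic_spec(seed = seed, n_complexes = 1,
                         mutations_per_complex = 1, n_residues = 8)
  make_dataset(spec)
}

test_that("binding only buries surface: dASA >= 0, far residues unchanged", {
  b <- toy_bundle_small()
  cs <- b$complexes[[1]]$cs_wt
  acc <- accessibility_table(cs, n_points = 240)
  expect_true(all(acc$dASA >= -1e-9))
  ifc <- detect_interface(cs)
  far <- setdiff(unique(acc$key), ifc$interface_residues)
  far_rows <- acc[acc$key %in% far, ]
  expect_true(all(abs(far_rows$dASA) < 1e-9))
  # interface residues do lose area
  buried <- acc[acc$key %in% ifc$interface_residues &
                  acc$category == "total", ]
  expect_true(all(buried$dASA > 0))
})

test_that("cumulative interface accessibility features are exact sums", {
  b <- toy_bundle_small()
  cs <- b$complexes[[1]]$cs_wt
  ifc <- detect_interface(cs)
  acc <- accessibility_table(cs, n_points = 240)
  target <- ifc$interface_residues[1]
  f <- accessibility_features(acc, target, ifc)
  manual <- acc[acc$key %in% ifc$interface_residues &
                  acc$category == "total", ]
  expect_equal(unname(f[["IR-dASA"]][["total"]]), sum(manual$dASA))
  expect_equal(unname(f[["IR-dRSA"]][["total"]]), sum(manual$dRSA))
  expect_length(f$bASA, 5)
  expect_equal(unname(f$dASA),
               unname(f$uASA - f$bASA))
})

test_that("an ideal donor-acceptor geometry counts as one hydrogen bond", {
  # N donor with antecedent C; acceptor O at 2.9 A, angle ~160 degrees
  ang <- 160 * pi / 180
  cs <- micro_structure(list(
    list(key = "A:1", kind = "amino_acid", code = "A",
         atoms = atomdf(c("CA", "N"), c("C", "N"),
                        c(-1.4, 0), c(0, 0), c(0, 0))),
    list(key = "B:1", kind = "dna_nucleotide", code = "A",
         atoms = atomdf("O2", "O", 2.9 * cos(pi - ang), 2.9 * sin(pi - ang),
                        0))
  ))
  expect_equal(hydrogen_bonds(cs, "A:1"), 1L)
  # same geometry at 4.5 A: beyond cutoff
  cs_far <- micro_structure(list(
    list(key = "A:1", kind = "amino_acid", code = "A",
         atoms = atomdf(c("CA", "N"), c("C", "N"), c(-1.4, 0), c(0, 0),
                        c(0, 0))),
    list(key = "B:1", kind = "dna_nucleotide", code = "A",
         atoms = atomdf("O2", "O", 4.5 * cos(pi - ang), 4.5 * sin(pi - ang),
                        0))
  ))
  expect_equal(hydrogen_bonds(cs_far, "A:1"), 0L)
  # a bad antecedent-donor-acceptor angle (acceptor behind the donor) fails
  cs_bad <- micro_structure(list(
    list(key = "A:1", kind = "amino_acid", code = "A",
         atoms = atomdf(c("CA", "N"), c("C", "N"), c(-1.4, 0), c(0, 0),
                        c(0, 0))),
    list(key = "B:1", kind = "dna_nucleotide", code = "A",
         atoms = atomdf("O2", "O", -2.9, 0.3, 0))
  ))
  expect_equal(hydrogen_bonds(cs_bad, "A:1"), 0L)
})

test_that("hydrogen-bond counts match an independent donor-acceptor scan", {
  b <- toy_bundle_small(seed = 11)
  cs <- b$complexes[[1]]$cs_wt
  ifc <- detect_interface(cs)
  # independent re-derivation with plain loops
  oracle_nhb <- function(cs, target) {
    atoms <- cs$atoms
    roles <- pnimut:::hb_roles(atoms)
    n <- 0L
    for (di in which(roles$donor)) {
      for (ai in which(roles$acceptor)) {
        t_d <- atoms$key[di] == target
        t_a <- atoms$key[ai] == target
        if (t_d == t_a) next
        dd <- sqrt((atoms$x[di] - atoms$x[ai])^2 +
                     (atoms$y[di] - atoms$y[ai])^2 +
                     (atoms$z[di] - atoms$z[ai])^2)
        if (dd > 3.5 || dd <= 0.1) next
        ante <- pnimut:::antecedent_coords(atoms, di)
        if (!is.null(ante)) {
          v1 <- ante - c(atoms$x[di], atoms$y[di], atoms$z[di])
          v2 <- c(atoms$x[ai], atoms$y[ai], atoms$z[ai]) -
            c(atoms$x[di], atoms$y[di], atoms$z[di])
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          if (acos(max(min(cosang, 1), -1)) * 180 / pi < 90) next
        }
        n <- n + 1L
      }
    }
    n
  }
  for (k in c(ifc$interface_residues[1], "A:1")) {
    expect_equal(hydrogen_bonds(cs, k), oracle_nhb(cs, k))
  }
  expect_equal(ir_hydrogen_bonds(cs, ifc),
               sum(vapply(ifc$interface_residues,
                          function(k) oracle_nhb(cs, k), numeric(1))))
})

test_that("contact strengths are counts and averages over partners", {
  cs <- micro_structure(list(
    list(key = "A:1", kind = "amino_acid", code = "A",
         atoms = atomdf(c("CA", "CB1"), "C", c(0, 1), 0, 0)),
    mono1("A:2", 3, 0, 0),     # partner 1
    mono1("A:3", 0, 4, 0),     # partner 2
    mono1("A:4", 20, 0, 0),    # out of range
    mono1("B:1", 40, 0, 0, kind = "dna_nucleotide")
  ))
  cf <- contact_features(cs, "A:1")
  # A:2 contacts both target atoms (3 and 2 A); A:3 contacts CA (4 A) and
  # CB1 (sqrt(17) > 4 but < 5): count atomic pairs under 5 A
  expect_equal(unname(cf$CFAA[["n_partners"]]), 2)
  expect_equal(unname(cf$CFNA), c(0, 0))
  # brute-force equality on a random toy complex
  b <- toy_bundle_small(seed = 13)
  cs2 <- b$complexes[[1]]$cs_wt
  ifc <- detect_interface(cs2)
  tgt <- ifc$interface_residues[2]
  atoms <- cs2$atoms
  t_at <- atoms[atoms$key == tgt, ]
  counts <- list(amino_acid = c(0, 0), nucleic = c(0, 0))
  for (kind in c("amino_acid", "nucleic")) {
    sel <- if (kind == "amino_acid") atoms$kind == "amino_acid" else
      atoms$kind != "amino_acid"
    o_at <- atoms[sel & atoms$key != tgt, ]
    nc <- 0; partners <- character()
    for (i in seq_len(nrow(t_at))) {
      for (j in seq_len(nrow(o_at))) {
        d <- sqrt((t_at$x[i] - o_at$x[j])^2 + (t_at$y[i] - o_at$y[j])^2 +
                    (t_at$z[i] - o_at$z[j])^2)
        if (d < 5) { nc <- nc + 1; partners <- c(partners, o_at$key[j]) }
      }
    }
    np <- length(unique(partners))
    counts[[kind]] <- c(np, if (np > 0) nc / np else 0)
  }
  cf2 <- contact_features(cs2, tgt)
  expect_equal(unname(cf2$CFAA), counts$amino_acid)
  expect_equal(unname(cf2$CFNA), counts$nucleic)
  # interface cumulants are exact sums
  ircf <- ir_contact_features(cs2, ifc)
  manual <- Reduce(`+`, lapply(ifc$interface_residues, function(k) {
    unlist(contact_features(cs2, k))
  }))
  expect_equal(unname(unlist(ircf)), unname(manual))
})

test_that("conservation scores follow the divergence formula and bounds", {
  bg <- pnimut:::BLOSUM62_BG
  prof <- tibble::as_tibble(as.list(setNames(bg / sum(bg),
                                             paste0("p.", names(bg))))) |>
    dplyr::mutate(position = 1L, aa = "A", .before = 1)
  expect_equal(jsd_conservation(prof, 1), 0, tolerance = 1e-12)
  # delta distribution against uniform background: direct formula
  p <- c(1, rep(0, 19))
  q <- rep(1 / 20, 20)
  m <- (p + q) / 2
  hand <- 0.5 * sum(p[p > 0] * log2(p[p > 0] / m[p > 0])) +
    0.5 * sum(q * log2(q / m))
  prof2 <- prof
  prof2[1, paste0("p.", names(bg))] <- as.list(p)
  expect_equal(jsd_conservation(prof2, 1, background = setNames(q, names(bg))),
               hand)
  set.seed(1)
  for (i in 1:200) {
    r <- stats::rgamma(20, 0.3); r <- r / sum(r)
    v <- pnimut:::jsd_divergence(r, unname(bg))
    expect_true(v >= 0 && v <= 1)
  }
  expect_error(jsd_conservation(prof, 99), "not in profile")
})

test_that("synthetic profiles survive the PSSM round trip", {
  spec <- synthetic_spec(seed = 3, n_complexes = 1, n_residues = 8)
  b <- make_dataset(spec)
  prof <- b$complexes[[1]]$profile
  path <- tempfile(fileext = ".pssm")
  write_pssm(prof, path)
  back <- read_pssm(path)
  expect_equal(nrow(back), nrow(prof))
  p <- as.matrix(back[, paste0("p.", names(pnimut:::BLOSUM62_BG))])
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)))
  # percentages are rounded to integers on disk
  expect_equal(p, as.matrix(prof[, colnames(p)]), tolerance = 0.05)
})

test_that("all-zero profile rows fall back to the background", {
  aa <- names(pnimut:::BLOSUM62_BG)
  path <- tempfile(fileext = ".pssm")
  writeLines(c(
    "", "header", paste0("           ", paste(sprintf("%3s", c(aa, aa)),
                                              collapse = " ")),
    paste0("    1 A  ", paste(sprintf("%3d", rep(0, 40)), collapse = " "),
           "  0.00      0.00"),
    ""
  ), path)
  prof <- read_pssm(path)
  expect_equal(as.numeric(prof[1, paste0("p.", aa)]),
               unname(pnimut:::BLOSUM62_BG), tolerance = 1e-9)
})

test_that("the score provider contract is enforced and sums over interfaces", {
  b <- toy_bundle_small(seed = 17)
  cs <- b$complexes[[1]]$cs_wt
  prof <- b$complexes[[1]]$profile
  ifc <- detect_interface(cs)
  tgt <- ifc$interface_residues[1]
  es <- endes_scores(cs, tgt, ifc, prof)
  expect_length(es$ENDES, 7)
  manual <- Reduce(`+`, lapply(ifc$interface_residues, function(k) {
    pnimut:::default_endes_provider(cs, k, ifc, prof)
  }))
  expect_equal(es[["IR-ENDES"]], manual)
  # zero-fill provider keeps the pipeline running
  set_endes_provider(function(cs, target, iface, profile) numeric(7))
  on.exit(set_endes_provider(NULL), add = TRUE)
  es0 <- endes_scores(cs, tgt, ifc, prof)
  expect_equal(unname(es0$ENDES), rep(0, 7))
  # wrong length breaks the contract
  set_endes_provider(function(cs, target, iface, profile) numeric(3))
  expect_error(endes_scores(cs, tgt, ifc, prof), "7-vector")
})

test_that("difference blocks vanish when mutant equals wild type", {
  b <- toy_bundle_small(seed = 19)
  cx <- b$complexes[[1]]
  pm <- cx$per_mutation[[1]]
  f <- compute_mutation_features(
    cs_wt = cx$cs_wt, cs_mut = cx$cs_wt, tab_wt = pm$tab_wt,
    tab_mut = pm$tab_wt, target = pm$target, profile = cx$profile,
    groups = c("EWC", "NHB", "CFAA", "JSD", "ENDES"), n_points = 120
  )
  for (g in names(f)) {
    d <- f[[g]][grepl("\\.diff\\.", names(f[[g]]))]
    expect_equal(unname(d), rep(0, length(d)), info = g)
  }
})
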