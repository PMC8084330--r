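# Pair-energy table reading and the five partition-based energy feature
# groups, with conservation, permutation and linearity properties.

# micro complex: 3 protein residues on a line, 1 nucleotide nearby
micro3p1n <- function() {
  micro_structure(list(
    mono1("A:1", 0, 0, 0),
    mono1("A:2", 2.5, 0, 0),
    mono1("A:3", 8, 0, 0),
    mono1("B:1", 0, 4, 0, kind = "dna_nucleotide")
  ))
}

test_that("decomposition tables canonicalize pairs and sum directions", {
  cs <- micro3p1n()
  keys <- cs$monomers$key
  ent <- micro_entries(keys, off = dplyr::bind_rows(
    entry_row("A:2", "A:1", 0.5),
    entry_row("A:1", "A:2", 0.5)
  ))
  tab <- pair_energy_table(ent, cs)
  expect_equal(nrow(tab$entries), 5)  # 4 selves + 1 merged pair
  expect_equal(pnimut:::pairwise_energy(tab, "A:1", "A:2")[["total"]], 1.0)
  # csv round trip with split directions
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    chain_i = c("A", "A", "A", "A", "B", "A"),
    seq_i = c(1L, 2L, 3L, 2L, 1L, 1L), icode_i = "",
    chain_j = c("A", "A", "A", "A", "B", "A"),
    seq_j = c(1L, 2L, 3L, 1L, 1L, 2L), icode_j = "",
    total = c(0, 0, 0, 0.5, 0, 0.5), ele = c(0, 0, 0, 0.5, 0, 0.5),
    vdw = 0, gb = 0, sa = 0
  ), path)
  tab2 <- read_pair_energy_table(path, cs)
  expect_equal(tab2$entries, tab$entries)
})

test_that("unresolvable keys and missing self entries are rejected", {
  cs <- micro3p1n()
  keys <- cs$monomers$key
  bad <- micro_entries(keys, off = entry_row("Z:9", "A:1", 1))
  expect_error(pair_energy_table(bad, cs), "Z:9")
  expect_error(pair_energy_table(micro_entries(keys[-1]), cs), "self")
  off_closure <- micro_entries(keys)
  off_closure$total[1] <- 5
  expect_error(pair_energy_table(off_closure, cs), "closure")
})

test_that("whole-complex energies are the term-wise sum of all entries", {
  cs <- micro3p1n()
  keys <- cs$monomers$key
  ent <- micro_entries(keys, self_total = 0)
  ent$total <- c(1.0, -2.0, 0.5, 0)
  ent$ele <- ent$total
  tab <- pair_energy_table(ent, cs)
  expect_equal(ewc(tab)[["total"]], -0.5)
  zero <- pair_energy_table(micro_entries(keys), cs)
  expect_equal(unname(ewc(zero)), rep(0, 5))
  # brute-force double loop on a random 30-monomer table
  cloud <- random_cloud(30, seed = 3)
  cs2 <- micro_structure(cloud)
  tab2 <- pair_energy_table(random_entries(cs2$monomers$key, seed = 4), cs2)
  brute <- colSums(tab2$entries[, pnimut:::ENERGY_TERMS])
  expect_equal(ewc(tab2), brute)
})

test_that("target shell energies place neighbors by distance convention", {
  cs <- micro3p1n()
  keys <- cs$monomers$key
  # A:2 at 2.5 A (shell 0-3), A:3 at 8 A (shell >6) from A:1
  ent <- micro_entries(keys, off = dplyr::bind_rows(
    entry_row("A:1", "A:3", -1.0)
  ))
  ent$total[ent$key_i == "A:1" & ent$key_j == "A:1"] <- 2.0
  ent$ele[ent$key_i == "A:1" & ent$key_j == "A:1"] <- 2.0
  tab <- pair_energy_table(ent, cs)
  sh <- etor(tab, cs, "A:1")
  expect_equal(unname(sh[, "total"]), c(2, 0, 0, 0, 0, -1))
  # residue at exactly 3.0 A falls into the (0,3] shell
  cs3 <- micro_structure(list(mono1("A:1", 0, 0, 0), mono1("A:2", 3, 0, 0),
                              mono1("B:1", 0, 5.5, 0,
                                    kind = "dna_nucleotide")))
  t3 <- pair_energy_table(
    micro_entries(cs3$monomers$key, off = entry_row("A:1", "A:2", 1)), cs3)
  expect_equal(etor(t3, cs3, "A:1")["0-3", "total"], 1)
  expect_error(etor(tab, cs, "B:1"), "not a protein")
})

test_that("shell sums conserve the target's pair energies with the protein", {
  cloud <- random_cloud(20, seed = 5)
  cs <- micro_structure(cloud)
  tab <- pair_energy_table(random_entries(cs$monomers$key, seed = 6), cs)
  target <- cs$monomers$key[1]
  sh <- etor(tab, cs, target)
  pk <- cs$monomers$key[cs$monomers$kind == "amino_acid"]
  expected <- pnimut:::pairwise_energy(tab, target, target)
  for (o in setdiff(pk, target)) {
    expected <- expected + pnimut:::pairwise_energy(tab, target, o)
  }
  expect_equal(colSums(sh), expected, tolerance = 1e-12)
})

test_that("residue energies obey the diagonal/off-diagonal identity", {
  cs <- micro3p1n()
  keys <- cs$monomers$key
  ent <- micro_entries(keys, off = dplyr::bind_rows(
    entry_row("A:1", "A:2", 0.5), entry_row("A:1", "B:1", -0.25)
  ))
  ent$total[1] <- 1; ent$ele[1] <- 1
  tab <- pair_energy_table(ent, cs)
  expect_equal(residue_energy(tab, "A:1")[["total"]], 1.25)
  expect_equal(residue_energy(tab, "A:3")[["total"]], 0)
  # sum over residue energies counts pairs twice: sum_res = ewc + offdiag
  cloud <- random_cloud(16, seed = 9)
  cs2 <- micro_structure(cloud)
  tab2 <- pair_energy_table(random_entries(cs2$monomers$key, seed = 10), cs2)
  tot <- Reduce(`+`, lapply(cs2$monomers$key,
                            function(k) residue_energy(tab2, k)))
  off <- tab2$entries[tab2$entries$key_i != tab2$entries$key_j, ]
  expect_equal(tot, ewc(tab2) + colSums(off[, pnimut:::ENERGY_TERMS]),
               tolerance = 1e-12)
})

test_that("partitioned-protein sums conserve and track residue moves", {
  cloud <- random_cloud(14, seed = 12)
  cs <- micro_structure(cloud)
  tab <- pair_energy_table(random_entries(cs$monomers$key, seed = 13), cs)
  target <- cs$monomers$key[2]
  shp <- epp(tab, cs, target)
  expect_equal(shp["self", ], residue_energy(tab, target))
  pk <- cs$monomers$key[cs$monomers$kind == "amino_acid"]
  tot <- Reduce(`+`, lapply(pk, function(k) residue_energy(tab, k)))
  expect_equal(colSums(shp), tot, tolerance = 1e-12)
  # moving a residue between shells relocates, not changes, the total
  cs_a <- micro_structure(list(mono1("A:1", 0, 0, 0),
                               mono1("A:2", 3.5, 0, 0),
                               mono1("B:1", 0, 9, 0,
                                     kind = "dna_nucleotide")))
  cs_b <- micro_structure(list(mono1("A:1", 0, 0, 0),
                               mono1("A:2", 4.5, 0, 0),
                               mono1("B:1", 0, 9, 0,
                                     kind = "dna_nucleotide")))
  ent <- micro_entries(cs_a$monomers$key, off = entry_row("A:1", "A:2", 2))
  ta <- pair_energy_table(ent, cs_a)
  pa <- epp(ta, cs_a, "A:1")
  pb <- epp(ta, cs_b, "A:1")
  expect_equal(pa["3-4", "total"], pb["4-5", "total"])
  expect_equal(pa["4-5", "total"], 0)
  expect_equal(colSums(pa), colSums(pb))
})

test_that("interface/noninterface sums split the whole-complex energy", {
  cs <- micro3p1n()  # A:1 within 4 A of B:1; A:2 at 4.7; A:3 far
  ifc <- detect_interface(cs)
  tab <- pair_energy_table(random_entries(cs$monomers$key, seed = 20), cs)
  m <- eini(tab, ifc)
  expect_equal(m["interface", ] + m["noninterface", ], ewc(tab),
               tolerance = 1e-12)
  # a pair straddling the interface boundary counts as noninterface
  member <- c(ifc$interface_residues, ifc$interface_nucleotides)
  expect_true("A:3" %in% setdiff(cs$monomers$key, member))
  e2 <- micro_entries(cs$monomers$key,
                      off = entry_row(ifc$interface_residues[1], "A:3", 7))
  t2 <- pair_energy_table(e2, cs)
  m2 <- eini(t2, ifc)
  expect_equal(m2["noninterface", "total"], 7)
  # degenerate: everything interfacial
  all_if <- list(interface_residues = cs$monomers$key[1:3],
                 interface_nucleotides = "B:1")
  m3 <- eini(tab, structure(c(all_if, list(cutoff = 5)),
                            class = "interface_set"))
  expect_equal(m3["interface", ], ewc(tab))
  expect_equal(unname(m3["noninterface", ]), rep(0, 5))
})

test_that("interface pair types sum to the interface partition", {
  cs <- micro_structure(list(
    mono1("A:1", 0, 0, 0),
    mono1("B:1", 0, 3, 0, kind = "dna_nucleotide"),
    mono1("A:9", 30, 0, 0)
  ))
  ifc <- detect_interface(cs)
  ent <- micro_entries(cs$monomers$key, off = entry_row("A:1", "B:1", -3))
  ent$total[ent$key_i == "A:1" & ent$key_j == "A:1"] <- 1
  ent$ele[ent$key_i == "A:1" & ent$key_j == "A:1"] <- 1
  ent$total[ent$key_i == "B:1" & ent$key_j == "B:1"] <- 2
  ent$ele[ent$key_i == "B:1" & ent$key_j == "B:1"] <- 2
  tab <- pair_energy_table(ent, cs)
  m <- epi(tab, ifc, cs)
  expect_equal(unname(m[, "total"]), c(1, -3, 2))
  expect_equal(m["nuc_nuc", "total"], 2)  # nucleotide self joins nuc-nuc
  # conservation against the interface partition, random case
  cloud <- random_cloud(12, span = 12, seed = 22)
  cs2 <- micro_structure(cloud)
  ifc2 <- detect_interface(cs2)
  tab2 <- pair_energy_table(random_entries(cs2$monomers$key, seed = 23), cs2)
  expect_equal(colSums(epi(tab2, ifc2, cs2)),
               eini(tab2, ifc2)["interface", ], tolerance = 1e-12)
})

test_that("energy feature blocks have fixed lengths and difference behavior", {
  cs <- micro3p1n()
  tab <- pair_energy_table(random_entries(cs$monomers$key, seed = 30), cs)
  blocks <- assemble_energy_block(tab, tab, cs, cs, "A:1")
  lens <- vapply(blocks, length, integer(1))
  expect_equal(unname(lens), c(10L, 60L, 60L, 20L, 30L))
  for (b in blocks) {
    expect_equal(unname(b[grepl("\\.diff\\.", names(b))]),
                 rep(0, sum(grepl("\\.diff\\.", names(b)))))
  }
  # perturbing one mutant pair energy shifts only the affected partitions
  ent2 <- tab$entries
  sel <- ent2$key_i == "A:1" & ent2$key_j == "A:2"
  ent2$ele[sel] <- ent2$ele[sel] + 1
  ent2$total[sel] <- ent2$total[sel] + 1
  tab2 <- pair_energy_table(ent2, cs, state = "mutant")
  blocks2 <- assemble_energy_block(tab, tab2, cs, cs, "A:1")
  d_ewc <- blocks2$EWC[grepl("diff", names(blocks2$EWC))]
  expect_equal(unname(d_ewc[c("EWC.diff.total", "EWC.diff.ele")]), c(1, 1))
  expect_equal(unname(d_ewc[c("EWC.diff.vdw", "EWC.diff.gb", "EWC.diff.sa")]),
               rep(0, 3))
  d_etor <- blocks2$ETOR[grepl("diff", names(blocks2$ETOR))]
  expect_equal(unname(d_etor[["ETOR.diff.0-3.total"]]), 1)
  expect_equal(sum(d_etor != 0), 2)  # total and ele in one shell only
  # mismatched GB tags refuse to combine
  tab_hct <- pair_energy_table(tab$entries, cs, gb_model_tag = "HCT")
  expect_error(assemble_energy_block(tab_hct, tab2, cs, cs, "A:1"),
               "mismatch")
})

test_that("features are invariant to row order and linear in the table", {
  cloud <- random_cloud(10, span = 12, seed = 40)
  cs <- micro_structure(cloud)
  ent <- random_entries(cs$monomers$key, seed = 41)
  ifc <- detect_interface(cs)
  tab <- pair_energy_table(ent, cs)
  set.seed(42)
  tab_perm <- pair_energy_table(ent[sample(nrow(ent)), ], cs)
  target <- cs$monomers$key[1]
  expect_equal(etor(tab, cs, target), etor(tab_perm, cs, target))
  expect_equal(eini(tab, ifc), eini(tab_perm, ifc))
  ent_scaled <- ent
  ent_scaled[pnimut:::ENERGY_TERMS] <- ent_scaled[pnimut:::ENERGY_TERMS] * 2.5
  tab_s <- pair_energy_table(ent_scaled, cs)
  expect_equal(etor(tab_s, cs, target), 2.5 * etor(tab, cs, target))
  expect_equal(ewc(tab_s), 2.5 * ewc(tab))
  expect_equal(epi(tab_s, ifc, cs), 2.5 * epi(tab, ifc, cs))
})
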