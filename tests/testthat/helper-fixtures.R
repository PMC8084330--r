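# In-code fixtures: micro complexes with hand-placed atoms, random monomer
# clouds, and small energy tables. All randomness is locally seeded.

# build a complex_structure from a compact atom spec:
# list(key chr "A:1", kind, code, atoms = matrix/df with name, element, x, y, z)
micro_structure <- function(monomers, id = "micro") {
  rows <- lapply(monomers, function(m) {
    a <- as.data.frame(m$atoms, stringsAsFactors = FALSE)
    parts <- strsplit(m$key, ":")[[1]]
    resno <- as.integer(gsub("[A-Za-z]", "", parts[2]))
    icode <- gsub("[0-9]", "", parts[2])
    kind <- m$kind %||% "amino_acid"
    code <- m$code %||% if (kind == "amino_acid") "A" else "G"
    resname <- if (kind == "amino_acid") pnimut:::AA1[[code]] else
      if (kind == "dna_nucleotide") paste0("D", code) else code
    tibble::tibble(
      chain = parts[1], resno = resno, icode = icode, resname = resname,
      kind = kind, code = code,
      key = m$key, atom = a$name, element = a$element,
      x = a$x, y = a$y, z = a$z,
      is_heavy = !(a$element %in% c("H", "D")),
      record_class = pnimut:::atom_record_class(a$name, kind)
    )
  })
  pnimut:::new_complex_structure(id, dplyr::bind_rows(rows))
}

atomdf <- function(name, element, x, y, z) {
  data.frame(name = name, element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# single-atom monomer helper
mono1 <- function(key, x, y, z, kind = "amino_acid", code = NULL,
                  element = NULL, name = NULL) {
  defname <- if (kind == "amino_acid") "CA" else "P"
  defel <- if (kind == "amino_acid") "C" else "P"
  list(key = key, kind = kind, code = code,
       atoms = atomdf(name %||% defname, element %||% defel, x, y, z))
}

# random cloud of single-atom monomers, half protein half nucleic
random_cloud <- function(n, span = 30, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kind <- if (i <= n / 2) "amino_acid" else "dna_nucleotide"
    chain <- if (kind == "amino_acid") "A" else "B"
    resno <- if (kind == "amino_acid") i else i - floor(n / 2)
    mono1(paste0(chain, ":", resno), runif(1, 0, span), runif(1, 0, span),
          runif(1, 0, span), kind = kind)
  })
}

# entries tibble covering all self pairs plus given off-diagonal rows
micro_entries <- function(keys, off = NULL, self_total = 0) {
  selfs <- tibble::tibble(
    key_i = keys, key_j = keys,
    total = self_total, ele = self_total, vdw = 0, gb = 0, sa = 0
  )
  dplyr::bind_rows(selfs, off)
}

entry_row <- function(ki, kj, total, ele = total, vdw = 0, gb = 0, sa = 0) {
  tibble::tibble(key_i = ki, key_j = kj, total = total, ele = ele, vdw = vdw,
                 gb = gb, sa = sa)
}

# random full pair-energy entries with exact term closure
random_entries <- function(keys, seed = 1) {
  set.seed(seed)
  n <- length(keys)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  comp <- matrix(rnorm(nrow(idx) * 4), ncol = 4)
  tibble::tibble(
    key_i = keys[idx[, 1]], key_j = keys[idx[, 2]],
    ele = comp[, 1], vdw = comp[, 2], gb = comp[, 3], sa = comp[, 4],
    total = rowSums(comp)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny synthetic modeling dataset built directly from tabular features
fake_dataset <- function(n_complexes = 5, per = 3, seed = 1, p = 4,
                         signal = TRUE) {
  set.seed(seed)
  n <- n_complexes * per
  x <- matrix(rnorm(n * p), ncol = p,
              dimnames = list(NULL, paste0("G1.wt.", seq_len(p))))
  ddg <- if (signal) x[, 1] * 2 + rnorm(n, 0, 0.2) else rnorm(n)
  feats <- tibble::tibble(
    mutation_id = seq_len(n),
    complex_id = rep(sprintf("CPX%02d", seq_len(n_complexes)), each = per),
    ddg = ddg
  ) |> dplyr::bind_cols(tibble::as_tibble(x))
  manifest <- tibble::tibble(group = "G1", feature = colnames(x))
  mutation_dataset(feats, manifest)
}
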