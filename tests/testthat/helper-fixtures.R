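# Fixture builders and independent oracles shared across the test files.

# one PDB ATOM/HETATM line in strict fixed-column format
pdb_line <- function(record = "ATOM", serial = 1, name = "CA", alt = "",
                     comp = "ALA", chain = "A", seq = 1, x = 0, y = 0, z = 0,
                     occ = 1, elem = "C") {
  nm <- if (nchar(name) < 4L && nchar(elem) == 1L) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, comp, chain, seq, x, y, z, occ, 0, elem)
}

# atom-table row(s) in the package's internal layout
atom_row <- function(serial, name, elem, comp, chain, seq, x, y, z,
                     occ = 1, het = TRUE) {
  data.frame(serial = serial, atom_name = name, element = elem, alt_loc = "",
             comp_id = comp, chain_id = chain, seq_id = seq, insert = "",
             x = x, y = y, z = z, occupancy = occ, is_hetero = het,
             is_hydrogen = elem %in% c("H", "D"), stringsAsFactors = FALSE)
}

# SAM component atoms from the ideal template, as an atom table
sam_atoms <- function(seq = 401L, chain = "A", offset = c(0, 0, 0)) {
  tmpl <- sam_template()
  atom_row(seq_len(nrow(tmpl)), tmpl$atom_name, tmpl$element, "SAM", chain, seq,
           tmpl$x + offset[1], tmpl$y + offset[2], tmpl$z + offset[3])
}

# regular carbon hexagon (side `side`) centered at `center`, in the xy-ish
# plane spanned by two unit vectors orthogonal to `axis`
hexagon_atoms <- function(center, comp = "X99", chain = "A", seq = 402L,
                          side = 1.40, serial0 = 100L, axis = c(0, 0, 1)) {
  u <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- u - sum(u * axis) / sum(axis^2) * axis
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(axis[2] * n1[3] - axis[3] * n1[2],
          axis[3] * n1[1] - axis[1] * n1[3],
          axis[1] * n1[2] - axis[2] * n1[1])
  n2 <- n2 / sqrt(sum(n2^2))
  pos <- t(sapply(0:5, function(k) {
    th <- k * pi / 3
    center + side * (cos(th) * n1 + sin(th) * n2)
  }))
  atom_row(serial0 + 0:5, sprintf("C%d", 1:6), "C", comp, chain, seq,
           pos[, 1], pos[, 2], pos[, 3])
}

# wrap atom tables into a macromol structure
mk_structure <- function(entry_id, ...) {
  at <- do.call(rbind, list(...))
  at$serial <- seq_len(nrow(at))
  s <- parse_structure(text = write_pdb(structure(
    list(entry_id = entry_id, atoms = at, resolution = NA_real_),
    class = "macromol")), dialect = "pdb", entry_id = entry_id)
  s
}

# independent O(n^2) interface-tally oracle: plain double loop, no linear
# algebra shared with the implementation
oracle_tally <- function(cof_xyz, lig_xyz, cutoff) {
  nc <- 0L
  for (i in seq_len(nrow(cof_xyz))) {
    near <- FALSE
    for (j in seq_len(nrow(lig_xyz))) {
      d <- sqrt(sum((cof_xyz[i, ] - lig_xyz[j, ])^2))
      if (d < cutoff) { near <- TRUE; break }
    }
    if (near) nc <- nc + 1L
  }
  nl <- 0L
  for (j in seq_len(nrow(lig_xyz))) {
    near <- FALSE
    for (i in seq_len(nrow(cof_xyz))) {
      d <- sqrt(sum((cof_xyz[i, ] - lig_xyz[j, ])^2))
      if (d < cutoff) { near <- TRUE; break }
    }
    if (near) nl <- nl + 1L
  }
  c(n_cofactor = nc, n_ligand = nl)
}

# rigid-body transform of an atom table (rotation about z by `theta` then
# translation)
rigid_transform_atoms <- function(at, theta = 0.7, shift = c(5, -3, 2)) {
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  at
}

# component_instance wrapper around an atom table
as_component <- function(at, role) {
  structure(list(comp_id = at$comp_id[1L], chain_id = at$chain_id[1L],
                 seq_id = at$seq_id[1L], role = role, atoms = at),
            class = "component_instance")
}
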