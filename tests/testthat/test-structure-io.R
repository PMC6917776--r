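test_that("fixed-column PDB records map to the atom table", {
  txt <- c(pdb_line("ATOM", 1, "CA", comp = "ALA", x = 1.5, y = 2.25, z = -3),
           pdb_line("ATOM", 2, "CB", comp = "ALA", x = 2.5, y = 2.25, z = -3),
           pdb_line("ATOM", 3, "O", comp = "ALA", x = 3.5, y = 2.25, z = -3,
                    elem = "O"),
           "END")
  s <- parse_structure(text = txt, dialect = "pdb", entry_id = "fx1")
  expect_s3_class(s, "macromol")
  expect_equal(nrow(s$atoms), 3L)
  expect_equal(s$atoms$atom_name, c("CA", "CB", "O"))
  expect_equal(s$atoms$element, c("C", "C", "O"))
  expect_equal(s$atoms$x, c(1.5, 2.5, 3.5))
  expect_false(any(s$atoms$is_hetero))
})

test_that("altloc conformers collapse to the highest occupancy, ties to the first id", {
  txt <- c(pdb_line("ATOM", 1, "CA", alt = "A", comp = "SER", seq = 5,
                    x = 1, occ = 0.6),
           pdb_line("ATOM", 2, "CA", alt = "B", comp = "SER", seq = 5,
                    x = 2, occ = 0.4),
           pdb_line("ATOM", 3, "OG", alt = "B", comp = "SER", seq = 5,
                    x = 4, occ = 0.5, elem = "O"),
           pdb_line("ATOM", 4, "OG", alt = "A", comp = "SER", seq = 5,
                    x = 3, occ = 0.5, elem = "O"),
           "END")
  s <- parse_structure(text = txt, dialect = "pdb")
  expect_equal(nrow(s$atoms), 2L)
  ca <- s$atoms[s$atoms$atom_name == "CA", ]
  expect_equal(ca$alt_loc, "A")   # higher occupancy wins
  expect_equal(ca$x, 1)
  og <- s$atoms[s$atoms$atom_name == "OG", ]
  expect_equal(og$alt_loc, "A")   # occupancy tie: lexicographically first
  expect_false(anyDuplicated(s$atoms$serial) > 0)
})

test_that("elements are inferred from atom names when the column is absent", {
  expect_equal(infer_element(c("CA", "CB", "N", "OXT"),
                             c("ALA", "ALA", "ALA", "ALA")),
               c("C", "C", "N", "O"))
  expect_equal(infer_element(c("CL1", "FE", "ZN", "C7", "O3'"),
                             c("LIG", "HEM", "ZN", "LIG", "SAM")),
               c("CL", "FE", "ZN", "C", "O"))
})

test_that("write/parse round trip preserves names and coordinates to 3 decimals", {
  toy <- make_toy_complex(synth_spec(7, "toy_complex"))
  s1 <- parse_structure(text = toy$pdb_text, entry_id = "rt")
  s2 <- parse_structure(text = write_pdb(s1), entry_id = "rt")
  expect_equal(nrow(s2$atoms), nrow(s1$atoms))
  expect_equal(s2$atoms$atom_name, s1$atoms$atom_name)
  expect_equal(s2$atoms$comp_id, s1$atoms$comp_id)
  expect_equal(s2$atoms$x, s1$atoms$x, tolerance = 1e-9)
  expect_equal(s2$atoms$y, s1$atoms$y, tolerance = 1e-9)
  expect_equal(s2$atoms$z, s1$atoms$z, tolerance = 1e-9)
})

test_that("mmCIF atom_site records parse to the same atoms as PDB", {
  cif <- c(
    "data_FX", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol", "label_atom_id",
                            "label_alt_id", "label_comp_id", "label_asym_id",
                            "label_entity_id", "label_seq_id",
                            "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                            "Cartn_z", "occupancy", "B_iso_or_equiv",
                            "pdbx_formal_charge", "auth_seq_id",
                            "auth_comp_id", "auth_asym_id", "auth_atom_id",
                            "pdbx_PDB_model_num")),
    "ATOM 1 C CA . ALA A 1 1 ? 1.500 2.250 -3.000 1.00 20.00 ? 1 ALA A CA 1",
    "HETATM 2 S SD . SAM A 2 2 ? 0.000 0.000 0.000 1.00 20.00 ? 401 SAM A SD 1")
  s <- parse_structure(text = cif, dialect = "mmcif", entry_id = "fxcif")
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$element, c("C", "S"))
  expect_equal(s$atoms$comp_id, c("ALA", "SAM"))
  expect_equal(s$atoms$is_hetero, c(FALSE, TRUE))
  expect_equal(s$atoms$x, c(1.5, 0))
})

test_that("empty or unparseable input errors out", {
  expect_error(parse_structure(text = c("", "")), "empty")
  expect_error(parse_structure(text = "REMARK nothing here"), "atom|unparseable")
  expect_error(parse_structure(), "required")
})

test_that("classification assigns exactly one role per component", {
  far <- 30
  s <- mk_structure(
    "cls1",
    sam_atoms(),
    hexagon_atoms(c(far, 0, 0), comp = "X99", seq = 402L),
    atom_row(200, "C1", "C", "GOL", "A", 403, far, 5, 0),
    atom_row(201, "MG", "MG", "MG", "A", 404, far, 10, 0),
    atom_row(202, "O", "O", "HOH", "A", 405, far, 15, 0),
    atom_row(210, "CA", "C", "ALA", "A", 1, far, 20, 0, het = FALSE)
  )
  comps <- classify_components(s)
  roles <- vapply(comps, `[[`, character(1), "role")
  names(roles) <- vapply(comps, `[[`, character(1), "comp_id")
  expect_equal(unname(roles[c("SAM", "X99", "GOL", "MG", "HOH", "ALA")]),
               c("cofactor_SAM", "candidate_ligand", "excluded", "excluded",
                 "excluded", "polymer"))
  # partition: every component exactly one role
  expect_true(all(roles %in% c("cofactor_SAM", "cofactor_SAH", "polymer",
                               "excluded", "candidate_ligand")))
})

test_that("an SAH-only structure yields one cofactor and no candidates", {
  sah <- sam_atoms()
  sah$comp_id <- "SAH"
  s <- mk_structure("sah1", sah)
  roles <- vapply(classify_components(s), `[[`, character(1), "role")
  expect_equal(unname(roles), "cofactor_SAH")
})

test_that("bond perception follows the scaled covalent-radius rule", {
  two_c <- function(d) as_component(
    atom_row(1:2, c("C1", "C2"), "C", "LIG", "A", 1, c(0, d), 0, 0),
    "candidate_ligand")
  expect_equal(nrow(perceive_bonds(two_c(1.5), scale = 1.3)$edges), 1L)
  # threshold: 1.3 * (0.76 + 0.76) = 1.976
  expect_equal(nrow(perceive_bonds(two_c(2.5), scale = 1.3)$edges), 0L)
  expect_equal(nrow(perceive_bonds(two_c(1.97), scale = 1.3)$edges), 1L)
  expect_equal(nrow(perceive_bonds(two_c(1.98), scale = 1.3)$edges), 0L)
  hexa <- as_component(hexagon_atoms(c(0, 0, 0)), "candidate_ligand")
  bg <- perceive_bonds(hexa)
  expect_equal(nrow(bg$edges), 6L)        # one six-cycle
  expect_true(has_ring(hexa, bg))
  expect_error(perceive_bonds(as_component(
    atom_row(1, "XX", "XX", "LIG", "A", 1, 0, 0, 0), "candidate_ligand")),
    "covalent radius")
})

test_that("perceived edges are monotone non-decreasing in the scale factor", {
  at <- sam_atoms()
  counts <- vapply(c(1.0, 1.15, 1.3, 1.45), function(sc)
    nrow(perceive_bonds(at, scale = sc)$edges), numeric(1))
  expect_true(all(diff(counts) >= 0))
  # edges join atoms of the same component by construction of the API
  bg <- perceive_bonds(at, scale = 1.3)
  expect_true(all(bg$edges[, 1L] < bg$edges[, 2L]))  # no self-edges, undirected
})
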