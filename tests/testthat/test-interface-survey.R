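test_that("hand-checkable tallies: one contact inside, one outside the cutoff", {
  cof <- as_component(atom_row(1, "SD", "S", "SAM", "A", 401, 0, 0, 0),
                      "cofactor_SAM")
  lig <- as_component(
    atom_row(2:3, c("C1", "C2"), "C", "LIG", "A", 402, c(3.5, 4.5), 0, 0),
    "candidate_ligand")
  tl <- tally_interface(cof, lig, cutoff = 4.0)
  expect_equal(tl$n_cofactor_atoms, 1L)
  expect_equal(tl$n_ligand_atoms, 1L)
})

test_that("the cutoff is strict: an atom at exactly 4.0 A does not count", {
  cof <- as_component(atom_row(1, "SD", "S", "SAM", "A", 401, 0, 0, 0),
                      "cofactor_SAM")
  at_cut <- as_component(atom_row(2, "C1", "C", "LIG", "A", 402, 4.0, 0, 0),
                         "candidate_ligand")
  tl <- tally_interface(cof, at_cut, cutoff = 4.0)
  expect_equal(tl$n_cofactor_atoms, 0L)
  expect_equal(tl$n_ligand_atoms, 0L)
  just_in <- as_component(atom_row(2, "C1", "C", "LIG", "A", 402, 3.999999, 0, 0),
                          "candidate_ligand")
  expect_equal(tally_interface(cof, just_in, 4.0)$n_ligand_atoms, 1L)
})

test_that("a non-cofactor first argument is rejected", {
  lig <- as_component(atom_row(1, "C1", "C", "LIG", "A", 1, 0, 0, 0),
                      "candidate_ligand")
  expect_error(tally_interface(lig, lig), "cofactor")
})

test_that("tally equals the brute-force all-pairs oracle on 100 seeded fixtures", {
  set.seed(4242)
  for (rep in 1:100) {
    nc <- sample(5:20, 1); nl <- sample(3:15, 1)
    cof_xyz <- matrix(stats::runif(nc * 3, -6, 6), nc, 3)
    lig_xyz <- matrix(stats::runif(nl * 3, -6, 6), nl, 3)
    cutoff <- stats::runif(1, 2, 6)
    cof <- as_component(atom_row(seq_len(nc), sprintf("S%d", seq_len(nc)), "S",
                                 "SAM", "A", 1, cof_xyz[, 1], cof_xyz[, 2],
                                 cof_xyz[, 3]), "cofactor_SAM")
    lig <- as_component(atom_row(nc + seq_len(nl), sprintf("C%d", seq_len(nl)),
                                 "C", "LIG", "A", 2, lig_xyz[, 1], lig_xyz[, 2],
                                 lig_xyz[, 3]), "candidate_ligand")
    tl <- tally_interface(cof, lig, cutoff)
    orc <- oracle_tally(cof_xyz, lig_xyz, cutoff)
    expect_identical(c(tl$n_cofactor_atoms, tl$n_ligand_atoms),
                     unname(orc))
  }
})

test_that("tallies are monotone in the cutoff and invariant under rigid motion", {
  set.seed(99)
  cof_at <- sam_atoms()
  lig_at <- hexagon_atoms(c(8, 0, 0))
  cof <- as_component(cof_at, "cofactor_SAM")
  lig <- as_component(lig_at, "candidate_ligand")
  cuts <- c(2, 3, 4, 5, 6, 8)
  tl <- lapply(cuts, function(cc) tally_interface(cof, lig, cc))
  ncof <- vapply(tl, `[[`, numeric(1), "n_cofactor_atoms")
  nlig <- vapply(tl, `[[`, numeric(1), "n_ligand_atoms")
  expect_true(all(diff(ncof) >= 0))
  expect_true(all(diff(nlig) >= 0))
  # rigid-body invariance: same rotation+translation applied to both partners
  cof_t <- as_component(rigid_transform_atoms(cof_at), "cofactor_SAM")
  lig_t <- as_component(rigid_transform_atoms(lig_at), "candidate_ligand")
  t1 <- tally_interface(cof, lig, 4.5)
  t2 <- tally_interface(cof_t, lig_t, 4.5)
  expect_equal(t2$n_cofactor_atoms, t1$n_cofactor_atoms)
  expect_equal(t2$n_ligand_atoms, t1$n_ligand_atoms)
})

test_that("ring detection: cycles yes, chains no, SAM yes", {
  expect_true(has_ring(as_component(hexagon_atoms(c(0, 0, 0)),
                                    "candidate_ligand")))
  chain <- as_component(
    atom_row(1:4, sprintf("C%d", 1:4), "C", "LIG", "A", 1,
             c(0, 1.5, 3.0, 4.5), 0, 0), "candidate_ligand")
  expect_false(has_ring(chain))
  expect_true(has_ring(as_component(sam_atoms(), "cofactor_SAM")))
})

test_that("survey keeps ringed interface ligands and reports rejection reasons", {
  near <- sam_atoms()
  anchor <- as.numeric(near[which.max(near$x), c("x", "y", "z")])
  s1 <- mk_structure(
    "ent1",
    sam_atoms(),
    # ringed ligand in contact
    hexagon_atoms(anchor + c(4.2, 0, 0), comp = "X99", seq = 402L),
    # ring-less ligand in contact
    atom_row(300:302, sprintf("C%d", 1:3), "C", "CHN", "A", 403,
             anchor[1] + c(3.0, 4.5, 6.0), anchor[2], anchor[3]),
    # ringed ligand far away: zero interface
    hexagon_atoms(anchor + c(30, 0, 0), comp = "FAR", seq = 404L),
    # deny-listed component in contact: never a candidate
    atom_row(310, "C1", "C", "GOL", "A", 405, anchor[1] + 3, anchor[2], anchor[3])
  )
  sv <- run_survey(list(s1), hydrogen_mode = "none")
  expect_s3_class(sv, "survey_result")
  expect_setequal(sv$ligand_comp, c("X99", "CHN", "FAR"))
  expect_true(sv$kept[sv$ligand_comp == "X99"])
  expect_equal(sv$reason[sv$ligand_comp == "CHN"], "no_ring")
  expect_equal(sv$reason[sv$ligand_comp == "FAR"], "zero_interface")
  rep <- attr(sv, "report")
  expect_equal(rep$n_kept, 1L)
  expect_equal(rep$n_structures, 1L)
})

test_that("survey deduplicates repeated ligand-cofactor pairs, keeping the largest tally", {
  near <- sam_atoms()
  anchor <- as.numeric(near[which.max(near$x), c("x", "y", "z")])
  mk_entry <- function(id, dx) mk_structure(
    id, sam_atoms(), hexagon_atoms(anchor + c(dx, 0, 0), comp = "X99", seq = 402L))
  e1 <- mk_entry("entA", 4.6)  # grazing contact
  e2 <- mk_entry("entB", 3.6)  # closer: larger tallies
  sv <- run_survey(list(e1, e2), hydrogen_mode = "none")
  expect_equal(sum(sv$kept), 1L)
  expect_equal(sv$entry_id[sv$kept], "entB")
  expect_equal(sv$reason[!sv$kept], "duplicate")
  # kept rows contain no duplicate (ligand, cofactor) keys
  keys <- paste(sv$ligand_comp[sv$kept], sv$cofactor_comp[sv$kept])
  expect_false(anyDuplicated(keys) > 0)
  # output is sorted by descending combined tally
  comb <- sv$n_cofactor_atoms + sv$n_ligand_atoms
  expect_true(all(diff(comb) <= 0))
})

test_that("a structure with only deny-listed heteroatoms yields zero kept records", {
  s <- mk_structure("ent0", sam_atoms(),
                    atom_row(300, "C1", "C", "GOL", "A", 403, 3, 0, 0),
                    atom_row(301, "MG", "MG", "MG", "A", 404, -3, 0, 0))
  sv <- run_survey(list(s), hydrogen_mode = "none")
  expect_equal(sum(sv$kept), 0L)
})

test_that("a survey with no cofactor warns and returns an empty table", {
  s <- mk_structure("nocof", hexagon_atoms(c(0, 0, 0), comp = "X99", seq = 1L))
  expect_warning(sv <- run_survey(list(s), hydrogen_mode = "none"), "cofactor")
  expect_equal(nrow(sv), 0L)
})

test_that("survey TSV and JSON report round-trip to disk", {
  near <- sam_atoms()
  anchor <- as.numeric(near[which.max(near$x), c("x", "y", "z")])
  s <- mk_structure("io1", sam_atoms(),
                    hexagon_atoms(anchor + c(4, 0, 0), comp = "X99", seq = 402L))
  sv <- run_survey(list(s), hydrogen_mode = "none")
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_survey(sv, tsv, js)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(sv))
  rep <- jsonlite::read_json(js)
  expect_equal(rep$cutoff, 4)
  expect_equal(rep$hydrogen_mode, "none")
  unlink(c(tsv, js))
})
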