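test_that("a minimal hand-written PDB parses into the expected model", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   67.230   67.230  146.940  90.00  90.00  90.00 P 43 21 2",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "END"), p)
  m <- read_structure(p)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(length(polymer_chains(m)), 1)
  expect_equal(nrow(chain_residues(m, "A")), 1)
  expect_equal(m$metadata$space_group, "P 43 21 2")
  expect_equal(m$metadata$cell[1:3], c(67.23, 67.23, 146.94))
})

test_that("altlocs resolve to the highest occupancy, ties alphabetically", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   SER A   5       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA ASER A   5       1.458   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA BSER A   5       1.500   0.100   0.000  0.40 10.00           C",
    "ATOM      4  OG BSER A   5       2.500   0.100   0.000  0.50 10.00           O",
    "ATOM      5  OG ASER A   5       2.400   0.000   0.000  0.50 10.00           O",
    "END"), p)
  m <- read_structure(p)
  ca <- m$atoms[m$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$occ, 0.6)
  expect_equal(ca$altloc, "A")
  og <- m$atoms[m$atoms$name == "OG", ]   # tied occupancy: altloc A wins
  expect_equal(og$altloc, "A")
  expect_equal(og$x, 2.4)
})

test_that("parse failures and empty models raise informative errors", {
  expect_error(read_structure(tempfile()), "not found")
  p <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), p)
  expect_error(read_structure(p), "parse|empty|coordinate")
})

test_that("waters and metal ions are flagged hetero and separable", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "HETATM    2 CA    CA A 201       5.000   0.000   0.000  1.00 10.00          CA",
    "HETATM    3  O   HOH A 301       8.000   0.000   0.000  1.00 10.00           O",
    "END"), p)
  m <- read_structure(p)
  expect_equal(sum(m$atoms$hetero), 2)
  expect_equal(sum(m$atoms$is_water), 1)
  # the calcium ion is distinguished from the C-alpha by the hetero flag
  sites <- find_metal_sites(m)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$serial, 2)
})

test_that("writing and re-reading a model preserves keys and coordinates", {
  p <- tempfile(fileext = ".pdb")
  write_structure(wt_complex, p)
  back <- read_structure(p)
  expect_equal(nrow(back$atoms), nrow(wt_complex$atoms))
  key <- function(a) paste(a$chain, a$resseq, a$icode, a$name)
  expect_identical(key(back$atoms), key(wt_complex$atoms))
  expect_lt(max(abs(atom_coords(back) - atom_coords(wt_complex))), 1e-3)
})

test_that("mmCIF atom_site records parse equivalently to PDB", {
  cif <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "_cell.length_a 67.230",
    "_cell.length_b 67.230",
    "_cell.length_c 146.940",
    "_cell.angle_alpha 90.00",
    "_cell.angle_beta 90.00",
    "_cell.angle_gamma 90.00",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 10.00 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 10.00 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 2.009 1.420 0.000 1.00 10.00 1 ALA A C 1"),
    cif)
  m <- read_structure(cif)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$name, c("N", "CA", "C"))
  expect_equal(m$metadata$cell[3], 146.94)
})
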