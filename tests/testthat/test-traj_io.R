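# Structure/trajectory I/O: PDB and DCD codecs, atom selection.

pdb_fixture_lines <- function(models = 1L) {
  atoms <- c(
    "ATOM      1  NE2 HIS A 173      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  O   SER A 183      14.000  10.000  10.000  1.00  0.00           O",
    "ATOM      3  CB  HIS A  67       5.000   5.000   5.000  1.00  0.00           C",
    "ATOM      4  CD1 ILE A 165      12.000   5.000   5.000  1.00  0.00           C")
  hdr <- "CRYST1   60.000   60.000   60.000  90.00  90.00  90.00 P 1           1"
  if (models == 1L) return(c(hdr, atoms, "END"))
  body <- unlist(lapply(seq_len(models), function(m)
    c(sprintf("MODEL     %4d", m),
      sub("10.000  10.000  10.000",
          sprintf("10.000  10.000  %6.3f", 10 + m), atoms[1]),
      atoms[-1], "ENDMDL")))
  c(hdr, body, "END")
}

test_that("read_pdb parses single- and multi-model fixtures", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_fixture_lines(1L), f)
  r <- read_pdb(f)
  expect_equal(n_atoms(r$topology), 4L)
  expect_equal(n_frames(r$trajectory), 1L)
  expect_equal(r$topology$element, c("N", "O", "C", "C"))
  expect_equal(r$trajectory$box[, 1], c(60, 60, 60))
  expect_equal(frame_coords(r$trajectory, 1)[2, ], c(14, 10, 10))

  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_fixture_lines(3L), f3)
  r3 <- read_pdb(f3)
  expect_equal(n_frames(r3$trajectory), 3L)
  expect_identical(r3$topology, r$topology)
  expect_equal(r3$trajectory$coords[1, 3, ], c(11, 12, 13))
})

test_that("read_pdb rejects malformed, empty and triclinic input", {
  f <- withr::local_tempfile(fileext = ".pdb")
  bad <- pdb_fixture_lines(1L)
  bad[3] <- paste0(substr(bad[3], 1, 30), "  badnum", substr(bad[3], 39, 80))
  writeLines(bad, f)
  expect_error(read_pdb(f), "line 3")

  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_pdb(f), "no ATOM")

  tri <- pdb_fixture_lines(1L)
  tri[1] <- "CRYST1   60.000   60.000   60.000  90.00  95.00  90.00 P 1"
  writeLines(tri, f)
  expect_error(read_pdb(f), "triclinic")

  expect_error(read_pdb("/nonexistent/x.pdb"), "no such file")
})

test_that("PDB write -> read round-trips identity exactly and coordinates to format precision", {
  g <- gen_gating_fixture(d1 = 4.123, d2 = 7.456, chi_sf = 135,
                          chi_ce = -60)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(g$topology, g$trajectory, f)
  r <- read_pdb(f)
  expect_identical(r$topology$atom_name, g$topology$atom_name)
  expect_identical(r$topology$residue_name, g$topology$residue_name)
  expect_identical(r$topology$residue_number, g$topology$residue_number)
  expect_identical(r$topology$chain_id, g$topology$chain_id)
  expect_lt(max(abs(r$trajectory$coords - g$trajectory$coords)), 1e-3)

  # multi-frame round trip through MODEL blocks
  set.seed(5)
  mt <- make_z_trajectory(matrix(rnorm(9, sd = 5), nrow = 3),
                          box = c(40, 40, 200))
  fm <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(mt$topology, mt, fm)
  rm2 <- read_pdb(fm, box = c(40, 40, 200))
  expect_equal(n_frames(rm2$trajectory), 3L)
  expect_lt(max(abs(rm2$trajectory$coords - mt$coords)), 1e-3)
})

test_that("a minimal aquaflux PDB parses under an independent parser", {
  top <- topology("OH2", "TIP3", 1L, "W", element = "O")
  traj <- trajectory(top, matrix(c(1.5, -2.25, 3.125), 1), c(30, 30, 30))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(top, traj, f)
  out <- system2("python", c("-c", shQuote(paste0(
    "from Bio.PDB import PDBParser;",
    "s=PDBParser(QUIET=True).get_structure('x','", f, "');",
    "a=list(s.get_atoms());",
    "print(len(a), a[0].get_name(), round(a[0].coord[2],3))"))),
    stdout = TRUE, stderr = FALSE)
  expect_equal(out[length(out)], "1 OH2 3.125")
})

test_that("write_dcd / read_dcd round-trip a 10-frame synthetic trajectory", {
  set.seed(11)
  zmat <- matrix(rnorm(5 * 10, sd = 8), nrow = 5)
  traj <- make_z_trajectory(zmat, box = c(40, 45, 200), dt_ns = 0.5)
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(traj, f)
  r1 <- read_dcd(f, traj$topology)
  # one float32 quantization, then bitwise stable
  expect_lt(max(abs(r1$coords - traj$coords)), 1e-4)
  expect_equal(r1$box, traj$box)
  expect_equal(r1$times, traj$times)
  f2 <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(r1, f2)
  r2 <- read_dcd(f2, traj$topology)
  expect_identical(r2$coords, r1$coords)
})

test_that("DCD reader reports structural problems", {
  set.seed(2)
  traj <- make_z_trajectory(matrix(rnorm(12), nrow = 3))
  f <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(traj, f)
  wrong <- topology(rep("OH2", 5), "TIP3", 1:5, "W")
  expect_error(read_dcd(f, wrong), "does not match topology")

  # empty-frame file: truncate right after the natom record
  raw <- readBin(f, "raw", file.info(f)$size)
  f3 <- withr::local_tempfile(fileext = ".dcd")
  writeBin(raw[1:196], f3)
  expect_error(read_dcd(f3, traj$topology), "empty trajectory")

  # truncation inside a frame names the last complete frame
  nbytes <- file.info(f)$size
  f4 <- withr::local_tempfile(fileext = ".dcd")
  writeBin(raw[seq_len(nbytes - 10)], f4)
  expect_error(read_dcd(f4, traj$topology), "DCD|frame")

  expect_error(write_dcd(structure(list(coords = array(0, c(1, 3, 0))),
                                   class = "trajectory"), f),
               "0-frame")
})

test_that("select_atoms matches by residue/atom criteria with Ile CD dialect tolerance", {
  for (cd in c("CD", "CD1")) {
    g <- gen_gating_fixture(ile_cd_name = cd)
    top <- g$topology
    expect_length(select_atoms(top, "HIS", 173, "NE2"), 1L)
    expect_length(select_atoms(top, "ILE", 165, "CD"), 1L)
    expect_length(select_atoms(top, "ILE", 165, "CD1"), 1L)
    expect_length(select_atoms(top, "XXX"), 0L)
    expect_length(select_atoms(top, "HIS"), 8L)
    expect_length(select_atoms(top, chain = "A"), 10L)
    expect_length(select_atoms(top, chain = "B"), 0L)
    # idempotent and criterion-order independent
    s1 <- select_atoms(top, residue_name = "HIS", atom_name = "NE2")
    s2 <- select_atoms(top, atom_name = "NE2", residue_name = "HIS")
    expect_identical(s1, s2)
    expect_identical(atom_selection(s1), s1)
  }
})

test_that("topology invariants are enforced", {
  expect_error(topology(c("CA", "CA"), "GLY", c(1, 1), "A"),
               "duplicate")
  expect_error(topology(character(0), character(0), integer(0)), "empty")
  expect_error(topology("CA", "GLY", 1, "A", vdw = -1), "vdw")
  expect_warning(vdw_radius("XX"), "unknown element")
  expect_equal(suppressWarnings(vdw_radius(c("C", "XX"))), c(1.70, 1.70))
  expect_equal(infer_element(c("NE2", "1HG1", "OH2", "CD1")),
               c("N", "H", "O", "C"))
})
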