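test_that("ensemble constructor validates roster, frames and times", {
  atoms <- data.frame(serial = 1:3, atom_name = c("N", "CA", "C"),
                      residue_name = "ALA", residue_number = 1L,
                      chain_id = "A", element = c("N", "C", "C"))
  xyz <- array(rnorm(9), c(3, 3, 1))
  e <- conformational_ensemble(atoms, xyz)
  expect_equal(n_frames(e), 1L)
  expect_equal(n_atoms(e), 3L)
  expect_equal(e$frame_times, 0)

  expect_error(conformational_ensemble(atoms, array(rnorm(18), c(3, 3, 2)),
                                       frame_times = c(1, 1)),
               "strictly increasing")
  expect_error(conformational_ensemble(atoms[c(1, 1, 2), ], xyz), "duplicate")
  bad <- xyz; bad[1] <- NA
  expect_error(conformational_ensemble(atoms, bad), "finite")
})

test_that("multi-model PDB round-trips coordinates and roster", {
  spec <- ensemble_spec(6, sigma = 0.8, n_frames = 4, seed = 11)
  e <- sample_ensemble(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e, path)
  txt <- readLines(path)
  expect_equal(sum(startsWith(txt, "MODEL")), 4L)
  expect_equal(sum(startsWith(txt, "ENDMDL")), 4L)

  e2 <- read_multimodel_pdb(path)
  expect_equal(n_frames(e2), 4L)
  # format precision is 3 decimals
  expect_lt(max(abs(e2$coords - e$coords)), 1e-3)
  expect_equal(e2$atoms$atom_name, e$atoms$atom_name)
  expect_equal(e2$atoms$residue_number, e$atoms$residue_number)
  expect_equal(e2$atoms$chain_id, e$atoms$chain_id)
})

test_that("second model translated by (1,0,0) reads back as that offset", {
  spec <- ensemble_spec(4, sigma = 0.3, n_frames = 2, seed = 3)
  e <- sample_ensemble(spec)
  e$coords[, , 2] <- e$coords[, , 1]
  e$coords[, 1, 2] <- e$coords[, 1, 2] + 1
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e, path)
  e2 <- read_multimodel_pdb(path)
  diff <- e2$coords[, , 2] - e2$coords[, , 1]
  expect_equal(diff[, 1], rep(1, 4), tolerance = 1e-9)
  expect_equal(max(abs(diff[, 2:3])), 0)
})

test_that("models are matched by atom identity, not serial order", {
  spec <- ensemble_spec(4, sigma = 0.2, n_frames = 2, seed = 5)
  e <- sample_ensemble(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e, path)
  txt <- readLines(path)
  # reverse the atom order (and leave stale serials) inside model 2
  m2 <- which(startsWith(txt, "MODEL") )[2]
  end2 <- which(startsWith(txt, "ENDMDL"))[2]
  atoms2 <- (m2 + 1):(end2 - 1)
  txt[atoms2] <- rev(txt[atoms2])
  writeLines(txt, path)
  e2 <- read_multimodel_pdb(path)
  expect_lt(max(abs(e2$coords - e$coords)), 1e-3)
})

test_that("roster mismatches and bad records are reported precisely", {
  spec <- ensemble_spec(3, sigma = 0.2, n_frames = 2, seed = 6)
  e <- sample_ensemble(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e, path)
  txt <- readLines(path)
  atom_lines <- which(startsWith(txt, "ATOM"))

  # drop one atom from model 2 -> error naming the missing atom
  writeLines(txt[-atom_lines[5]], path)
  expect_error(read_multimodel_pdb(path), "missing roster atom A/2/CA")

  # truncate an ATOM line -> error with its line number
  txt2 <- txt
  txt2[atom_lines[2]] <- substr(txt2[atom_lines[2]], 1, 30)
  writeLines(txt2, path)
  expect_error(read_multimodel_pdb(path), paste0("line ", atom_lines[2]))

  # insertion codes are rejected
  txt3 <- txt
  substr(txt3[atom_lines[1]], 27, 27) <- "B"
  writeLines(txt3, path)
  expect_error(read_multimodel_pdb(path), "insertion code")
})

test_that("extra atoms in a later model are rejected", {
  spec <- ensemble_spec(3, sigma = 0.2, n_frames = 2, seed = 8)
  e <- sample_ensemble(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e, path)
  txt <- readLines(path)
  atom_lines <- which(startsWith(txt, "ATOM"))
  extra <- sub(" CA ", " CB ", txt[atom_lines[4]])
  writeLines(append(txt, extra, after = atom_lines[6]), path)
  expect_error(read_multimodel_pdb(path), "absent from model 1")
})

test_that("domain maps parse, validate and cover the expected residues", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "all 1 10"), path)
  dm <- read_domain_map(path)
  expect_equal(nrow(dm), 1L)
  expect_equal(domain_residue_count(dm), 10L)

  writeLines(c("a 1 5", "b 4 8"), path)
  expect_error(read_domain_map(path), "'a' and 'b'")

  writeLines("bad 7 3", path)
  expect_error(read_domain_map(path), "exceeds")

  expect_error(domain_map(c("x", "x"), c(1, 5), c(2, 9)), "duplicate")
})

test_that("the packaged four-domain decomposition matches the built-in one", {
  path <- system.file("extdata", "htop1_domains.txt", package = "topotraj")
  dm <- read_domain_map(path)
  expect_equal(nrow(dm), 4L)
  expect_equal(dm$name, htop1_domains()$name)
  expect_equal(domain_residue_count(dm), domain_residue_count(htop1_domains()))
  expect_equal(assign_domains(c(1, 214, 215, 635, 636, 712, 713, 765, 766), dm),
               c("N-terminal", "N-terminal", "core", "core", "linker",
                 "linker", "C-terminal", "C-terminal", NA))
})

test_that("matrix TSV round-trips at full precision", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(diag(2), c("r1", "r2"), c("c1", "c2"), path)
  expect_length(readLines(path), 3L)

  m <- matrix(c(pi, -exp(1), 1 / 3, 2 / 7, 0.1, -1e-8), 2, 3)
  write_matrix_tsv(m, 1:2, c("a", "b", "c"), path)
  back <- read_matrix_tsv(path)
  expect_lt(max(abs(back - m)), 1e-12)
  expect_equal(dim(back), c(2L, 3L))

  expect_error(write_matrix_tsv(m, 1:3, c("a", "b", "c"), path),
               "row_labels")
})

test_that("frame slicing keeps roster and validates indices", {
  e <- sample_ensemble(ensemble_spec(4, n_frames = 10, seed = 2))
  s <- slice_frames(e, seq(2, 10, by = 2))
  expect_equal(n_frames(s), 5L)
  expect_equal(s$coords[, , 3], e$coords[, , 6])
  expect_error(slice_frames(e, 11), "out of range")
})

test_that("pair config files resolve default selectors and cutoffs", {
  path <- system.file("extdata", "salt_bridge_pairs.txt", package = "topotraj")
  pairs <- read_pair_config(path)
  expect_length(pairs, 2L)
  expect_equal(pairs[[1]]$atoms_a, c("OE1", "OE2"))
  expect_equal(pairs[[1]]$atoms_b, c("NH1", "NH2", "NE"))
  expect_equal(pairs[[2]]$residue_a$number, 707L)
  expect_equal(pairs[[1]]$cutoff, 4.0)
})
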