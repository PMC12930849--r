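test_that("ensemble loading counts and strides frames correctly", {
  pep <- generate_peptide("ADA")
  path <- withr::local_tempfile(fileext = ".pdb")
  generate_trajectory(pep, path, n_frames = 10, amplitude = 0.5, seed = 3)

  ens <- load_ensemble(path, stride = 1, timestep_ps = 100)
  expect_equal(ens$n_frames, 10)
  expect_equal(ens$times, (0:9) * 100)

  ens2 <- load_ensemble(path, stride = 2, timestep_ps = 100)
  expect_equal(ens2$n_frames, 5)
  expect_equal(ens2$frame_indices, c(0L, 2L, 4L, 6L, 8L))

  snaps <- lapply(seq_len(ens$n_frames), get_frame, ensemble = ens)
  times <- vapply(snaps, frame_time, 0)
  expect_true(all(diff(times) > 0))
})

test_that("atom-count mismatch between topology and trajectory errors", {
  pep <- generate_peptide("ADA")
  other <- generate_peptide("ADAK")
  traj <- withr::local_tempfile(fileext = ".pdb")
  topo <- withr::local_tempfile(fileext = ".pdb")
  generate_trajectory(pep, traj, n_frames = 3, amplitude = 0, seed = 1)
  write_snapshot_pdb(other, topo)
  expect_error(load_ensemble(topo, traj), class = "trajpka_topology_error")
  expect_error(load_ensemble("no/such/file.pdb"),
               class = "trajpka_input_error")
})

test_that("water and ion residues are stripped when protein_only", {
  pep <- generate_peptide("ADA")
  solvated <- new_snapshot(dplyr::bind_rows(
    tibble::as_tibble(pep),
    tibble::tibble(atom_name = "O", resname = "HOH", chain = "A",
                   resid = 90L, x = 30, y = 0, z = 0)
  ))
  path <- withr::local_tempfile(fileext = ".pdb")
  generate_trajectory(solvated, path, n_frames = 2, amplitude = 0, seed = 1)
  ens <- load_ensemble(path)
  expect_false("HOH" %in% ens$topology$resname)
  ens_full <- load_ensemble(path, protein_only = FALSE)
  expect_true("HOH" %in% ens_full$topology$resname)
})

test_that("frame splitting is contiguous, near-equal, and complete", {
  s <- split_frames(10, 3)
  expect_equal(s$stop - s$start, c(4L, 3L, 3L))
  expect_equal(s$start, c(0L, 4L, 7L))

  expect_equal(split_frames(5, 1)$stop, 5L)

  s3 <- split_frames(3, 5)
  expect_equal(s3$stop - s3$start, c(1L, 1L, 1L, 0L, 0L))

  # completeness: concatenated ranges reproduce 0..n-1 exactly once
  for (n_frames in c(1, 2, 7, 10, 23)) {
    for (n_workers in c(1, 2, 3, 8, 30)) {
      s <- split_frames(n_frames, n_workers)
      covered <- unlist(lapply(seq_len(nrow(s)), function(i) {
        if (s$start[i] < s$stop[i]) seq(s$start[i], s$stop[i] - 1L) else integer(0)
      }))
      expect_equal(covered, 0:(n_frames - 1))
    }
  }
  expect_error(split_frames(0, 3), class = "trajpka_value_error")
})

test_that("residue-name normalisation maps variants and is idempotent", {
  snap <- new_snapshot(tibble::tibble(
    atom_name = paste0("CA", 1:6),
    resname = c("ASH", "HID", "HIE", "HIP", "ALA", "CYX"),
    chain = "A", resid = 1:6,
    x = 1:6, y = 0, z = 0
  ))
  out <- normalize_residue_names(snap)
  expect_equal(out$resname, c("ASP", "HIS", "HIS", "HIS", "ALA", "CYS"))
  expect_identical(out[, c("x", "y", "z")], snap[, c("x", "y", "z")])
  expect_identical(normalize_residue_names(out), out)

  weird <- new_snapshot(tibble::tibble(
    atom_name = "C1", resname = "LIG", chain = "A", resid = 1L,
    x = 0, y = 0, z = 0
  ))
  expect_warning(out2 <- normalize_residue_names(weird),
                 class = "trajpka_unknown_resname")
  expect_equal(out2$resname, "LIG")
})

test_that("snapshot PDB writing round-trips at PDB precision", {
  one <- new_snapshot(tibble::tibble(
    atom_name = "CA", resname = "ALA", chain = "A", resid = 1L,
    x = 1, y = 2, z = 3
  ))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_snapshot_pdb(one, path)
  atom_line <- grep("^ATOM", readLines(path), value = TRUE)[1]
  expect_equal(as.numeric(substr(atom_line, 31, 38)), 1.000)
  expect_equal(as.numeric(substr(atom_line, 39, 46)), 2.000)
  expect_equal(as.numeric(substr(atom_line, 47, 54)), 3.000)

  pep <- generate_peptide(test_sequence, seed = 5)
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_snapshot_pdb(pep, path2)
  back <- read_snapshot_pdb(path2)
  expect_equal(nrow(back), nrow(pep))
  expect_equal(back$atom_name, pep$atom_name)
  expect_equal(back$resname, pep$resname)
  expect_equal(back$resid, pep$resid)
  expect_equal(as.matrix(back[, c("x", "y", "z")]),
               as.matrix(pep[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)

  far <- new_snapshot(tibble::tibble(
    atom_name = "CA", resname = "ALA", chain = "A", resid = 1L,
    x = 10000, y = 0, z = 0
  ))
  expect_error(write_snapshot_pdb(far, path), class = "trajpka_io_error")
})
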