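#' Construct a frame snapshot
#'
#' A snapshot is one trajectory frame represented as a tibble of atoms
#' (class `pka_snapshot`), the unit handed to per-structure pKa engines.
#' Rows are atoms in file order; the frame index (0-based) and time in
#' picoseconds travel as attributes.
#'
#' @param atoms A data frame with columns `atom_name`, `resname`, `chain`,
#'   `resid`, `x`, `y`, `z` and optionally `element` (inferred from the
#'   atom name when absent).
#' @param frame_index 0-based frame index within the trajectory.
#' @param time_ps Frame time in picoseconds (non-negative).
#' @return A `pka_snapshot` tibble.
#' @export
new_snapshot <- function(atoms, frame_index = 0L, time_ps = 0) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("atom_name", "resname", "chain", "resid", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("Snapshot atoms lack column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "trajpka_value_error"
    )
  }
  if (nrow(atoms) == 0) {
    rlang::abort("Snapshot must contain at least one atom",
                 class = "trajpka_value_error")
  }
  if (time_ps < 0) {
    rlang::abort("time_ps must be non-negative",
                 class = "trajpka_value_error")
  }
  if (!"element" %in% names(atoms)) {
    atoms$element <- element_from_name(atoms$atom_name)
  }
  atoms$resid <- as.integer(atoms$resid)
  dup <- atoms |>
    dplyr::count(.data$chain, .data$resid, .data$atom_name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(
      paste0("Duplicate atom name(s) within a residue: ",
             paste(res_label(dup$atom_name, dup$resid, dup$chain),
                   collapse = "; ")),
      class = "trajpka_value_error"
    )
  }
  structure(
    atoms,
    frame_index = as.integer(frame_index),
    time_ps = as.numeric(time_ps),
    class = c("pka_snapshot", class(tibble::tibble()))
  )
}

#' @export
print.pka_snapshot <- function(x, ...) {
  n_res <- nrow(unique(x[, c("chain", "resid")]))
  cat(sprintf("<pka_snapshot> frame %d, t = %g ps: %d atoms, %d residues\n",
              frame_index(x), frame_time(x), nrow(x), n_res))
  NextMethod()
}

#' Snapshot frame index and time
#'
#' @param snapshot A `pka_snapshot`.
#' @return `frame_index()` the 0-based frame index; `frame_time()` the frame
#'   time in picoseconds.
#' @export
frame_index <- function(snapshot) attr(snapshot, "frame_index")

#' @rdname frame_index
#' @export
frame_time <- function(snapshot) attr(snapshot, "time_ps")

#' Residues of a snapshot
#'
#' One row per residue in order of first appearance, with its label.
#'
#' @param snapshot A `pka_snapshot`.
#' @return A tibble with columns `chain`, `resid`, `resname`, `label`.
#' @export
snapshot_residues <- function(snapshot) {
  snapshot |>
    dplyr::distinct(.data$chain, .data$resid, .data$resname) |>
    dplyr::mutate(label = res_label(.data$resname, .data$resid, .data$chain))
}

#' Normalise residue names to engine-recognised forms
#'
#' Protonation-state variant names used by common force fields (`ASH`,
#' `GLH`, `HID`/`HIE`/`HIP`, `HSD`/`HSE`/`HSP`, `CYX`/`CYM`, `LYN`, `ARN`,
#' `TYM`) are mapped to the canonical names (`ASP`, `GLU`, `HIS`, `CYS`,
#' `LYS`, `ARG`, `TYR`) that single-structure pKa engines accept. Canonical
#' names and cap residues pass through unchanged; unrecognised names are
#' passed through with a warning. Coordinates are untouched and the mapping
#' is idempotent.
#'
#' @param snapshot A `pka_snapshot`.
#' @return The snapshot with normalised `resname` values.
#' @export
normalize_residue_names <- function(snapshot) {
  resname <- snapshot$resname
  hit <- resname %in% names(RESNAME_CONVERSION)
  resname[hit] <- RESNAME_CONVERSION[resname[hit]]
  unknown <- setdiff(unique(resname), c(CANONICAL_AA, CAP_RESIDUES))
  if (length(unknown) > 0) {
    rlang::warn(
      paste0("Unrecognised residue name(s) passed through unchanged: ",
             paste(unknown, collapse = ", ")),
      class = "trajpka_unknown_resname"
    )
  }
  snapshot$resname <- resname
  snapshot
}

#' Write a snapshot as a single-model PDB file
#'
#' ATOM records are written in the snapshot's atom order at standard PDB
#' precision (3 decimals, angstrom). This is the interchange format handed
#' to external per-structure engines.
#'
#' @param snapshot A `pka_snapshot`.
#' @param path Output file path.
#' @param b Optional per-atom temperature-factor values (recycled scalar or
#'   one per atom); defaults to 0.
#' @return `path`, invisibly.
#' @export
write_snapshot_pdb <- function(snapshot, path, b = 0) {
  if (nrow(snapshot) == 0) {
    rlang::abort("Cannot write an empty snapshot",
                 class = "trajpka_value_error")
  }
  xyz <- as.vector(t(as.matrix(snapshot[, c("x", "y", "z")])))
  if (any(abs(xyz) >= 10000)) {
    rlang::abort(
      "Coordinates exceed the PDB fixed-column width (|x| >= 10000 A)",
      class = "trajpka_io_error"
    )
  }
  if (!dir.exists(dirname(path))) {
    rlang::abort(paste0("Output directory does not exist: ", dirname(path)),
                 class = "trajpka_io_error")
  }
  b <- rep_len(b, nrow(snapshot))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = snapshot$resid, resid = snapshot$resname,
    eleno = seq_len(nrow(snapshot)), elety = snapshot$atom_name,
    chain = snapshot$chain, o = rep(1, nrow(snapshot)), b = b
  )
  invisible(path)
}

#' Read a single-model PDB file as a snapshot
#'
#' @param path PDB file path.
#' @param frame_index,time_ps Metadata recorded on the snapshot.
#' @return A `pka_snapshot`.
#' @export
read_snapshot_pdb <- function(path, frame_index = 0L, time_ps = 0) {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path),
                 class = "trajpka_input_error")
  }
  pdb <- bio3d::read.pdb(path)
  atoms_from_bio3d(pdb$atom, frame_index = frame_index, time_ps = time_ps)
}

atoms_from_bio3d <- function(atom_df, frame_index = 0L, time_ps = 0) {
  chain <- atom_df$chain
  chain[is.na(chain)] <- "A"
  new_snapshot(
    tibble::tibble(
      atom_name = atom_df$elety,
      resname = atom_df$resid,
      chain = chain,
      resid = as.integer(atom_df$resno),
      x = atom_df$x, y = atom_df$y, z = atom_df$z
    ),
    frame_index = frame_index, time_ps = time_ps
  )
}

# Heavy-atom centroid of a coordinate block.
heavy_centroid <- function(snapshot) {
  heavy <- snapshot[is_heavy_atom(snapshot$atom_name), , drop = FALSE]
  c(mean(heavy$x), mean(heavy$y), mean(heavy$z))
}

# Centroid of the backbone atoms (N, CA, C, O): invariant under side-chain
# pseudo-mutation, which only removes side-chain atoms.
backbone_centroid <- function(snapshot) {
  bb <- snapshot[snapshot$atom_name %in% c("N", "CA", "C", "O"), ,
                 drop = FALSE]
  if (nrow(bb) == 0) bb <- snapshot
  c(mean(bb$x), mean(bb$y), mean(bb$z))
}
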