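WATER_ION_RESNAMES <- c(
  "HOH", "WAT", "TIP3", "TIP4", "TIP5", "SPC", "SOL",
  "NA", "CL", "K", "MG", "ZN", "CA2", "NA+", "CL-", "POT", "SOD", "CLA"
)

#' Load a topology + trajectory ensemble
#'
#' Reads a topology (PDB) together with one or more trajectory files
#' (multi-model PDB or DCD), applies an optional frame stride, and returns
#' an ensemble handle from which individual frames can be extracted as
#' snapshots. Frames are concatenated across trajectory files in the order
#' given.
#'
#' Trajectory files in PDB format carry no time information, so frame times
#' are `frame_index * timestep_ps` (with `timestep_ps` defaulting to 1).
#'
#' @param topology_path Path to a PDB topology file.
#' @param trajectory_paths Character vector of trajectory files (multi-model
#'   PDB or DCD), read in order. Defaults to the topology itself, so a
#'   single multi-model PDB can serve as both.
#' @param stride Keep every `stride`-th stored frame (first frame always
#'   kept).
#' @param timestep_ps Time between consecutive stored frames, in
#'   picoseconds.
#' @param protein_only Drop water and ion residues before prediction
#'   (default `TRUE`).
#' @return A `pka_ensemble` object with fields `topology` (atom template),
#'   `xyz` (sampled frames x 3N coordinate matrix), `frame_indices`
#'   (0-based indices of the retained frames), `times` (ps), `stride`,
#'   `timestep_ps` and `n_frames`.
#' @export
load_ensemble <- function(topology_path, trajectory_paths = topology_path,
                          stride = 1L, timestep_ps = 1,
                          protein_only = TRUE) {
  if (stride < 1) {
    rlang::abort("stride must be >= 1", class = "trajpka_value_error")
  }
  for (p in c(topology_path, trajectory_paths)) {
    if (!file.exists(p)) {
      rlang::abort(paste0("File not found: ", p),
                   class = "trajpka_input_error")
    }
  }
  topo_pdb <- bio3d::read.pdb(topology_path, multi = FALSE)
  topo <- atoms_from_bio3d(topo_pdb$atom)
  n_atoms_topo <- nrow(topo)

  xyz <- do.call(rbind, lapply(trajectory_paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    m <- switch(ext,
      pdb = bio3d::read.pdb(p, multi = TRUE)$xyz,
      dcd = bio3d::read.dcd(p, verbose = FALSE),
      rlang::abort(
        paste0("Unsupported trajectory format: .", ext,
               " (supported: multi-model PDB, DCD)"),
        class = "trajpka_input_error"
      )
    )
    matrix(as.numeric(m), nrow = nrow(as.matrix(m)))
  }))

  if (ncol(xyz) != 3L * n_atoms_topo) {
    rlang::abort(
      sprintf(
        "Topology has %d atoms but trajectory frames have %d",
        n_atoms_topo, ncol(xyz) %/% 3L
      ),
      class = "trajpka_topology_error"
    )
  }
  if (nrow(xyz) == 0) {
    rlang::abort("Trajectory contains no frames",
                 class = "trajpka_empty_ensemble_error")
  }

  keep_atoms <- rep(TRUE, n_atoms_topo)
  if (protein_only) {
    keep_atoms <- !(topo$resname %in% WATER_ION_RESNAMES)
    if (!any(keep_atoms)) {
      rlang::abort("No protein atoms left after stripping waters/ions",
                   class = "trajpka_topology_error")
    }
  }
  if (!all(keep_atoms)) {
    col_idx <- rep((which(keep_atoms) - 1L) * 3L, each = 3L) + 1:3
    xyz <- xyz[, col_idx, drop = FALSE]
    topo <- new_snapshot(topo[keep_atoms, , drop = FALSE])
  }

  frame_indices <- seq(0L, nrow(xyz) - 1L, by = as.integer(stride))
  xyz <- xyz[frame_indices + 1L, , drop = FALSE]

  structure(
    list(
      topology = topo,
      xyz = xyz,
      frame_indices = frame_indices,
      times = frame_indices * timestep_ps,
      stride = as.integer(stride),
      timestep_ps = timestep_ps,
      n_frames = length(frame_indices),
      topology_path = topology_path,
      trajectory_paths = trajectory_paths
    ),
    class = "pka_ensemble"
  )
}

#' @export
print.pka_ensemble <- function(x, ...) {
  cat(sprintf(
    "<pka_ensemble> %d sampled frames (stride %d, dt %g ps), %d atoms\n",
    x$n_frames, x$stride, x$timestep_ps, nrow(x$topology)
  ))
  invisible(x)
}

#' Extract one frame of an ensemble as a snapshot
#'
#' @param ensemble A `pka_ensemble`.
#' @param position 1-based position among the sampled frames.
#' @return A `pka_snapshot` carrying the original 0-based frame index and
#'   frame time.
#' @export
get_frame <- function(ensemble, position) {
  if (position < 1 || position > ensemble$n_frames) {
    rlang::abort(
      sprintf("Frame position %d out of range 1..%d",
              position, ensemble$n_frames),
      class = "trajpka_value_error"
    )
  }
  atoms <- ensemble$topology
  coords <- matrix(ensemble$xyz[position, ], ncol = 3L, byrow = TRUE)
  atoms$x <- coords[, 1]
  atoms$y <- coords[, 2]
  atoms$z <- coords[, 3]
  new_snapshot(
    atoms,
    frame_index = ensemble$frame_indices[position],
    time_ps = ensemble$times[position]
  )
}

#' Split frames into contiguous worker ranges
#'
#' Partitions `0..n_frames-1` into `n_workers` contiguous, near-equal
#' blocks; earlier workers receive the remainder, and workers beyond the
#' frame count receive empty ranges. Contiguous blocks (rather than
#' round-robin) preserve trajectory locality per worker and make the merge
#' order trivial.
#'
#' @param n_frames Number of sampled frames (>= 1).
#' @param n_workers Number of workers (>= 1).
#' @return A tibble with one row per worker: `worker_id` (0-based), `start`
#'   (inclusive, 0-based) and `stop` (exclusive).
#' @export
#' @examples
#' split_frames(10, 3)
split_frames <- function(n_frames, n_workers) {
  if (n_frames < 1 || n_workers < 1) {
    rlang::abort("n_frames and n_workers must both be >= 1",
                 class = "trajpka_value_error")
  }
  base <- n_frames %/% n_workers
  extra <- n_frames %% n_workers
  sizes <- rep(base, n_workers) + (seq_len(n_workers) <= extra)
  stops <- cumsum(sizes)
  tibble::tibble(
    worker_id = seq_len(n_workers) - 1L,
    start = as.integer(stops - sizes),
    stop = as.integer(stops)
  )
}
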