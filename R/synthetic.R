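#' Generate a synthetic peptide structure
#'
#' Builds an extended-chain peptide with idealised geometry: consecutive
#' C-alpha atoms 3.8 angstrom apart along the x axis, backbone N/C/O at
#' fixed local offsets, and template side-chain heavy atoms stacked away
#' from the backbone. The goal is a chemically plausible, engine-parseable
#' structure, not a realistic fold. A small seeded jitter (< 0.005
#' angstrom) on side-chain atoms breaks exact degeneracies while keeping
#' the construction deterministic for a fixed seed.
#'
#' @param sequence One-letter amino-acid string (e.g. `"ADGKE"`).
#' @param chain Chain identifier.
#' @param seed Integer seed.
#' @return A `pka_snapshot`.
#' @export
#' @examples
#' pep <- generate_peptide("ADA")
#' snapshot_residues(pep)
generate_peptide <- function(sequence, chain = "A", seed = 1L) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(letters1, names(AA_1TO3))
  if (length(unknown) > 0 || length(letters1) == 0) {
    rlang::abort(
      paste0("Unknown amino-acid letter(s): ",
             paste(unknown, collapse = ", ")),
      class = "trajpka_value_error"
    )
  }
  resnames <- unname(AA_1TO3[letters1])
  set.seed(seed)
  rows <- list()
  for (i in seq_along(resnames)) {
    ca <- c(3.8 * (i - 1), 0, 0)
    backbone <- list(
      N = ca + c(-1.20, 0.84, 0.00),
      CA = ca,
      C = ca + c(1.06, 1.01, 0.05),
      O = ca + c(1.15, 2.24, 0.05)
    )
    sc_names <- SIDECHAIN_ATOMS[[resnames[i]]]
    side <- lapply(seq_along(sc_names), function(j) {
      jit <- stats::runif(3, -0.004, 0.004)
      ca + c(0.35 * sin(1.7 * j),
             -1.50 - 1.05 * (j - 1),
             0.55 * ((j %% 2) * 2 - 1)) + jit
    })
    names(side) <- sc_names
    coords <- c(backbone, side)
    if (i == length(resnames)) {
      coords$OXT <- ca + c(1.95, 0.35, 0.05)
    }
    rows[[i]] <- tibble::tibble(
      atom_name = names(coords),
      resname = resnames[i],
      chain = chain,
      resid = i,
      x = vapply(coords, `[`, 0, 1L),
      y = vapply(coords, `[`, 0, 2L),
      z = vapply(coords, `[`, 0, 3L)
    )
  }
  new_snapshot(dplyr::bind_rows(rows))
}

#' Generate a synthetic multi-model PDB trajectory
#'
#' Displaces the reference structure along per-atom fixed random unit
#' vectors with a coherent sinusoidal amplitude: frame k (0-based) is
#' `reference + amplitude * sin(2 pi k / n_frames) * u_atom`. The coherent
#' periodic motion gives the built-in engine's pKa series a deterministic
#' structure that correlation analyses can detect, unlike white noise.
#'
#' @param reference A `pka_snapshot`.
#' @param path Output multi-model PDB path.
#' @param n_frames Number of models.
#' @param amplitude Displacement amplitude in angstrom (>= 0).
#' @param seed Integer seed for the per-atom directions.
#' @return `path`, invisibly.
#' @export
generate_trajectory <- function(reference, path, n_frames = 10L,
                                amplitude = 1, seed = 1L) {
  if (amplitude < 0) {
    rlang::abort("amplitude must be >= 0", class = "trajpka_value_error")
  }
  n_atoms <- nrow(reference)
  set.seed(seed)
  u <- matrix(stats::rnorm(3L * n_atoms), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  base <- as.matrix(reference[, c("x", "y", "z")])
  xyz <- t(vapply(seq_len(n_frames) - 1L, function(k) {
    as.vector(t(base + amplitude * sin(2 * pi * k / n_frames) * u))
  }, numeric(3L * n_atoms)))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = reference$resid, resid = reference$resname,
    eleno = seq_len(n_atoms), elety = reference$atom_name,
    chain = reference$chain, o = rep(1, n_atoms), b = rep(0, n_atoms)
  )
  invisible(path)
}

#' Generate labelled Gaussian blob features
#'
#' A clustering test bed: `k` isotropic unit-variance Gaussian blobs in
#' `n_features` dimensions with centres `separation_sd` standard
#' deviations apart along the first axis, plus the generating labels for
#' Adjusted-Rand-Index evaluation. "Unit variance" is the blob's total
#' variance (isotropic covariance `I / n_features`), so the blob's overall
#' spread — and hence the meaning of a given centre separation — does not
#' change with the feature-space dimension.
#'
#' @param n_per_cluster Frames per blob.
#' @param k Number of blobs.
#' @param separation_sd Centre separation in within-blob standard
#'   deviations.
#' @param n_features Feature-space dimension.
#' @param seed Integer seed.
#' @return A list with `features` (a `feature_matrix` in synthetic feature
#'   space, ready for clustering) and `labels` (integer vector, 0-based).
#' @export
generate_blob_features <- function(n_per_cluster = 30L, k = 3L,
                                   separation_sd = 10, n_features = 3L,
                                   seed = 1L) {
  if (k < 1) rlang::abort("k must be >= 1", class = "trajpka_value_error")
  set.seed(seed)
  n <- n_per_cluster * k
  labels <- rep(seq_len(k) - 1L, each = n_per_cluster)
  centres <- matrix(0, k, n_features)
  centres[, 1] <- separation_sd * (seq_len(k) - 1L)
  vals <- centres[labels + 1L, , drop = FALSE] +
    matrix(stats::rnorm(n * n_features, sd = 1 / sqrt(n_features)),
           n, n_features)
  colnames(vals) <- paste0("f", seq_len(n_features))
  fm <- new_feature_matrix(
    dplyr::bind_cols(
      tibble::tibble(frame = seq_len(n) - 1L, time_ps = as.numeric(seq_len(n) - 1L)),
      tibble::as_tibble(vals)
    ),
    normalization = "synthetic"
  )
  list(features = fm, labels = labels)
}

#' Generate an engine-output fixture document
#'
#' Writes a text document in the empirical engine's output layout — a
#' per-group detail section carrying the buried percentage, followed by
#' the `SUMMARY OF THIS PREDICTION` section with pKa and model pKa — that
#' [parse_propka_output()] round-trips exactly.
#'
#' @param entries Tibble with columns `resname`, `resid`, `chain`, `pka`,
#'   `model_pka` and optionally `buried_pct`.
#' @return Character scalar: the document text.
#' @export
generate_engine_output_fixture <- function(entries) {
  entries <- tibble::as_tibble(entries)
  if (!"buried_pct" %in% names(entries)) entries$buried_pct <- NA_real_
  detail <- c(
    "DESOLVATION EFFECTS AND DETERMINANTS",
    "RESIDUE    pKa   BURIED",
    vapply(seq_len(nrow(entries)), function(i) {
      if (is.na(entries$buried_pct[i])) return("")
      sprintf("%4s%4d %s  %6.2f   %3d %%",
              entries$resname[i], entries$resid[i], entries$chain[i],
              entries$pka[i], as.integer(round(entries$buried_pct[i])))
    }, "")
  )
  summary <- c(
    paste(rep("-", 80), collapse = ""),
    "SUMMARY OF THIS PREDICTION",
    "       Group      pKa  model-pKa   ligand atom-type",
    vapply(seq_len(nrow(entries)), function(i) {
      sprintf("%7s%4d %s%9.2f%11.2f",
              entries$resname[i], entries$resid[i], entries$chain[i],
              entries$pka[i], entries$model_pka[i])
    }, "")
  )
  paste(c(detail, summary, ""), collapse = "\n")
}
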