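#' Map per-residue scalar values onto a reference structure
#'
#' Builds a residue-to-value map for structure visualisation: each valued
#' residue's scalar (a single-frame pKa, a trajectory-mean pKa, a
#' deviation from the model value, or a buried ratio) will be written into
#' the temperature-factor column of every atom of that residue.
#'
#' @param snapshot Reference `pka_snapshot` the values are mapped onto.
#' @param values Named numeric vector keyed by residue label
#'   (`"RESNAME RESID CHAIN"`).
#' @param kind One of `"pka_frame"`, `"pka_mean"`, `"delta_model"`,
#'   `"buried"`.
#' @param unmapped_fill Value written for residues without an entry;
#'   defaults to the midpoint of the value range (0 for delta maps), a
#'   neutral rendering.
#' @return A `residue_value_map` object.
#' @export
residue_value_map <- function(snapshot, values,
                              kind = c("pka_frame", "pka_mean",
                                       "delta_model", "buried"),
                              unmapped_fill = NULL) {
  kind <- match.arg(kind)
  values <- values[!is.na(values)]
  res <- snapshot_residues(snapshot)
  missing_res <- setdiff(names(values), res$label)
  if (length(missing_res) > 0) {
    rlang::abort(
      paste0("Valued residue(s) absent from the reference structure: ",
             paste(missing_res, collapse = ", ")),
      class = "trajpka_value_error"
    )
  }
  if (is.null(unmapped_fill)) {
    unmapped_fill <- if (kind == "delta_model" || length(values) == 0) 0 else
      (min(values) + max(values)) / 2
  }
  structure(
    list(snapshot = snapshot, values = values, kind = kind,
         unmapped_fill = unmapped_fill),
    class = "residue_value_map"
  )
}

#' Map mean-vs-model pKa deviations onto a structure
#'
#' Values are `mean - model_pka` per residue, the shift of the trajectory
#' average from the engine's reference value. Residues whose summary lacks
#' a model value are left unmapped with a warning.
#'
#' @param summary A per-residue summary from [summarize_pka()].
#' @param snapshot Reference `pka_snapshot`.
#' @param unmapped_fill Fill value for unmapped residues (default 0).
#' @return A `residue_value_map` with `kind = "delta_model"`.
#' @export
delta_from_model_map <- function(summary, snapshot, unmapped_fill = 0) {
  no_model <- is.na(summary$delta_model) & !is.na(summary$mean)
  if (any(no_model)) {
    rlang::warn(paste0(
      "No model pKa for residue(s), left unmapped: ",
      paste(summary$residue[no_model], collapse = ", ")
    ))
  }
  vals <- stats::setNames(summary$delta_model, summary$residue)
  residue_value_map(snapshot, vals[!is.na(vals)], kind = "delta_model",
                    unmapped_fill = unmapped_fill)
}

#' Write an annotated structure plus a colouring command script
#'
#' Writes the reference structure as a PDB whose per-atom temperature
#' factor (B-factor) carries the residue's mapped value — the same value
#' on every atom of a residue, `unmapped_fill` elsewhere — together with a
#' plain-text `.pml`-style command script that, executed in a molecular
#' viewer, loads the PDB and applies a colour spectrum over the written
#' value range (a blue-white-red spectrum, centred at 0 for delta maps).
#'
#' @param map A [residue_value_map()].
#' @param out_path Output PDB path; the script is written next to it with
#'   extension `.pml`.
#' @return Tibble of the written paths, invisibly.
#' @export
write_annotated_structure <- function(map, out_path) {
  all_vals <- c(map$values, map$unmapped_fill)
  if (any(abs(all_vals) >= 1000)) {
    rlang::abort(
      "Mapped value exceeds the PDB B-factor column width (|v| >= 1000)",
      class = "trajpka_value_error"
    )
  }
  snap <- map$snapshot
  label <- res_label(snap$resname, snap$resid, snap$chain)
  b <- unname(map$values[label])
  b[is.na(b)] <- map$unmapped_fill
  write_snapshot_pdb(snap, out_path, b = b)

  lo <- min(all_vals)
  hi <- max(all_vals)
  if (map$kind == "delta_model") {
    half <- max(abs(c(lo, hi)), 1e-6)
    lo <- -half
    hi <- half
  }
  if (hi <= lo) hi <- lo + 1e-6
  script_path <- sub("\\.pdb$", ".pml", out_path)
  writeLines(c(
    sprintf("# trajpka %s value map (%s)",
            as.character(utils::packageVersion("trajpka")), map$kind),
    sprintf("load %s, mapped", basename(out_path)),
    "hide everything, mapped",
    "show cartoon, mapped",
    "show sticks, mapped and not (name C+N+O) and sidechain",
    sprintf("spectrum b, blue_white_red, mapped, minimum=%.3f, maximum=%.3f",
            lo, hi)
  ), script_path)
  invisible(tibble::tibble(pdb = out_path, script = script_path))
}

#' Read back the per-residue values of an annotated structure
#'
#' @param path Annotated PDB written by [write_annotated_structure()].
#' @return Tibble of `residue`, `value` (B-factor, one row per residue).
#' @export
read_annotated_values <- function(path) {
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom
  chain <- atoms$chain
  chain[is.na(chain)] <- "A"
  tibble::tibble(
    residue = res_label(atoms$resid, atoms$resno, chain),
    value = atoms$b
  ) |>
    dplyr::distinct(.data$residue, .keep_all = TRUE)
}
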