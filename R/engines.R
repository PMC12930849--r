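#' Specify the per-structure pKa engine
#'
#' Engines predict per-residue pKa values from a single structure. Three
#' are registered: `"propka"` (external empirical predictor, the default
#' for real work), `"pkai"` (external deep-learning predictor), and
#' `"mock"` (built-in deterministic engine used for testing and examples).
#' The external engines are driven through their command-line entry points
#' and must be on `PATH`; their energy models are never re-implemented
#' here. The buried ratio is only available from the empirical engine (and
#' the mock).
#'
#' @param engine One of `"mock"`, `"propka"`, `"pkai"`.
#' @param buried Request per-residue buried ratios (percent).
#' @param model_pka Named vector of reference pKa values used by the mock
#'   engine only; external engines report their own model values.
#' @param command Override the external engine executable name.
#' @return An `engine_spec` object.
#' @export
engine_spec <- function(engine = c("mock", "propka", "pkai"),
                        buried = TRUE, model_pka = MOCK_MODEL_PKA,
                        command = NULL) {
  engine <- match.arg(engine)
  if (buried && engine == "pkai") {
    rlang::abort(
      "Buried ratios are only available with the empirical engine (propka) or the mock engine",
      class = "trajpka_config_error"
    )
  }
  if (is.null(command)) {
    command <- switch(engine, propka = "propka3", pkai = "pKAI", mock = NULL)
  }
  structure(
    list(engine = engine, buried = buried, model_pka = model_pka,
         command = command),
    class = "engine_spec"
  )
}

#' Check that an engine is available
#'
#' The mock engine is always available; external engines require their
#' executable on `PATH`.
#'
#' @param spec An [engine_spec()] or engine name.
#' @return `TRUE`/`FALSE`.
#' @export
engine_available <- function(spec) {
  if (is.character(spec)) spec <- engine_spec(spec, buried = FALSE)
  if (spec$engine == "mock") return(TRUE)
  nzchar(Sys.which(spec$command))
}

assert_engine_available <- function(spec) {
  if (!engine_available(spec)) {
    rlang::abort(
      sprintf("Engine '%s' requested but executable '%s' is not on PATH",
              spec$engine, spec$command),
      class = "trajpka_config_error"
    )
  }
  invisible(spec)
}

#' Deterministic built-in pKa engine
#'
#' A test engine with a closed-form prediction: for each ionizable residue
#' i, `pka_i = model(resname) + 0.1 * d_i`, where `d_i` is the distance in
#' angstrom from the residue's heavy-atom centroid to the structure's
#' backbone-atom (N, CA, C, O) centroid, and
#' `buried_i = 100 * max(0, 1 - d_i / 20)`, clamped to \[0, 100\]. The
#' global reference is the backbone centroid — not the all-heavy-atom
#' centroid — so that it is invariant under side-chain truncation: a
#' residue's prediction depends only on its own atoms and the (mutation-
#' and engine-invariant) backbone, which makes pseudo-mutation locality
#' exactly checkable. The prediction is translation-invariant.
#'
#' @param snapshot A `pka_snapshot`.
#' @param model_pka Named vector of per-residue-type reference values.
#' @return A tibble with one row per ionizable residue: `label`, `resname`,
#'   `resid`, `chain`, `pka`, `model_pka`, `buried_pct`.
#' @export
mock_predict <- function(snapshot, model_pka = MOCK_MODEL_PKA) {
  if (nrow(snapshot) == 0) {
    rlang::abort("Empty snapshot", class = "trajpka_value_error")
  }
  global <- backbone_centroid(snapshot)
  heavy <- snapshot[is_heavy_atom(snapshot$atom_name), , drop = FALSE]
  ionizable <- heavy |>
    dplyr::filter(.data$resname %in% IONIZABLE_RESIDUES) |>
    dplyr::group_by(.data$chain, .data$resid, .data$resname) |>
    dplyr::summarise(
      d = sqrt((mean(.data$x) - global[1])^2 +
               (mean(.data$y) - global[2])^2 +
               (mean(.data$z) - global[3])^2),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chain, .data$resid)
  tibble::tibble(
    label = res_label(ionizable$resname, ionizable$resid, ionizable$chain),
    resname = ionizable$resname,
    resid = ionizable$resid,
    chain = ionizable$chain,
    pka = unname(model_pka[ionizable$resname]) + 0.1 * ionizable$d,
    model_pka = unname(model_pka[ionizable$resname]),
    buried_pct = pmin(100, pmax(0, 100 * (1 - ionizable$d / 20)))
  )
}

#' Parse the empirical engine's output document
#'
#' Extracts per-residue pKa and model pKa from the `SUMMARY OF THIS
#' PREDICTION` section and the buried ratio (percent) from the per-group
#' detail section. Groups are keyed by `(resname, resid, chain)`; chain
#' termini appear as resnames `N+` and `C-`.
#'
#' @param text The complete output document as a single string or a
#'   character vector of lines.
#' @return A tibble with columns `label`, `resname`, `resid`, `chain`,
#'   `pka`, `model_pka`, `buried_pct` (`NA` when the detail section lacks
#'   the group).
#' @export
parse_propka_output <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  summary_at <- grep("SUMMARY OF THIS PREDICTION", lines, fixed = TRUE)
  if (length(summary_at) == 0) {
    rlang::abort(
      "Engine output is missing the 'SUMMARY OF THIS PREDICTION' section",
      class = "trajpka_parse_error"
    )
  }
  group_re <- "^\\s*([A-Z][A-Za-z0-9]{0,2}|N\\+|C-)\\s+(\\d+)\\s+(\\S)\\s+"
  summary_re <- paste0(group_re, "(-?\\d+\\.\\d+)\\s+(-?\\d+\\.\\d+)")
  detail_re <- paste0(group_re, "(-?\\d+\\.\\d+)\\s+(\\d+)\\s*%")

  summary_lines <- lines[seq(summary_at[1] + 1L, length(lines))]
  hits <- regmatches(summary_lines, regexec(summary_re, summary_lines))
  hits <- hits[lengths(hits) == 6L]
  if (length(hits) == 0) {
    rlang::abort("No residue rows found in the prediction summary section",
                 class = "trajpka_parse_error")
  }
  res <- tibble::tibble(
    resname = vapply(hits, `[`, "", 2L),
    resid = as.integer(vapply(hits, `[`, "", 3L)),
    chain = vapply(hits, `[`, "", 4L),
    pka = as.numeric(vapply(hits, `[`, "", 5L)),
    model_pka = as.numeric(vapply(hits, `[`, "", 6L))
  )

  detail_lines <- lines[seq_len(summary_at[1] - 1L)]
  dhits <- regmatches(detail_lines, regexec(detail_re, detail_lines))
  dhits <- dhits[lengths(dhits) == 6L]
  buried <- tibble::tibble(
    resname = vapply(dhits, `[`, "", 2L),
    resid = as.integer(vapply(dhits, `[`, "", 3L)),
    chain = vapply(dhits, `[`, "", 4L),
    buried_pct = as.numeric(vapply(dhits, `[`, "", 6L))
  )
  res <- dplyr::left_join(res, buried,
                          by = c("resname", "resid", "chain"))
  res$label <- res_label(res$resname, res$resid, res$chain)
  res[, c("label", "resname", "resid", "chain",
          "pka", "model_pka", "buried_pct")]
}

run_external_engine <- function(snapshot, spec, workdir) {
  assert_engine_available(spec)
  pdb_path <- file.path(
    workdir, sprintf("trajpka_frame%06d.pdb", frame_index(snapshot))
  )
  write_snapshot_pdb(snapshot, pdb_path)
  out_path <- sub("\\.pdb$", ".pka", pdb_path)
  on.exit(unlink(c(pdb_path, out_path)), add = TRUE)
  if (spec$engine == "propka") {
    status <- system2(spec$command, shQuote(basename(pdb_path)),
                      stdout = FALSE, stderr = FALSE)
    # propka writes <name>.pka next to its working directory
    if (!file.exists(out_path)) {
      out_path2 <- file.path(getwd(), basename(out_path))
      if (file.exists(out_path2)) out_path <- out_path2
    }
    if (status != 0 || !file.exists(out_path)) {
      rlang::abort("Empirical engine failed on frame",
                   class = "trajpka_engine_error")
    }
    parse_propka_output(readLines(out_path, warn = FALSE))
  } else {
    out <- suppressWarnings(
      system2(spec$command, shQuote(pdb_path), stdout = TRUE, stderr = FALSE)
    )
    if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
      rlang::abort("Deep-learning engine failed on frame",
                   class = "trajpka_engine_error")
    }
    parse_pkai_output(out)
  }
}

# pKAI prints one line per residue: "CHAIN RESNAME RESID pKa"; model values
# are not part of its output, so the solution reference values are attached.
parse_pkai_output <- function(lines) {
  re <- "^\\s*(\\S)\\s+([A-Z]{3})\\s+(\\d+)\\s+(-?\\d+\\.\\d+)"
  hits <- regmatches(lines, regexec(re, lines))
  hits <- hits[lengths(hits) == 5L]
  if (length(hits) == 0) {
    rlang::abort("No residue rows found in engine output",
                 class = "trajpka_parse_error")
  }
  resname <- vapply(hits, `[`, "", 3L)
  resid <- as.integer(vapply(hits, `[`, "", 4L))
  chain <- vapply(hits, `[`, "", 2L)
  tibble::tibble(
    label = res_label(resname, resid, chain),
    resname = resname, resid = resid, chain = chain,
    pka = as.numeric(vapply(hits, `[`, "", 5L)),
    model_pka = unname(MOCK_MODEL_PKA[resname]),
    buried_pct = NA_real_
  )
}

#' Predict pKa values for one frame
#'
#' Runs the configured engine on a single (already normalised) snapshot.
#' External engines receive the snapshot as a temporary PDB file, which is
#' removed together with the engine's output after parsing.
#'
#' @param snapshot A `pka_snapshot`.
#' @param spec An [engine_spec()].
#' @param workdir Directory for temporary engine files.
#' @return A per-residue prediction tibble (see [mock_predict()]), with the
#'   frame index and time attached as attributes `frame_index`/`time_ps`.
#' @export
predict_frame <- function(snapshot, spec = engine_spec("mock"),
                          workdir = tempdir()) {
  entries <- if (spec$engine == "mock") {
    mock_predict(snapshot, spec$model_pka)
  } else {
    run_external_engine(snapshot, spec, workdir)
  }
  attr(entries, "frame_index") <- frame_index(snapshot)
  attr(entries, "time_ps") <- frame_time(snapshot)
  entries
}

#' Run the full per-frame prediction pipeline
#'
#' For every sampled frame: normalise residue names, optionally apply
#' alanine pseudo-mutations, predict with the configured engine, and parse
#' the result. Frames are split into contiguous worker ranges
#' ([split_frames()]); partial results are merged and sorted by frame time,
#' so the output is identical for any number of workers given a
#' deterministic engine. Frames on which the engine fails are logged in a
#' failure manifest and excluded; the run errors only if every frame fails.
#'
#' @param ensemble A `pka_ensemble`.
#' @param spec An [engine_spec()].
#' @param mutations Optional [mutation_spec()] (or `"CHAIN:RESID"` strings).
#' @param n_workers Number of worker ranges (>= 1).
#' @param workdir Directory for temporary engine files.
#' @return A `pka_run` list: `pka` (a `pka_table`), `buried` (a `pka_table`
#'   of buried percentages, or `NULL`), `failures` (tibble of
#'   `frame_index`, `message`), `engine`.
#' @export
run_prediction_pipeline <- function(ensemble, spec = engine_spec("mock"),
                                    mutations = NULL, n_workers = 1L,
                                    workdir = tempdir()) {
  assert_engine_available(spec)
  if (n_workers < 1) {
    rlang::abort("n_workers must be >= 1", class = "trajpka_value_error")
  }
  if (!is.null(mutations)) {
    if (!inherits(mutations, "mutation_spec")) {
      mutations <- mutation_spec(mutations)
    }
    validate_mutation_spec(mutations, ensemble$topology)
  }

  ranges <- split_frames(ensemble$n_frames, n_workers)
  process_range <- function(i) {
    start <- ranges$start[i]
    stop <- ranges$stop[i]
    if (start >= stop) return(list(results = list(), failures = NULL))
    results <- list()
    failures <- list()
    for (pos in seq(start + 1L, stop)) {
      snap <- normalize_residue_names(get_frame(ensemble, pos))
      if (!is.null(mutations)) {
        snap <- apply_alanine_mutation(snap, mutations)
      }
      res <- tryCatch(
        predict_frame(snap, spec, workdir),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <- tibble::tibble(
          frame_index = frame_index(snap),
          message = conditionMessage(res)
        )
      } else {
        results[[length(results) + 1L]] <- res
      }
    }
    list(results = results,
         failures = if (length(failures)) dplyr::bind_rows(failures))
  }
  parts <- lapply(seq_len(nrow(ranges)), process_range)

  all_results <- purrr::flatten(purrr::map(parts, "results"))
  failures <- dplyr::bind_rows(purrr::map(parts, "failures"))
  if (length(all_results) == 0) {
    rlang::abort("All frames failed in the engine",
                 class = "trajpka_pipeline_error")
  }
  if (nrow(failures) > 0) {
    rlang::warn(sprintf("%d frame(s) failed in the engine and were skipped",
                        nrow(failures)))
  }
  out <- merge_worker_outputs(all_results, buried = spec$buried)
  out$failures <- failures
  out$engine <- spec$engine
  class(out) <- "pka_run"
  out
}

#' Merge per-frame prediction results into tables
#'
#' Combines per-frame prediction tibbles (from any worker order) into wide
#' frames-by-residues tables sorted by frame time. The column set is the
#' union of residues seen in any frame; a residue an engine omitted in some
#' frame holds `NA` there.
#'
#' @param results List of per-frame prediction tibbles as returned by
#'   [predict_frame()].
#' @param buried Also build the buried-ratio table.
#' @return A list with `pka` (a `pka_table`) and `buried` (a `pka_table` or
#'   `NULL`).
#' @export
merge_worker_outputs <- function(results, buried = TRUE) {
  frames <- vapply(results, function(r) attr(r, "frame_index"), 0L)
  if (anyDuplicated(frames)) {
    rlang::abort(
      paste0("Duplicate frame index in worker outputs: ",
             paste(unique(frames[duplicated(frames)]), collapse = ", ")),
      class = "trajpka_merge_error"
    )
  }
  times <- vapply(results, function(r) attr(r, "time_ps"), 0)
  ord <- order(times, frames)
  results <- results[ord]

  long <- dplyr::bind_rows(lapply(results, function(r) {
    r$frame <- attr(r, "frame_index")
    r$time_ps <- attr(r, "time_ps")
    r
  }))
  res_order <- long |>
    dplyr::distinct(.data$label, .data$chain, .data$resid, .data$resname) |>
    dplyr::arrange(.data$chain, .data$resid, .data$resname)
  model_pka <- long |>
    dplyr::filter(!is.na(.data$model_pka)) |>
    dplyr::distinct(.data$label, .keep_all = TRUE)
  model_vec <- stats::setNames(model_pka$model_pka, model_pka$label)

  widen <- function(col) {
    long |>
      dplyr::select("frame", "time_ps", "label", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "label", values_from = dplyr::all_of(col)) |>
      dplyr::select("frame", "time_ps",
                    dplyr::any_of(res_order$label)) |>
      dplyr::arrange(.data$time_ps)
  }
  pka_tab <- new_pka_table(widen("pka"), model_pka = model_vec)
  buried_tab <- NULL
  if (buried && any(!is.na(long$buried_pct))) {
    buried_tab <- new_pka_table(widen("buried_pct"), model_pka = NULL)
  }
  list(pka = pka_tab, buried = buried_tab)
}

#' @export
print.pka_run <- function(x, ...) {
  cat(sprintf(
    "<pka_run> engine %s: %d frames x %d residues%s; %d failed frame(s)\n",
    x$engine, nrow(x$pka), length(residue_cols(x$pka)),
    if (!is.null(x$buried)) " (+ buried ratios)" else "",
    if (is.null(x$failures)) 0L else nrow(x$failures)
  ))
  invisible(x)
}
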