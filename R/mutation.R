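#' Specify residues to pseudo-mutate to alanine
#'
#' Builds a validated mutation specification from `"CHAIN:RESID"` strings
#' (e.g. `"A:44"`). Pseudo-mutation truncates a residue's side chain to the
#' alanine atom set in place, without touching any other coordinate; it
#' probes a neighbour's contribution to pKa shifts in the original
#' ensemble, and is not a mutant pKa estimate.
#'
#' @param targets Character vector of `"CHAIN:RESID"` strings, or a data
#'   frame with columns `chain` and `resid`.
#' @param snapshot Optional reference `pka_snapshot`; when given, every
#'   target is checked to exist and not to be glycine (which lacks the CB
#'   that alanine requires).
#' @return A tibble with columns `chain` and `resid`, class `mutation_spec`.
#' @export
#' @examples
#' mutation_spec(c("A:44", "A:59"))
mutation_spec <- function(targets, snapshot = NULL) {
  if (is.data.frame(targets)) {
    spec <- tibble::as_tibble(targets[, c("chain", "resid")])
  } else {
    parts <- strsplit(targets, ":", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) {
      rlang::abort(
        paste0("Malformed mutation target(s): ",
               paste(targets[bad], collapse = ", "),
               " (expected \"CHAIN:RESID\")"),
        class = "trajpka_value_error"
      )
    }
    spec <- tibble::tibble(
      chain = vapply(parts, `[`, "", 1L),
      resid = as.integer(vapply(parts, `[`, "", 2L))
    )
  }
  spec <- dplyr::distinct(spec)
  if (!is.null(snapshot)) {
    validate_mutation_spec(spec, snapshot)
  }
  structure(spec, class = c("mutation_spec", class(tibble::tibble())))
}

validate_mutation_spec <- function(spec, snapshot) {
  res <- snapshot_residues(snapshot)
  for (i in seq_len(nrow(spec))) {
    hit <- res$chain == spec$chain[i] & res$resid == spec$resid[i]
    if (!any(hit)) {
      rlang::abort(
        sprintf("Mutation target %s:%d not found in structure",
                spec$chain[i], spec$resid[i]),
        class = "trajpka_lookup_error"
      )
    }
    if (any(res$resname[hit] == "GLY")) {
      rlang::abort(
        sprintf(
          "Cannot pseudo-mutate GLY %d %s to alanine (glycine has no CB)",
          spec$resid[i], spec$chain[i]
        ),
        class = "trajpka_unsupported_mutation_error"
      )
    }
  }
  invisible(spec)
}

#' Apply alanine pseudo-mutations to a snapshot
#'
#' Each target residue is truncated to the alanine atom set
#' `{N, CA, C, O, CB}` (plus backbone/beta hydrogens and OXT when present)
#' with its original coordinates, and renamed `ALA`. Every atom outside the
#' targets is untouched, including its stored coordinates, and atom order
#' is preserved. No CB reconstruction or minimisation is performed.
#' Proline is allowed (its ring atoms CG, CD are removed); glycine is
#' rejected.
#'
#' @param snapshot A `pka_snapshot`.
#' @param spec A [mutation_spec()] (or input accepted by it).
#' @return The mutated `pka_snapshot`.
#' @export
apply_alanine_mutation <- function(snapshot, spec) {
  if (!inherits(spec, "mutation_spec")) {
    spec <- mutation_spec(spec)
  }
  validate_mutation_spec(spec, snapshot)
  target_key <- paste(spec$chain, spec$resid)
  atom_key <- paste(snapshot$chain, snapshot$resid)
  in_target <- atom_key %in% target_key
  drop <- in_target & !(snapshot$atom_name %in% ALANINE_KEEP_ATOMS)
  out <- snapshot[!drop, , drop = FALSE]
  out$resname[paste(out$chain, out$resid) %in% target_key] <- "ALA"
  new_snapshot(out, frame_index = frame_index(snapshot),
               time_ps = frame_time(snapshot))
}
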