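#' Construct a frames-by-residues pKa table
#'
#' The central tabular container: a wide tibble with one row per sampled
#' frame, columns `frame` (0-based index), `time_ps` (strictly increasing)
#' and one column per ionizable residue named `"RESNAME RESID CHAIN"`.
#' Per-residue engine model pKa values travel in the `model_pka` attribute.
#' The same container holds buried-ratio tables (percent values, no model).
#'
#' @param data A data frame with columns `frame`, `time_ps` and residue
#'   columns.
#' @param model_pka Named numeric vector of reference model pKa values
#'   keyed by residue label, or `NULL`.
#' @return A `pka_table` tibble.
#' @export
new_pka_table <- function(data, model_pka = NULL) {
  data <- tibble::as_tibble(data)
  if (!all(c("frame", "time_ps") %in% names(data))) {
    rlang::abort("A pka_table needs 'frame' and 'time_ps' columns",
                 class = "trajpka_value_error")
  }
  if (is.unsorted(data$time_ps, strictly = TRUE)) {
    rlang::abort("Frame times must be strictly increasing",
                 class = "trajpka_value_error")
  }
  structure(
    data,
    model_pka = model_pka,
    class = c("pka_table", class(tibble::tibble()))
  )
}

#' Residue columns of a pKa table
#'
#' @param table A `pka_table`.
#' @return Character vector of residue labels (all non-metadata columns).
#' @export
residue_cols <- function(table) {
  setdiff(names(table), c("frame", "time_ps", "replica"))
}

#' Model pKa values of a table
#'
#' @param table A `pka_table`.
#' @return Named numeric vector keyed by residue label (possibly `NULL`).
#' @export
model_pka <- function(table) attr(table, "model_pka")

#' Pivot a pKa table to long format
#'
#' @param table A `pka_table`.
#' @return A tibble with columns `frame`, `time_ps`, `residue`, `pka`
#'   (plus `model_pka` when known).
#' @export
pka_long <- function(table) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(table),
    cols = dplyr::all_of(residue_cols(table)),
    names_to = "residue", values_to = "pka"
  )
  mp <- model_pka(table)
  if (!is.null(mp)) {
    long$model_pka <- unname(mp[long$residue])
  }
  long
}

#' Write / read the wide CSV interchange format
#'
#' The CSV carries comment header lines (prefixed `#`) recording the
#' package version, the engine and the model pKa values, followed by a
#' wide table with `frame`, `time_ps` and one column per residue.
#'
#' @param table A `pka_table`.
#' @param path Output/input CSV path.
#' @param comment Extra header comment lines (without the `#`).
#' @return `write_pka_csv()` returns `path` invisibly; `read_pka_csv()`
#'   returns a `pka_table`.
#' @export
write_pka_csv <- function(table, path, comment = character(0)) {
  header <- c(
    sprintf("# trajpka %s", as.character(utils::packageVersion("trajpka"))),
    paste0("# ", comment)[length(comment) > 0]
  )
  mp <- model_pka(table)
  if (!is.null(mp) && length(mp) > 0) {
    header <- c(header, paste0(
      "# model_pka: ",
      paste(sprintf("%s=%g", names(mp), mp), collapse = "; ")
    ))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(tibble::as_tibble(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pka_csv
#' @export
read_pka_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  data <- utils::read.csv(text = paste(body, collapse = "\n"),
                          check.names = FALSE)
  mp <- NULL
  mp_line <- grep("^# model_pka:", header, value = TRUE)
  if (length(mp_line) == 1) {
    pairs <- strsplit(sub("^# model_pka:\\s*", "", mp_line), ";\\s*")[[1]]
    kv <- strsplit(pairs, "=", fixed = TRUE)
    mp <- stats::setNames(
      as.numeric(vapply(kv, `[`, "", 2L)),
      vapply(kv, `[`, "", 1L)
    )
  }
  new_pka_table(data, model_pka = mp)
}
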