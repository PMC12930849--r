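#' Centered running average
#'
#' Moving mean with a centered window of `window` frames; at the series
#' edges the window is clipped to the available points, so the output has
#' the same length as the input. The transform is shift-equivariant:
#' adding a constant to the series adds it to the average.
#'
#' @param series Numeric vector.
#' @param window Window length in frames; >= 1, odd (even values are
#'   rounded up to the next odd number with a warning so the window stays
#'   centered).
#' @return Numeric vector, same length as `series`.
#' @export
#' @examples
#' running_average(c(1, 2, 3, 4, 5), 3)
running_average <- function(series, window) {
  n <- length(series)
  if (window < 1) {
    rlang::abort("window must be >= 1", class = "trajpka_value_error")
  }
  if (window > n) {
    rlang::abort("window larger than the series",
                 class = "trajpka_value_error")
  }
  if (window %% 2 == 0) {
    window <- window + 1
    rlang::warn(sprintf("Even window rounded up to %d to keep it centered",
                        window))
  }
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    mean(series[max(1, i - half):min(n, i + half)])
  }, 0)
}

#' Convert a time window to an odd frame count
#'
#' Translates a running-average window given as a time span (e.g. 5 ns)
#' into a frame count using the sampling timestep, rounding even results up
#' to the next odd number.
#'
#' @param window_ps Window length in picoseconds.
#' @param timestep_ps Time between sampled frames, in picoseconds.
#' @return Odd integer frame count (>= 1).
#' @export
window_frames <- function(window_ps, timestep_ps) {
  w <- max(1L, as.integer(round(window_ps / timestep_ps)))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

#' Per-residue summary statistics
#'
#' Mean, standard deviation, minimum and maximum pKa per residue over
#' non-missing frames, plus the shift of the mean from the engine's model
#' value (`delta_model = mean - model_pka`).
#'
#' @param table A `pka_table`.
#' @return A tibble with one row per residue: `residue`, `n`, `mean`, `sd`,
#'   `min`, `max`, `model_pka`, `delta_model`. Residues with no finite
#'   frames have `NA` statistics.
#' @export
summarize_pka <- function(table) {
  if (nrow(table) < 1) {
    rlang::abort("Need at least one frame", class = "trajpka_value_error")
  }
  out <- pka_long(table) |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(
      n = sum(!is.na(.data$pka)),
      mean = if (any(!is.na(.data$pka))) mean(.data$pka, na.rm = TRUE) else NA_real_,
      sd = if (sum(!is.na(.data$pka)) > 1) stats::sd(.data$pka, na.rm = TRUE) else
        if (sum(!is.na(.data$pka)) == 1) 0 else NA_real_,
      min = if (any(!is.na(.data$pka))) min(.data$pka, na.rm = TRUE) else NA_real_,
      max = if (any(!is.na(.data$pka))) max(.data$pka, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
  mp <- model_pka(table)
  out$model_pka <- if (is.null(mp)) NA_real_ else unname(mp[out$residue])
  out$delta_model <- out$mean - out$model_pka
  # preserve table column order
  out[match(residue_cols(table), out$residue), , drop = FALSE]
}

#' Per-residue pKa histograms
#'
#' Bins each residue's pKa values into left-closed, right-open bins of
#' width `bin_width` aligned at 0 (bin edges are multiples of the width),
#' matching the binning used in per-residue distribution strips. Counts
#' sum to the number of non-missing frames.
#'
#' @param table A `pka_table`.
#' @param bin_width Bin width in pKa units (> 0).
#' @return A tibble with columns `residue`, `bin_left`, `bin_right`,
#'   `count`.
#' @export
pka_distribution <- function(table, bin_width = 0.1) {
  if (bin_width <= 0) {
    rlang::abort("bin_width must be > 0", class = "trajpka_value_error")
  }
  pka_long(table) |>
    dplyr::filter(!is.na(.data$pka)) |>
    dplyr::mutate(bin = floor(.data$pka / bin_width)) |>
    dplyr::count(.data$residue, .data$bin, name = "count") |>
    dplyr::mutate(
      bin_left = .data$bin * bin_width,
      bin_right = (.data$bin + 1) * bin_width
    ) |>
    dplyr::select("residue", "bin_left", "bin_right", "count")
}

#' Scan residues for pKa / property correlations
#'
#' Computes the correlation coefficient between every residue's pKa series
#' and each user-supplied time-dependent property (typically projections of
#' the trajectory on principal components, which represent collective
#' motions). Property series are matched to frames by row order when the
#' lengths agree, else by nearest frame time within half a timestep.
#' Zero-variance series give a missing coefficient, never 0.
#'
#' @param table A `pka_table`.
#' @param properties A data frame of property columns (optionally with a
#'   `time_ps` column used for nearest-time matching), or a numeric vector.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param threshold Absolute-coefficient threshold for the `flagged`
#'   column.
#' @return A tibble sorted by descending `|correlation|`: `residue`,
#'   `property`, `correlation`, `n`, `flagged`.
#' @export
correlation_scan <- function(table, properties, method = c("pearson", "spearman"),
                             threshold = 0.5) {
  method <- match.arg(method)
  if (is.numeric(properties) && is.null(dim(properties))) {
    properties <- tibble::tibble(property1 = properties)
  }
  properties <- tibble::as_tibble(properties)
  if (nrow(properties) != nrow(table)) {
    if (!"time_ps" %in% names(properties)) {
      rlang::abort(
        sprintf(
          "Property series has %d rows but the table has %d frames (and no time_ps column to resample by)",
          nrow(properties), nrow(table)
        ),
        class = "trajpka_value_error"
      )
    }
    dt <- if (nrow(table) > 1) min(diff(table$time_ps)) else 1
    idx <- vapply(table$time_ps, function(t) {
      j <- which.min(abs(properties$time_ps - t))
      if (abs(properties$time_ps[j] - t) > dt / 2) NA_integer_ else j
    }, 0L)
    if (anyNA(idx)) {
      rlang::abort(
        "Property series cannot be matched to frame times within half a timestep",
        class = "trajpka_value_error"
      )
    }
    properties <- properties[idx, , drop = FALSE]
  }
  prop_cols <- setdiff(names(properties), "time_ps")

  out <- tidyr::expand_grid(
    residue = residue_cols(table),
    property = prop_cols
  )
  out <- out |>
    dplyr::mutate(purrr::map2_dfr(.data$residue, .data$property, function(r, p) {
      x <- properties[[p]]
      y <- table[[r]]
      ok <- !is.na(x) & !is.na(y)
      r_val <- if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        NA_real_
      } else {
        stats::cor(x[ok], y[ok], method = method)
      }
      tibble::tibble(correlation = r_val, n = sum(ok))
    })) |>
    dplyr::mutate(flagged = !is.na(.data$correlation) &
                    abs(.data$correlation) >= threshold) |>
    dplyr::arrange(dplyr::desc(abs(.data$correlation)))
  out
}

#' Flag residues sensitive to protonation at a reference pH
#'
#' For each residue, the fraction of frames whose predicted pKa lies within
#' `reference_ph +/- half_width` — the range over which both protonation
#' states retain significant populations (at +/- 1 pKa unit, between 10%
#' and 90% protonated). Residues with a non-zero fraction are returned,
#' sorted by descending fraction; they are candidates for alternative fixed
#' protonation states or constant-pH simulation.
#'
#' @param table A `pka_table`.
#' @param reference_ph Reference pH (default 7.4, physiological).
#' @param half_width Half-width of the sensitivity window in pKa units
#'   (> 0, default 1).
#' @return A tibble with columns `residue`, `fraction`, `n_in_window`, `n`.
#' @export
flag_protonation_sensitive <- function(table, reference_ph = 7.4,
                                       half_width = 1) {
  if (half_width <= 0) {
    rlang::abort("half_width must be > 0", class = "trajpka_value_error")
  }
  lo <- reference_ph - half_width
  hi <- reference_ph + half_width
  pka_long(table) |>
    dplyr::filter(!is.na(.data$pka)) |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_in_window = sum(.data$pka >= lo & .data$pka <= hi),
      fraction = .data$n_in_window / .data$n,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$fraction > 0) |>
    dplyr::arrange(dplyr::desc(.data$fraction)) |>
    dplyr::select("residue", "fraction", "n_in_window", "n")
}

#' Average pKa values over replica trajectories
#'
#' Computes each residue's mean within every replica and the unweighted
#' cross-replica mean of those means. Residues absent from some replicas
#' are averaged over the replicas that report them and flagged.
#'
#' @param tables A list of `pka_table` objects (one per replica).
#' @return A tibble with `residue`, `mean` (cross-replica), `n_replicas`,
#'   `incomplete` (missing from at least one replica), and one
#'   `mean_replica<i>` column per replica.
#' @export
average_over_replicas <- function(tables) {
  if (!is.list(tables) || length(tables) == 0) {
    rlang::abort("Provide a non-empty list of pka_table objects",
                 class = "trajpka_value_error")
  }
  all_res <- unique(unlist(lapply(tables, residue_cols)))
  shared <- Reduce(intersect, lapply(tables, residue_cols))
  if (length(shared) == 0) {
    rlang::abort("Replica tables share no residue columns",
                 class = "trajpka_value_error")
  }
  per_replica <- purrr::imap(tables, function(tab, i) {
    s <- summarize_pka(tab)
    tibble::tibble(residue = s$residue,
                   !!paste0("mean_replica", i) := s$mean)
  })
  wide <- purrr::reduce(per_replica,
                        dplyr::full_join, by = "residue")
  means <- as.matrix(wide[, -1, drop = FALSE])
  tibble::tibble(
    residue = wide$residue,
    mean = rowMeans(means, na.rm = TRUE),
    n_replicas = rowSums(!is.na(means)),
    incomplete = rowSums(is.na(means)) > 0
  ) |>
    dplyr::bind_cols(wide[, -1, drop = FALSE]) |>
    dplyr::arrange(match(.data$residue, all_res))
}

#' Compare wild-type and pseudo-mutant pKa profiles
#'
#' Quantifies how a pseudo-mutation reshapes one residue's pKa time
#' evolution: the per-frame shift, its mean, and the fluctuation ratio
#' `sd(mutant) / sd(wild)`. A ratio below 1 means the mutation damps the
#' residue's pKa fluctuations (e.g. by removing an intermittent hydrogen
#' bond), beyond any uniform shift of the profile.
#'
#' @param wild,mutant `pka_table` objects on the same frame times.
#' @param residue Residue label (e.g. `"ASP 52 A"`) present in both.
#' @return A list of class `pka_profile_diff`: `residue`, `delta` (tibble
#'   of `frame`, `time_ps`, `delta_pka`), `mean_shift`,
#'   `fluctuation_ratio`.
#' @export
compare_mutant_profiles <- function(wild, mutant, residue) {
  if (nrow(wild) != nrow(mutant) ||
      !isTRUE(all.equal(wild$time_ps, mutant$time_ps))) {
    rlang::abort("Wild-type and mutant tables are on different time axes",
                 class = "trajpka_value_error")
  }
  for (tab in list(wild, mutant)) {
    if (!residue %in% residue_cols(tab)) {
      rlang::abort(paste0("Residue not present in both tables: ", residue),
                   class = "trajpka_value_error")
    }
  }
  w <- wild[[residue]]
  m <- mutant[[residue]]
  delta <- m - w
  sd_w <- stats::sd(w)
  structure(
    list(
      residue = residue,
      delta = tibble::tibble(frame = wild$frame, time_ps = wild$time_ps,
                             delta_pka = delta),
      mean_shift = mean(delta, na.rm = TRUE),
      fluctuation_ratio = if (isTRUE(sd_w > 0)) stats::sd(m) / sd_w else NA_real_
    ),
    class = "pka_profile_diff"
  )
}

#' @export
print.pka_profile_diff <- function(x, ...) {
  cat(sprintf(
    "<pka_profile_diff> %s: mean shift %+.3f, fluctuation ratio %.3f\n",
    x$residue, x$mean_shift, x$fluctuation_ratio
  ))
  invisible(x)
}
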