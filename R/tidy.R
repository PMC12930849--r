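#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a clustering result
#'
#' @param x A `pka_clusters` object.
#' @param ... Unused.
#' @return The per-frame label tibble (`frame`, `time_ps`, optional
#'   `replica`, `label`).
#' @export
tidy.pka_clusters <- function(x, ...) {
  x$labels
}

#' One-row summary of a clustering result
#'
#' @param x A `pka_clusters` object.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_clusters`, `n_noise`,
#'   `silhouette`, `seed`.
#' @export
glance.pka_clusters <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_clusters = x$n_clusters,
    n_noise = x$n_noise,
    silhouette = x$silhouette,
    seed = x$seed
  )
}

#' Tidy a prediction run
#'
#' @param x A `pka_run` object.
#' @param ... Unused.
#' @return The pKa table in long format (one row per frame and residue).
#' @export
tidy.pka_run <- function(x, ...) {
  pka_long(x$pka)
}

#' One-row summary of a prediction run
#'
#' @param x A `pka_run` object.
#' @param ... Unused.
#' @return A one-row tibble: `engine`, `n_frames`, `n_residues`,
#'   `n_failed`.
#' @export
glance.pka_run <- function(x, ...) {
  tibble::tibble(
    engine = x$engine,
    n_frames = nrow(x$pka),
    n_residues = length(residue_cols(x$pka)),
    n_failed = if (is.null(x$failures)) 0L else nrow(x$failures)
  )
}

#' Tidy a pseudo-mutant profile comparison
#'
#' @param x A `pka_profile_diff` object.
#' @param ... Unused.
#' @return The per-frame delta-pKa tibble.
#' @export
tidy.pka_profile_diff <- function(x, ...) {
  x$delta
}

#' One-row summary of a profile comparison
#'
#' @param x A `pka_profile_diff` object.
#' @param ... Unused.
#' @return A one-row tibble: `residue`, `mean_shift`, `fluctuation_ratio`.
#' @export
glance.pka_profile_diff <- function(x, ...) {
  tibble::tibble(
    residue = x$residue,
    mean_shift = x$mean_shift,
    fluctuation_ratio = x$fluctuation_ratio
  )
}
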