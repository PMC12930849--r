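#' Declare clustering feature descriptors
#'
#' Features describing the local environment of selected ionizable
#' residues: their predicted pKa values, optionally their buried ratios
#' (empirical engine only), and optionally inter-residue distances
#' (minimum heavy-atom distance, which captures contact formation such as
#' salt bridges).
#'
#' @param pka Character vector of residue labels whose pKa becomes a
#'   feature.
#' @param buried Character vector of residue labels whose buried ratio
#'   becomes a feature.
#' @param distances List of length-2 character vectors of residue labels;
#'   each pair becomes a minimum heavy-atom distance feature.
#' @return A tibble with columns `kind`, `res1`, `res2`, `name`.
#' @export
#' @examples
#' feature_descriptors(
#'   pka = c("GLU 35 A", "ASP 52 A"),
#'   distances = list(c("GLU 35 A", "ARG 114 A"))
#' )
feature_descriptors <- function(pka = character(0), buried = character(0),
                                distances = list()) {
  rows <- list()
  if (length(pka) > 0) {
    rows <- c(rows, list(tibble::tibble(
      kind = "pka", res1 = pka, res2 = NA_character_
    )))
  }
  if (length(buried) > 0) {
    rows <- c(rows, list(tibble::tibble(
      kind = "buried", res1 = buried, res2 = NA_character_
    )))
  }
  if (length(distances) > 0) {
    bad <- vapply(distances, function(p) length(p) != 2 || p[1] == p[2],
                  TRUE)
    if (any(bad)) {
      rlang::abort(
        "Each distance descriptor needs two distinct residue labels",
        class = "trajpka_value_error"
      )
    }
    rows <- c(rows, list(tibble::tibble(
      kind = "distance",
      res1 = vapply(distances, `[`, "", 1L),
      res2 = vapply(distances, `[`, "", 2L)
    )))
  }
  if (length(rows) == 0) {
    rlang::abort("At least one descriptor is required",
                 class = "trajpka_value_error")
  }
  out <- dplyr::bind_rows(rows)
  out$name <- ifelse(
    out$kind == "distance",
    paste0("dist:", out$res1, "|", out$res2),
    paste0(out$kind, ":", out$res1)
  )
  out
}

#' Minimum heavy-atom distance between two residues
#'
#' The closest approach (angstrom) between the heavy atoms of two
#' residues in one snapshot — the contact measure used for distance
#' features (it captures salt-bridge formation directly).
#'
#' @param snapshot A `pka_snapshot`.
#' @param label1,label2 Residue labels (`"RESNAME RESID CHAIN"`).
#' @return Distance in angstrom.
#' @export
min_heavy_distance <- function(snapshot, label1, label2) {
  pick <- function(lab) {
    key <- parse_res_label(lab)
    sel <- snapshot$chain == key$chain & snapshot$resid == key$resid &
      is_heavy_atom(snapshot$atom_name)
    if (!any(sel)) {
      rlang::abort(paste0("Residue not found in structure: ", lab),
                   class = "trajpka_value_error")
    }
    as.matrix(snapshot[sel, c("x", "y", "z")])
  }
  a <- pick(label1)
  b <- pick(label2)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Assemble the clustering feature matrix
#'
#' One column per descriptor over all frames: pKa and buried values are
#' pulled from their tables, distances are computed from the ensemble's
#' coordinates as the minimum heavy-atom distance (angstrom) between the
#' two residues in each frame. Frames with any missing value are dropped
#' with a message. Tables from several replicas can be concatenated first
#' (see [bind_replica_tables()]); the `replica` column, when present, is
#' carried through.
#'
#' @param pka A `pka_table`.
#' @param descriptors A [feature_descriptors()] tibble.
#' @param buried Optional buried-ratio `pka_table` (required by `buried`
#'   descriptors).
#' @param ensemble Optional `pka_ensemble` (required by `distance`
#'   descriptors); for multi-replica tables, a list of ensembles in
#'   replica order.
#' @return A `feature_matrix` tibble: `frame`, `time_ps` (and `replica` if
#'   present) plus one column per feature; attribute `normalization` is
#'   `"raw"`.
#' @export
build_feature_matrix <- function(pka, descriptors, buried = NULL,
                                 ensemble = NULL) {
  id_cols <- intersect(c("replica", "frame", "time_ps"), names(pka))
  out <- tibble::as_tibble(pka)[, id_cols, drop = FALSE]
  for (i in seq_len(nrow(descriptors))) {
    kind <- descriptors$kind[i]
    name <- descriptors$name[i]
    if (kind == "pka") {
      src <- pka
    } else if (kind == "buried") {
      if (is.null(buried)) {
        rlang::abort("Buried descriptors need a buried-ratio table",
                     class = "trajpka_value_error")
      }
      src <- buried
    }
    if (kind %in% c("pka", "buried")) {
      if (!descriptors$res1[i] %in% residue_cols(src)) {
        rlang::abort(paste0("Descriptor references unknown residue: ",
                            descriptors$res1[i]),
                     class = "trajpka_value_error")
      }
      out[[name]] <- src[[descriptors$res1[i]]]
    } else {
      if (is.null(ensemble)) {
        rlang::abort("Distance descriptors need the ensemble",
                     class = "trajpka_value_error")
      }
      ensembles <- if (inherits(ensemble, "pka_ensemble")) list(ensemble) else ensemble
      rep_id <- if ("replica" %in% names(out)) out$replica else rep(1L, nrow(out))
      rep_levels <- unique(rep_id)
      out[[name]] <- vapply(seq_len(nrow(out)), function(j) {
        ens <- ensembles[[match(rep_id[j], rep_levels)]]
        pos <- match(out$frame[j], ens$frame_indices)
        if (is.na(pos)) {
          rlang::abort(sprintf("Frame %d not present in the ensemble",
                               out$frame[j]),
                       class = "trajpka_value_error")
        }
        min_heavy_distance(get_frame(ens, pos),
                           descriptors$res1[i], descriptors$res2[i])
      }, 0)
    }
  }
  feat_cols <- setdiff(names(out), id_cols)
  complete <- stats::complete.cases(out[, feat_cols, drop = FALSE])
  if (!all(complete)) {
    rlang::inform(sprintf(
      "Dropped %d frame(s) with missing feature values", sum(!complete)
    ))
    out <- out[complete, , drop = FALSE]
  }
  new_feature_matrix(out, normalization = "raw")
}

new_feature_matrix <- function(data, normalization) {
  structure(
    tibble::as_tibble(data),
    normalization = normalization,
    class = c("feature_matrix", class(tibble::tibble()))
  )
}

feature_cols <- function(fm) {
  setdiff(names(fm), c("replica", "frame", "time_ps"))
}

#' Feature values of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @return Numeric matrix of the feature columns (metadata columns
#'   excluded).
#' @export
feature_values <- function(fm) {
  as.matrix(tibble::as_tibble(fm)[, feature_cols(fm), drop = FALSE])
}

#' Concatenate replica pKa tables for joint clustering
#'
#' Stacks frames from several replicas into one table, keeping
#' `(replica, frame)` provenance, so all trajectories are clustered
#' jointly.
#'
#' @param tables List of `pka_table` objects.
#' @return A `pka_table` with a leading `replica` column and a synthetic
#'   strictly increasing time axis offset per replica.
#' @export
bind_replica_tables <- function(tables) {
  offset <- 0
  parts <- purrr::imap(tables, function(tab, i) {
    d <- tibble::as_tibble(tab)
    d$replica <- i
    d$time_ps <- d$time_ps + offset
    offset <<- max(d$time_ps) + if (nrow(d) > 1) min(diff(tab$time_ps)) else 1
    d
  })
  merged <- dplyr::bind_rows(parts) |>
    dplyr::select("replica", "frame", "time_ps", dplyr::everything())
  new_pka_table(merged, model_pka = model_pka(tables[[1]]))
}

#' Z-score normalise a feature matrix
#'
#' Per-column `(x - mean) / sd` with the population standard deviation
#' (denominator `n`), so that features on different scales (pKa units,
#' percentages, angstrom) become commensurate before Euclidean clustering.
#' Constant columns are dropped with a warning.
#'
#' @param fm A `feature_matrix`.
#' @return A zscored `feature_matrix`.
#' @export
zscore_features <- function(fm) {
  vals <- feature_values(fm)
  mu <- colMeans(vals)
  sdev <- sqrt(colMeans(sweep(vals, 2, mu)^2))
  constant <- sdev == 0
  if (all(constant)) {
    rlang::abort("All feature columns are constant; nothing to cluster",
                 class = "trajpka_value_error")
  }
  if (any(constant)) {
    rlang::warn(paste0(
      "Dropped constant feature column(s): ",
      paste(colnames(vals)[constant], collapse = ", ")
    ))
  }
  keep <- colnames(vals)[!constant]
  z <- sweep(sweep(vals[, keep, drop = FALSE], 2, mu[keep]), 2,
             sdev[keep], "/")
  out <- tibble::as_tibble(fm)[, setdiff(names(fm), feature_cols(fm)),
                               drop = FALSE]
  out <- dplyr::bind_cols(out, tibble::as_tibble(z))
  new_feature_matrix(out, normalization = "zscored")
}

#' Reduce a feature matrix with PCA
#'
#' Projects the (z-scored) features onto leading principal components.
#' Either a fixed component count or the smallest count whose cumulative
#' explained variance reaches `variance_fraction` is retained.
#'
#' @param fm A zscored `feature_matrix`.
#' @param n_components Number of components to keep.
#' @param variance_fraction Alternatively, the cumulative
#'   explained-variance target in (0, 1].
#' @return A `feature_matrix` of component scores (`PC1`, `PC2`, ...);
#'   attributes `explained_variance` (per retained component) and
#'   `total_variance` record the decomposition.
#' @export
reduce_pca <- function(fm, n_components = NULL, variance_fraction = NULL) {
  if (!identical(attr(fm, "normalization"), "zscored")) {
    rlang::abort("PCA reduction expects a z-scored feature matrix",
                 class = "trajpka_value_error")
  }
  vals <- feature_values(fm)
  if (!is.null(n_components) && n_components > ncol(vals)) {
    rlang::abort(sprintf(
      "Requested %d components from a %d-column matrix",
      n_components, ncol(vals)
    ), class = "trajpka_value_error")
  }
  pc <- stats::prcomp(vals, center = TRUE, scale. = FALSE)
  var_expl <- pc$sdev^2
  if (is.null(n_components)) {
    if (is.null(variance_fraction)) {
      n_components <- ncol(vals)
    } else {
      cum <- cumsum(var_expl) / sum(var_expl)
      n_components <- which(cum >= variance_fraction - 1e-12)[1]
    }
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  out <- tibble::as_tibble(fm)[, setdiff(names(fm), feature_cols(fm)),
                               drop = FALSE]
  out <- dplyr::bind_cols(out, tibble::as_tibble(scores))
  fm2 <- new_feature_matrix(out, normalization = "pca")
  attr(fm2, "explained_variance") <- var_expl[seq_len(n_components)]
  attr(fm2, "total_variance") <- sum(var_expl)
  fm2
}
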