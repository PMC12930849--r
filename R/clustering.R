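#' Cluster trajectory frames in feature space
#'
#' Groups frames by the local environment of the selected ionizable
#' residues, using one of four algorithms in Euclidean normalised feature
#' space:
#'
#' * `"kmedoids"` — partitioning around medoids (`k` clusters); the
#'   representative of each cluster is its medoid frame.
#' * `"greedy"` — the leader algorithm: frames are scanned in time order
#'   and join the first cluster whose leader lies within `cutoff`, else
#'   found a new cluster; the leader frame is the representative.
#' * `"dbscan"` — density-based clustering with radius `eps` and
#'   `min_samples`; unassigned frames are noise (label -1).
#' * `"hdbscan"` — hierarchical density-based clustering with
#'   `min_cluster_size` (and optional `min_samples`), extracting the most
#'   stable clusters from the mutual-reachability hierarchy.
#'
#' For the density methods the representative is the frame nearest the
#' cluster's feature-space mean. Non-noise labels are contiguous integers
#' from 0; the mean silhouette width is computed over non-noise frames.
#'
#' @param fm A normalised `feature_matrix` (zscored or PCA scores).
#' @param method One of `"kmedoids"`, `"greedy"`, `"dbscan"`, `"hdbscan"`.
#' @param k Number of clusters (kmedoids).
#' @param cutoff Leader distance cutoff (greedy).
#' @param eps Neighbourhood radius (dbscan).
#' @param min_samples Density threshold (dbscan, hdbscan).
#' @param min_cluster_size Smallest allowed cluster (hdbscan).
#' @param seed Integer seed; recorded and applied so repeated calls give
#'   identical labels.
#' @return A `pka_clusters` object: `labels` (tibble of `frame`,
#'   `time_ps`, optional `replica`, `label`), `representatives` (tibble of
#'   `label`, `row`, `frame`, `time_ps`), `silhouette` (mean width, `NA`
#'   for a single cluster), `method`, `hyperparameters`, `n_noise`.
#' @export
cluster_frames <- function(fm, method = c("kmedoids", "greedy", "dbscan", "hdbscan"),
                           k = NULL, cutoff = NULL, eps = NULL,
                           min_samples = 5L, min_cluster_size = 5L,
                           seed = 1L) {
  method <- match.arg(method)
  if (identical(attr(fm, "normalization"), "raw")) {
    rlang::abort("Cluster on a normalised feature matrix (zscore_features() first)",
                 class = "trajpka_value_error")
  }
  vals <- feature_values(fm)
  n <- nrow(vals)
  set.seed(seed)

  res <- switch(method,
    kmedoids = {
      if (is.null(k)) rlang::abort("kmedoids needs k", class = "trajpka_value_error")
      if (k > n) {
        rlang::abort(sprintf("Requested %d clusters from %d frames", k, n),
                     class = "trajpka_value_error")
      }
      fit <- cluster::pam(vals, k = k, metric = "euclidean",
                          pamonce = FALSE)
      list(labels = fit$clustering - 1L, reps = as.integer(fit$id.med))
    },
    greedy = {
      if (is.null(cutoff)) {
        rlang::abort("greedy needs a cutoff", class = "trajpka_value_error")
      }
      leader_cluster(vals, cutoff)
    },
    dbscan = {
      if (is.null(eps)) rlang::abort("dbscan needs eps", class = "trajpka_value_error")
      lab <- dbscan_labels(vals, eps, min_samples)
      list(labels = lab, reps = NULL)
    },
    hdbscan = {
      lab <- hdbscan_labels(vals, min_cluster_size, min_samples)
      list(labels = lab, reps = NULL)
    }
  )

  labels <- relabel_contiguous(res$labels)
  non_noise <- labels >= 0
  if (!any(non_noise)) {
    rlang::abort("All frames were labelled noise (degenerate clustering)",
                 class = "trajpka_degenerate_error")
  }
  reps <- res$reps
  if (is.null(reps)) {
    reps <- vapply(sort(unique(labels[non_noise])), function(cl) {
      members <- which(labels == cl)
      centre <- colMeans(vals[members, , drop = FALSE])
      members[which.min(rowSums(sweep(vals[members, , drop = FALSE], 2,
                                      centre)^2))]
    }, 0L)
  } else {
    # order representatives by their cluster's (relabeled) id
    reps <- reps[order(labels[reps])]
  }

  sil <- mean_silhouette(vals, labels)

  id_cols <- intersect(c("replica", "frame", "time_ps"), names(fm))
  label_tab <- dplyr::bind_cols(
    tibble::as_tibble(fm)[, id_cols, drop = FALSE],
    tibble::tibble(label = labels)
  )
  rep_tab <- dplyr::bind_cols(
    tibble::tibble(label = labels[reps], row = as.integer(reps)),
    tibble::as_tibble(fm)[reps, id_cols, drop = FALSE]
  )
  hyper <- list(k = k, cutoff = cutoff, eps = eps,
                min_samples = min_samples,
                min_cluster_size = min_cluster_size)
  hyper <- hyper[!vapply(hyper, is.null, TRUE)]
  structure(
    list(
      labels = label_tab,
      representatives = rep_tab,
      silhouette = sil,
      n_clusters = length(unique(labels[non_noise])),
      n_noise = sum(!non_noise),
      method = method,
      hyperparameters = hyper,
      seed = seed
    ),
    class = "pka_clusters"
  )
}

relabel_contiguous <- function(labels) {
  non_noise <- labels >= 0
  seen <- unique(labels[non_noise])
  out <- labels
  out[non_noise] <- match(labels[non_noise], seen) - 1L
  as.integer(out)
}

mean_silhouette <- function(vals, labels) {
  keep <- labels >= 0
  lab <- labels[keep]
  if (length(unique(lab)) < 2) return(NA_real_)
  sil <- cluster::silhouette(lab + 1L, stats::dist(vals[keep, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

leader_cluster <- function(vals, cutoff) {
  n <- nrow(vals)
  labels <- integer(n)
  leaders <- 1L
  labels[1] <- 0L
  for (i in seq_len(n)[-1]) {
    d <- sqrt(rowSums(sweep(vals[leaders, , drop = FALSE], 2, vals[i, ])^2))
    hit <- which(d <= cutoff)
    if (length(hit) > 0) {
      labels[i] <- hit[1] - 1L
    } else {
      leaders <- c(leaders, i)
      labels[i] <- length(leaders) - 1L
    }
  }
  list(labels = labels, reps = leaders)
}

# Classic density-based clustering (Ester et al. scheme): core points have
# at least min_samples neighbours (self included) within eps; clusters grow
# by breadth-first expansion from core points; border points join the first
# cluster that reaches them; the rest is noise (-1).
dbscan_labels <- function(vals, eps, min_samples) {
  n <- nrow(vals)
  d <- as.matrix(stats::dist(vals))
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(neighbours) >= min_samples
  labels <- rep(-1L, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neighbours[[i]], i)
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) {
          queue <- c(queue, setdiff(neighbours[[j]],
                                    which(labels != -1L)))
          queue <- unique(queue)
        }
      }
    }
  }
  labels
}

# Hierarchical density-based clustering: core distances, mutual
# reachability, minimum spanning tree, single-linkage hierarchy, condensed
# tree at min_cluster_size, and excess-of-mass cluster extraction.
hdbscan_labels <- function(vals, min_cluster_size = 5L, min_samples = NULL,
                           allow_single_cluster = FALSE) {
  n <- nrow(vals)
  if (is.null(min_samples)) min_samples <- min_cluster_size
  min_samples <- min(min_samples, n - 1L)
  d <- as.matrix(stats::dist(vals))
  core <- apply(d, 1, function(row) sort(row[-1])[min_samples])
  mreach <- pmax(d, outer(core, core, pmax))
  diag(mreach) <- 0

  # Prim's minimum spanning tree on the mutual-reachability graph
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best <- mreach[1, ]
  best_from <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L)  # from, to, weight
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    edges[e, ] <- c(best_from[j], j, best[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & mreach[j, ] < best
    best[upd] <- mreach[j, upd]
    best_from[upd] <- j
  }
  edges <- edges[order(edges[, 3]), , drop = FALSE]

  # single-linkage hierarchy via union-find; node ids: 1..n points,
  # n+1..2n-1 internal merge nodes
  parent_uf <- seq_len(2L * n - 1L)
  find <- function(x) {
    while (parent_uf[x] != x) x <- parent_uf[x]
    x
  }
  node_children <- vector("list", 2L * n - 1L)
  node_dist <- numeric(2L * n - 1L)
  node_size <- c(rep(1L, n), integer(n - 1L))
  nxt <- n
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    nxt <- nxt + 1L
    node_children[[nxt]] <- c(a, b)
    node_dist[nxt] <- edges[e, 3]
    node_size[nxt] <- node_size[a] + node_size[b]
    parent_uf[a] <- nxt
    parent_uf[b] <- nxt
  }
  root <- nxt

  lambda_of <- function(dist) if (dist > 0) 1 / dist else Inf
  subtree_points <- function(node) {
    stack <- node
    pts <- integer(0)
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v <= n) pts <- c(pts, v) else stack <- c(stack, node_children[[v]])
    }
    pts
  }

  # condensed tree: clusters with birth lambda, point exit lambdas, children
  clusters <- list()
  new_cluster <- function(parent, birth) {
    clusters[[length(clusters) + 1L]] <<- list(
      parent = parent, birth = birth, exits_pt = integer(0),
      exits_lambda = numeric(0), children = integer(0)
    )
    id <- length(clusters)
    if (!is.na(parent)) {
      clusters[[parent]]$children <<- c(clusters[[parent]]$children, id)
    }
    id
  }
  root_cluster <- new_cluster(NA_integer_, 0)
  # iterative walk: (tree node, cluster id)
  stack <- list(list(node = root, cl = root_cluster))
  while (length(stack) > 0) {
    item <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- item$node
    cl <- item$cl
    if (node <= n) {
      clusters[[cl]]$exits_pt <- c(clusters[[cl]]$exits_pt, node)
      clusters[[cl]]$exits_lambda <- c(clusters[[cl]]$exits_lambda, Inf)
      next
    }
    ch <- node_children[[node]]
    lam <- lambda_of(node_dist[node])
    sizes <- node_size[ch]
    big <- sizes >= min_cluster_size
    if (all(big)) {
      for (c_node in ch) {
        stack[[length(stack) + 1L]] <-
          list(node = c_node, cl = new_cluster(cl, lam))
      }
    } else if (any(big)) {
      small_pts <- unlist(lapply(ch[!big], subtree_points))
      clusters[[cl]]$exits_pt <- c(clusters[[cl]]$exits_pt, small_pts)
      clusters[[cl]]$exits_lambda <-
        c(clusters[[cl]]$exits_lambda, rep(lam, length(small_pts)))
      stack[[length(stack) + 1L]] <- list(node = ch[big], cl = cl)
    } else {
      pts <- unlist(lapply(ch, subtree_points))
      clusters[[cl]]$exits_pt <- c(clusters[[cl]]$exits_pt, pts)
      clusters[[cl]]$exits_lambda <-
        c(clusters[[cl]]$exits_lambda, rep(lam, length(pts)))
    }
  }

  n_cl <- length(clusters)
  stability <- vapply(seq_len(n_cl), function(i) {
    lam <- clusters[[i]]$exits_lambda
    lam[!is.finite(lam)] <- max(c(1 / node_dist[node_dist > 0], 1))
    sum(lam - clusters[[i]]$birth)
  }, 0)

  # excess-of-mass selection, deepest clusters first
  depth <- integer(n_cl)
  for (i in seq_len(n_cl)) {
    p <- clusters[[i]]$parent
    depth[i] <- if (is.na(p)) 0L else depth[p] + 1L
  }
  selected <- vector("list", n_cl)
  subtree_stab <- numeric(n_cl)
  for (i in order(depth, decreasing = TRUE)) {
    ch <- clusters[[i]]$children
    child_sum <- sum(subtree_stab[ch])
    is_root <- is.na(clusters[[i]]$parent)
    if (length(ch) == 0 ||
        (stability[i] >= child_sum && !(is_root && !allow_single_cluster))) {
      selected[[i]] <- i
      subtree_stab[i] <- stability[i]
    } else {
      selected[[i]] <- unlist(selected[ch])
      subtree_stab[i] <- max(child_sum, stability[i])
    }
  }
  chosen <- selected[[root_cluster]]
  if (is.na(clusters[[root_cluster]]$parent) &&
      identical(chosen, root_cluster) && !allow_single_cluster) {
    chosen <- integer(0)
  }

  labels <- rep(-1L, n)
  if (length(chosen) > 0) {
    ancestor_sets <- lapply(chosen, function(cl) {
      # all clusters whose chain to the root passes through cl
      members <- cl
      repeat {
        more <- which(vapply(seq_len(n_cl), function(j) {
          !is.na(clusters[[j]]$parent) && clusters[[j]]$parent %in% members &&
            !(j %in% members)
        }, TRUE))
        if (length(more) == 0) break
        members <- c(members, more)
      }
      members
    })
    for (ci in seq_along(chosen)) {
      for (cl in ancestor_sets[[ci]]) {
        labels[clusters[[cl]]$exits_pt] <- ci - 1L
      }
    }
  }
  labels
}

#' Optimise clustering hyperparameters by silhouette grid search
#'
#' Evaluates [cluster_frames()] at every point of a hyperparameter grid
#' and returns the result with the highest mean silhouette width. Ties are
#' broken by fewer clusters, then by grid order. Results with more than
#' 50% noise frames are ranked below any cleaner result; grid points that
#' fail outright (degenerate clusterings) are recorded in the score table
#' and skipped.
#'
#' @param fm A normalised `feature_matrix`.
#' @param method Clustering method (see [cluster_frames()]).
#' @param grid A named list of hyperparameter value vectors, expanded to
#'   their full cross product (e.g. `list(k = 2:6)`).
#' @param seed Seed passed to every evaluation.
#' @return The winning `pka_clusters`, with the full score table as a
#'   tibble in `$score_table` (columns: the grid variables, `n_clusters`,
#'   `n_noise`, `silhouette`, `error`).
#' @export
grid_search_clusters <- function(fm, method, grid, seed = 1L) {
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    rlang::abort("Hyperparameter grid must be non-empty",
                 class = "trajpka_value_error")
  }
  points <- do.call(tidyr::expand_grid, grid)
  results <- vector("list", nrow(points))
  scores <- purrr::map_dfr(seq_len(nrow(points)), function(i) {
    args <- c(list(fm = fm, method = method, seed = seed),
              as.list(points[i, ]))
    res <- tryCatch(do.call(cluster_frames, args), error = function(e) e)
    if (inherits(res, "error")) {
      return(dplyr::bind_cols(points[i, ], tibble::tibble(
        n_clusters = NA_integer_, n_noise = NA_integer_,
        silhouette = NA_real_, error = conditionMessage(res)
      )))
    }
    results[[i]] <<- res
    dplyr::bind_cols(points[i, ], tibble::tibble(
      n_clusters = res$n_clusters, n_noise = res$n_noise,
      silhouette = res$silhouette, error = NA_character_
    ))
  })
  n_frames <- nrow(fm)
  ok <- which(is.na(scores$error) & !is.na(scores$silhouette))
  if (length(ok) == 0) {
    msgs <- paste0(
      "grid point ", seq_len(nrow(scores)), ": ",
      dplyr::coalesce(scores$error, "silhouette undefined (single cluster)")
    )
    rlang::abort(
      paste0("Every grid point was degenerate:\n",
             paste(msgs, collapse = "\n")),
      class = "trajpka_degenerate_error"
    )
  }
  high_noise <- scores$n_noise[ok] / n_frames > 0.5
  ranking <- ok[order(high_noise, -scores$silhouette[ok],
                      scores$n_clusters[ok], ok)]
  best <- results[[ranking[1]]]
  best$score_table <- scores
  best
}

#' Write cluster-representative structures
#'
#' One PDB file per non-noise cluster, named
#' `cluster<label>_frame<frame>.pdb`, with the coordinates of the
#' representative frame taken from the ensemble.
#'
#' @param clusters A `pka_clusters` result.
#' @param ensemble The `pka_ensemble` the frames came from (or a list of
#'   ensembles for multi-replica clusterings, indexed by `replica`).
#' @param out_dir Output directory (created if needed).
#' @return Tibble of `label`, `frame`, `path`, invisibly.
#' @export
extract_representatives <- function(clusters, ensemble, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reps <- clusters$representatives
  reps <- reps[reps$label >= 0, , drop = FALSE]
  ensembles <- if (inherits(ensemble, "pka_ensemble")) list(ensemble) else ensemble
  paths <- vapply(seq_len(nrow(reps)), function(i) {
    rep_id <- if ("replica" %in% names(reps)) reps$replica[i] else 1L
    ens <- ensembles[[rep_id]]
    pos <- match(reps$frame[i], ens$frame_indices)
    snap <- get_frame(ens, pos)
    path <- file.path(out_dir,
                      sprintf("cluster%d_frame%d.pdb",
                              reps$label[i], reps$frame[i]))
    write_snapshot_pdb(snap, path)
    path
  }, "")
  invisible(dplyr::bind_cols(reps[, c("label", "frame")],
                             tibble::tibble(path = paths)))
}

#' Write the per-frame cluster labels as CSV
#'
#' @param clusters A `pka_clusters` result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_csv <- function(clusters, path) {
  header <- c(
    sprintf("# trajpka %s", as.character(utils::packageVersion("trajpka"))),
    sprintf("# method=%s; seed=%d; silhouette=%s", clusters$method,
            clusters$seed, format(clusters$silhouette)),
    sprintf("# hyperparameters: %s",
            paste(names(clusters$hyperparameters),
                  unlist(clusters$hyperparameters),
                  sep = "=", collapse = "; "))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(clusters$labels, con, row.names = FALSE)
  invisible(path)
}

#' @export
print.pka_clusters <- function(x, ...) {
  cat(sprintf(
    "<pka_clusters> %s: %d cluster(s), %d noise frame(s), mean silhouette %s\n",
    x$method, x$n_clusters, x$n_noise,
    format(x$silhouette, digits = 3)
  ))
  invisible(x)
}
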