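test_that("feature matrices assemble pKa, buried and distance columns", {
  ens <- make_test_ensemble(n_frames = 10)
  run <- run_prediction_pipeline(ens, engine_spec("mock"))
  desc <- feature_descriptors(
    pka = c("ASP 2 A", "GLU 5 A"),
    buried = "ASP 2 A",
    distances = list(c("ASP 2 A", "LYS 4 A"))
  )
  fm <- build_feature_matrix(run$pka, desc, buried = run$buried,
                             ensemble = ens)
  expect_equal(dim(feature_values(fm)), c(10, 4))
  expect_true(all(fm[["dist:ASP 2 A|LYS 4 A"]] > 0))

  bad <- feature_descriptors(pka = "ASP 99 A")
  expect_error(build_feature_matrix(run$pka, bad),
               class = "trajpka_value_error")
  expect_error(feature_descriptors(distances = list(c("A", "A"))),
               class = "trajpka_value_error")
})

test_that("minimum heavy-atom distance matches a hand calculation", {
  snap <- new_snapshot(tibble::tibble(
    atom_name = c("CA", "CA"),
    resname = c("GLY", "GLY"), chain = "A", resid = 1:2,
    x = c(0, 3), y = c(0, 4), z = c(0, 0)
  ))
  expect_equal(min_heavy_distance(snap, "GLY 1 A", "GLY 2 A"), 5)
})

test_that("z-scoring yields population-sd unit columns and drops constants", {
  fm <- trajpka:::new_feature_matrix(
    tibble::tibble(frame = 0:2, time_ps = 0:2,
                   a = c(1, 2, 3), b = c(5, 5, 5)),
    normalization = "raw"
  )
  expect_warning(z <- zscore_features(fm), "constant")
  expect_equal(colnames(feature_values(z)), "a")
  expect_equal(z$a, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_lt(abs(mean(z$a)), 1e-10)
  expect_lt(abs(sqrt(mean(z$a^2)) - 1), 1e-10)

  const <- trajpka:::new_feature_matrix(
    tibble::tibble(frame = 0:2, time_ps = 0:2, b = c(5, 5, 5)),
    normalization = "raw"
  )
  expect_error(zscore_features(const), class = "trajpka_value_error")

  # idempotence up to numerical tolerance
  set.seed(2)
  fm2 <- trajpka:::new_feature_matrix(
    tibble::tibble(frame = 0:49, time_ps = 0:49,
                   a = rnorm(50), b = runif(50)),
    normalization = "raw"
  )
  z1 <- zscore_features(fm2)
  z2 <- zscore_features(z1)
  expect_equal(feature_values(z2), feature_values(z1), tolerance = 1e-10)
})

test_that("PCA reduction keeps requested variance and conserves totals", {
  set.seed(5)
  x <- rnorm(40)
  fm <- trajpka:::new_feature_matrix(
    tibble::tibble(frame = 0:39, time_ps = 0:39,
                   a = x, b = 2 * x + 1e-9 * rnorm(40), c = rnorm(40)),
    normalization = "raw"
  )
  z <- zscore_features(fm)

  # rank-deficient pair: 0.9 of the variance in few components
  red <- reduce_pca(z, variance_fraction = 0.9)
  expect_lte(ncol(feature_values(red)), 2)

  full <- reduce_pca(z, n_components = 3)
  expect_equal(sum(apply(feature_values(full), 2, stats::var)),
               sum(apply(feature_values(z), 2, stats::var)),
               tolerance = 1e-8)

  expect_error(reduce_pca(z, n_components = 5),
               class = "trajpka_value_error")
  expect_error(reduce_pca(fm, n_components = 2),
               class = "trajpka_value_error")

  # perfectly correlated two-column matrix: one component suffices
  fm2 <- trajpka:::new_feature_matrix(
    tibble::tibble(frame = 0:39, time_ps = 0:39, a = x, b = 3 * x),
    normalization = "raw"
  )
  red2 <- reduce_pca(zscore_features(fm2), variance_fraction = 0.9)
  expect_equal(ncol(feature_values(red2)), 1)
})

test_that("all four methods recover well-separated blobs", {
  b <- generate_blob_features(30, 3, 10, 3, seed = 7)
  args_by_method <- list(
    kmedoids = list(k = 3),
    greedy = list(cutoff = 5),
    dbscan = list(eps = 1.5, min_samples = 5),
    hdbscan = list(min_cluster_size = 10)
  )
  for (m in names(args_by_method)) {
    cl <- do.call(cluster_frames,
                  c(list(fm = b$features, method = m, seed = 1),
                    args_by_method[[m]]))
    expect_equal(ari(cl$labels$label, b$labels), 1.0)
    expect_equal(cl$n_clusters, 3)
    expect_gte(cl$silhouette, -1)
    expect_lte(cl$silhouette, 1)
    # labels contiguous from 0
    expect_setequal(unique(cl$labels$label), 0:2)
  }
})

test_that("kmedoids representatives are exhaustively optimal medoids", {
  b <- generate_blob_features(30, 3, 10, 3, seed = 13)
  cl <- cluster_frames(b$features, "kmedoids", k = 3, seed = 1)
  vals <- feature_values(b$features)
  d <- as.matrix(dist(vals))
  for (lab in 0:2) {
    members <- which(cl$labels$label == lab)
    sums <- rowSums(d[members, members, drop = FALSE])
    best <- members[which.min(sums)]
    rep_row <- cl$representatives$row[cl$representatives$label == lab]
    expect_equal(rep_row, best)
  }

  # k = 1: representative minimises summed distance to all frames
  one <- generate_blob_features(30, 1, 0, 3, seed = 3)
  cl1 <- cluster_frames(one$features, "kmedoids", k = 1, seed = 1)
  d1 <- as.matrix(dist(feature_values(one$features)))
  expect_equal(cl1$representatives$row, unname(which.min(rowSums(d1))))
  expect_equal(cl1$n_clusters, 1)
})

test_that("dbscan matches a brute-force density classification at small n", {
  b <- generate_blob_features(10, 2, 8, 2, seed = 21)
  vals <- feature_values(b$features)
  eps <- 1.5
  min_samples <- 4
  cl <- cluster_frames(b$features, "dbscan", eps = eps,
                       min_samples = min_samples, seed = 1)
  d <- as.matrix(dist(vals))
  core <- rowSums(d <= eps) >= min_samples
  # every core point is non-noise; every labelled point is within eps of a
  # core point of the same cluster
  labels <- cl$labels$label
  expect_true(all(labels[core] >= 0))
  for (i in which(labels >= 0)) {
    same <- which(labels == labels[i] & core)
    expect_true(any(d[i, same] <= eps))
  }
  # noise points are within eps of no core point
  for (i in which(labels < 0)) {
    expect_false(any(d[i, core] <= eps))
  }
  # non-noise points recover the generating partition exactly
  keep <- labels >= 0
  expect_equal(ari(labels[keep], b$labels[keep]), 1.0)
  expect_equal(cl$n_clusters, 2)
})

test_that("clustering is reproducible for a fixed seed", {
  b <- generate_blob_features(20, 3, 6, 3, seed = 9)
  for (m in c("kmedoids", "hdbscan")) {
    args <- if (m == "kmedoids") list(k = 3) else list(min_cluster_size = 8)
    c1 <- do.call(cluster_frames,
                  c(list(fm = b$features, method = m, seed = 42), args))
    c2 <- do.call(cluster_frames,
                  c(list(fm = b$features, method = m, seed = 42), args))
    expect_identical(c1$labels, c2$labels)
  }
})

test_that("grid search maximises silhouette with stated tie-breaks", {
  b <- generate_blob_features(30, 3, 10, 3, seed = 7)
  gs <- grid_search_clusters(b$features, "kmedoids", list(k = 2:6), seed = 1)
  expect_equal(gs$hyperparameters$k, 3)
  expect_equal(nrow(gs$score_table), 5)
  expect_equal(max(gs$score_table$silhouette, na.rm = TRUE), gs$silhouette)

  single <- grid_search_clusters(b$features, "kmedoids", list(k = 3), seed = 1)
  expect_equal(single$hyperparameters$k, 3)

  # every grid point degenerate -> error listing failures
  expect_error(
    grid_search_clusters(b$features, "dbscan",
                         list(eps = c(1e-6, 1e-5), min_samples = 50), seed = 1),
    class = "trajpka_degenerate_error"
  )
  expect_error(grid_search_clusters(b$features, "kmedoids", list(), seed = 1),
               class = "trajpka_value_error")
})

test_that("representative structures round-trip trajectory coordinates", {
  ens <- make_test_ensemble(n_frames = 12)
  run <- run_prediction_pipeline(ens, engine_spec("mock"))
  fm <- build_feature_matrix(
    run$pka, feature_descriptors(pka = residue_cols(run$pka))
  )
  cl <- cluster_frames(zscore_features(fm), "kmedoids", k = 2, seed = 1)
  out_dir <- withr::local_tempdir()
  files <- extract_representatives(cl, ens, out_dir)
  expect_equal(nrow(files), 2)
  expect_true(all(file.exists(files$path)))
  for (i in seq_len(nrow(files))) {
    snap <- read_snapshot_pdb(files$path[i])
    pos <- match(files$frame[i], ens$frame_indices)
    expect_equal(as.matrix(snap[, c("x", "y", "z")]),
                 as.matrix(get_frame(ens, pos)[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }

  path <- file.path(out_dir, "labels.csv")
  write_cluster_csv(cl, path)
  body <- read.csv(path, comment.char = "#")
  expect_equal(nrow(body), 12)
  expect_true(all(c("frame", "time_ps", "label") %in% names(body)))
})

test_that("joint clustering of replicas keeps provenance", {
  ens1 <- make_test_ensemble(n_frames = 6, seed = 1)
  ens2 <- make_test_ensemble(n_frames = 6, seed = 2)
  r1 <- run_prediction_pipeline(ens1, engine_spec("mock"))
  r2 <- run_prediction_pipeline(ens2, engine_spec("mock"))
  joint <- bind_replica_tables(list(r1$pka, r2$pka))
  expect_equal(nrow(joint), 12)
  expect_equal(unique(joint$replica), c(1, 2))
  fm <- build_feature_matrix(
    joint, feature_descriptors(pka = residue_cols(joint))
  )
  cl <- cluster_frames(zscore_features(fm), "kmedoids", k = 2, seed = 1)
  expect_true("replica" %in% names(cl$labels))
  expect_equal(nrow(cl$labels), 12)
})
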