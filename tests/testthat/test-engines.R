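test_that("mock engine follows its closed-form prediction", {
  # residue centroid coincides with the backbone centroid: d = 0
  centered <- make_centered_asp()
  res <- mock_predict(centered)
  expect_equal(res$pka, res$model_pka)
  expect_equal(res$buried_pct, 100)

  # translating all atoms leaves every prediction unchanged
  pep <- generate_peptide(test_sequence, seed = 4)
  shifted <- pep
  shifted$x <- shifted$x + 13.2
  shifted$y <- shifted$y - 7.9
  shifted$z <- shifted$z + 101
  expect_equal(mock_predict(shifted)$pka, mock_predict(pep)$pka)

  # arithmetic at d = 5: model 4.50 -> pka 5.00, buried 75
  glu <- new_snapshot(tibble::tibble(
    atom_name = c("N", "CA", "C", "O", "CB"),
    resname = "GLU", chain = "A", resid = 1L,
    x = c(1, -1, 1, -1, 5 * 5),  # CB pulls residue centroid to (5,0,0)
    y = c(1, -1, -1, 1, 0),
    z = 0
  ))
  res5 <- mock_predict(glu)
  expect_equal(res5$pka, 5.00)
  expect_equal(res5$buried_pct, 75)
})

test_that("engine output parsing recovers every authored entry exactly", {
  entries <- fixture_engine_entries()
  doc <- generate_engine_output_fixture(entries)
  parsed <- parse_propka_output(doc)

  expect_equal(nrow(parsed), nrow(entries))
  key <- paste(parsed$resname, parsed$resid, parsed$chain)
  key_in <- paste(entries$resname, entries$resid, entries$chain)
  reord <- match(key_in, key)
  expect_equal(parsed$pka[reord], entries$pka)
  expect_equal(parsed$model_pka[reord], entries$model_pka)
  expect_equal(parsed$buried_pct[reord], entries$buried_pct)
  expect_true(all(is.na(parsed$buried_pct) |
                    (parsed$buried_pct >= 0 & parsed$buried_pct <= 100)))

  expect_error(parse_propka_output(""), class = "trajpka_parse_error")
  expect_error(
    parse_propka_output(generate_engine_output_fixture(entries[0, ])),
    class = "trajpka_parse_error"
  )
})

test_that("engine configuration is validated up front", {
  expect_error(engine_spec("pkai", buried = TRUE),
               class = "trajpka_config_error")
  spec <- engine_spec("propka", command = "no-such-binary-on-path")
  ens <- make_test_ensemble(n_frames = 2)
  expect_error(run_prediction_pipeline(ens, spec),
               class = "trajpka_config_error")
})

test_that("pipeline output is invariant to the number of workers", {
  ens <- make_test_ensemble(n_frames = 10)
  out_dir <- withr::local_tempdir()
  csvs <- lapply(c(1, 2, 4), function(w) {
    run <- run_prediction_pipeline(ens, engine_spec("mock"), n_workers = w)
    path <- file.path(out_dir, sprintf("pka_w%d.csv", w))
    write_pka_csv(run$pka, path)
    readBin(path, "raw", file.size(path))
  })
  expect_identical(csvs[[1]], csvs[[2]])
  expect_identical(csvs[[1]], csvs[[3]])
})

test_that("stride halves the number of prediction rows", {
  ens1 <- make_test_ensemble(n_frames = 10, stride = 1)
  ens2 <- make_test_ensemble(n_frames = 10, stride = 2)
  r1 <- run_prediction_pipeline(ens1, engine_spec("mock"))
  r2 <- run_prediction_pipeline(ens2, engine_spec("mock"))
  expect_equal(nrow(r2$pka), nrow(r1$pka) / 2)
})

test_that("worker outputs merge sorted by time and reject duplicates", {
  ens <- make_test_ensemble(n_frames = 10)
  results <- lapply(seq_len(ens$n_frames), function(pos) {
    predict_frame(normalize_residue_names(get_frame(ens, pos)))
  })
  scrambled <- results[c(5:7, 1:4, 8:10)]
  merged <- merge_worker_outputs(scrambled)
  expect_equal(merged$pka$frame, 0:9)
  expect_true(all(diff(merged$pka$time_ps) > 0))

  single <- merge_worker_outputs(results[1])
  expect_equal(nrow(single$pka), 1)

  expect_error(merge_worker_outputs(results[c(1, 2, 2)]),
               class = "trajpka_merge_error")
})

test_that("per-frame engine failures are logged, not fatal", {
  ens <- make_test_ensemble(n_frames = 10)
  flaky <- engine_spec("mock")
  # an engine that fails deterministically on frame 7
  real_predict <- trajpka::mock_predict
  local_mocked_bindings(
    mock_predict = function(snapshot, model_pka) {
      if (frame_index(snapshot) == 7L) stop("engine blew up")
      real_predict(snapshot, model_pka)
    },
    .package = "trajpka"
  )
  run <- suppressWarnings(run_prediction_pipeline(ens, flaky))
  expect_equal(nrow(run$pka), 9)
  expect_equal(run$failures$frame_index, 7L)
})

test_that("pKa CSV round-trips values and model pKa header", {
  ens <- make_test_ensemble(n_frames = 5)
  run <- run_prediction_pipeline(ens, engine_spec("mock"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pka_csv(run$pka, path, comment = "engine=mock; seed=1")
  back <- read_pka_csv(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(run$pka),
               tolerance = 1e-12)
  expect_equal(model_pka(back)[names(model_pka(run$pka))],
               model_pka(run$pka))
  expect_true(any(startsWith(readLines(path), "#")))
})
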