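make_table <- function(values, residues = NULL, model = NULL) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (is.null(residues)) {
    residues <- res_label("ASP", seq_len(ncol(values)), "A")
  }
  colnames(values) <- residues
  new_pka_table(
    dplyr::bind_cols(
      tibble::tibble(frame = seq_len(nrow(values)) - 1L,
                     time_ps = as.numeric(seq_len(nrow(values)) - 1L)),
      tibble::as_tibble(values)
    ),
    model_pka = model
  )
}

test_that("running average uses a centered window clipped at the edges", {
  expect_equal(running_average(c(1, 2, 3, 4, 5), 3), c(1.5, 2, 3, 4, 4.5))
  expect_equal(running_average(c(4, 7, 1), 1), c(4, 7, 1))
  expect_equal(running_average(rep(2.5, 9), 5), rep(2.5, 9))
  # shift-equivariance
  x <- sin(1:40 / 3) + cos(1:40 / 7)
  expect_equal(running_average(x + 10, 7), running_average(x, 7) + 10)
  expect_error(running_average(1:3, 5), class = "trajpka_value_error")
  expect_warning(out <- running_average(1:10, 4), "rounded up")
  expect_equal(out, running_average(1:10, 5))
  # window conversion from a time span: 5 ns at 100 ps/frame -> 51 frames
  expect_equal(window_frames(5000, 100), 51)
})

test_that("per-residue summaries report moments and model deltas", {
  tab <- make_table(c(4.0, 4.2, 4.4, 3.9, 4.0),
                    residues = "ASP 1 A", model = c("ASP 1 A" = 3.8))
  s <- summarize_pka(tab)
  expect_equal(s$mean, 4.1)
  expect_equal(s$min, 3.9)
  expect_equal(s$max, 4.4)
  expect_equal(s$delta_model, 4.1 - 3.8)
  expect_true(s$min <= s$mean && s$mean <= s$max)

  single <- summarize_pka(make_table(4.5, residues = "GLU 2 A"))
  expect_equal(single$sd, 0)
})

test_that("histograms are zero-aligned and conserve frame counts", {
  tab <- make_table(rep(4.05, 10), residues = "ASP 1 A")
  d <- pka_distribution(tab, 0.1)
  expect_equal(nrow(d), 1)
  expect_equal(d$bin_left, 4.0)
  expect_equal(d$count, 10)

  tab2 <- make_table(c(3.95, 4.05), residues = "ASP 1 A")
  d2 <- pka_distribution(tab2, 0.1)
  expect_equal(d2$bin_left, c(3.9, 4.0))
  expect_equal(d2$count, c(1, 1))

  # conservation across residues on an arbitrary table
  set.seed(1)
  m <- matrix(rnorm(60, 6, 2), ncol = 3)
  d3 <- pka_distribution(make_table(m), 0.25)
  counts <- tapply(d3$count, d3$residue, sum)
  expect_true(all(counts == 20))
})

test_that("correlation scan recovers exact and noisy relations", {
  n <- 1000
  set.seed(42)
  x <- rnorm(n)
  eps <- rnorm(n)
  for (rho in c(0, 0.5, 0.9)) {
    y <- rho * x + sqrt(1 - rho^2) * eps
    tab <- make_table(y, residues = "GLU 1 A")
    rep <- correlation_scan(tab, tibble::tibble(pc1 = x))
    expect_lt(abs(rep$correlation - rho), 0.05)
  }

  tab <- make_table(2 * x[1:50] + 1, residues = "GLU 1 A")
  expect_equal(
    correlation_scan(tab, tibble::tibble(pc1 = x[1:50]))$correlation, 1.0
  )
  expect_equal(
    correlation_scan(tab, tibble::tibble(pc1 = -3 * tab[["GLU 1 A"]]))$correlation,
    -1.0
  )

  const <- make_table(rep(4, 50), residues = "GLU 1 A")
  expect_true(is.na(
    correlation_scan(const, tibble::tibble(pc1 = x[1:50]))$correlation
  ))
  expect_error(
    correlation_scan(tab, tibble::tibble(pc1 = x[1:49])),
    class = "trajpka_value_error"
  )
})

test_that("correlation scan flags and ranks by absolute coefficient", {
  set.seed(7)
  n <- 200
  x <- rnorm(n)
  tab <- make_table(cbind(-x + 0.1 * rnorm(n), rnorm(n)),
                    residues = c("ASP 1 A", "GLU 2 A"))
  rep <- correlation_scan(tab, tibble::tibble(pc1 = x), threshold = 0.5)
  expect_equal(rep$residue[1], "ASP 1 A")
  expect_true(rep$flagged[1])
  expect_lt(rep$correlation[1], 0)  # signed value kept
  expect_false(rep$flagged[rep$residue == "GLU 2 A"])
})

test_that("protonation-sensitivity fractions match window membership", {
  away <- make_table(rep(4, 6), residues = "ASP 1 A")
  expect_equal(nrow(flag_protonation_sensitive(away, 7.4, 1)), 0)

  tab <- make_table(c(6.5, 7.0, 8.0, 9.0), residues = "HIS 1 A")
  out <- flag_protonation_sensitive(tab, 7.4, 1)
  expect_equal(out$fraction, 0.75)

  wide <- flag_protonation_sensitive(tab, 7.4, 10)
  expect_equal(wide$fraction, 1.0)
})

test_that("cross-replica averaging is an unweighted mean of replica means", {
  t1 <- make_table(rep(4.0, 5), residues = "ASP 1 A")
  t2 <- make_table(rep(4.2, 5), residues = "ASP 1 A")
  avg <- average_over_replicas(list(t1, t2))
  expect_equal(avg$mean, 4.1)
  expect_false(avg$incomplete)

  expect_equal(average_over_replicas(list(t1))$mean, 4.0)
  # identical replicas equal the single-replica mean exactly
  expect_equal(average_over_replicas(list(t1, t1))$mean,
               summarize_pka(t1)$mean)

  t3 <- make_table(cbind(rep(4.0, 5), rep(9.9, 5)),
                   residues = c("ASP 1 A", "LYS 2 A"))
  avg3 <- average_over_replicas(list(t3, t1))
  expect_true(avg3$incomplete[avg3$residue == "LYS 2 A"])
  expect_equal(avg3$mean[avg3$residue == "LYS 2 A"], 9.9)

  t4 <- make_table(rep(1, 5), residues = "TYR 9 B")
  expect_error(average_over_replicas(list(t1, t4)),
               class = "trajpka_value_error")
})

test_that("mutant profile comparison separates shift from shape change", {
  set.seed(3)
  w <- make_table(4 + sin(1:30 / 4) + 0.1 * rnorm(30), residues = "ASP 1 A")
  shifted <- make_table(w[["ASP 1 A"]] + 0.5, residues = "ASP 1 A")
  cmp <- compare_mutant_profiles(w, shifted, "ASP 1 A")
  expect_equal(cmp$mean_shift, 0.5)
  expect_equal(cmp$fluctuation_ratio, 1.0)

  damped <- make_table(rep(mean(w[["ASP 1 A"]]), 30), residues = "ASP 1 A")
  expect_equal(compare_mutant_profiles(w, damped, "ASP 1 A")$fluctuation_ratio, 0)

  same <- compare_mutant_profiles(w, w, "ASP 1 A")
  expect_equal(same$mean_shift, 0)
  expect_equal(same$fluctuation_ratio, 1)

  short <- make_table(w[["ASP 1 A"]][1:10], residues = "ASP 1 A")
  expect_error(compare_mutant_profiles(w, short, "ASP 1 A"),
               class = "trajpka_value_error")
  expect_error(compare_mutant_profiles(w, shifted, "GLU 9 A"),
               class = "trajpka_value_error")
})
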