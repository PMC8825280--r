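# Generators: determinism, label consistency, and the designed statistical
# properties of each simulated modality.

test_that("all generators are byte-identical under a fixed seed", {
  pairs <- list(
    function(s) gen_vagal_recording(240, 5000, 8, list(c(120, 30, 2)), seed = s),
    function(s) gen_calcium_population(3, 2, 1, 1, 1, seed = s),
    function(s) gen_dff_population(2, 2, 1, 1, seed = s),
    function(s) gen_cq_matrix(c(8, 6), genes = c("A", "B"),
                              de_genes = c(A = 1), dropout_prob = 0.2, seed = s),
    function(s) gen_receptor_population(2, 10, seed = s),
    function(s) gen_intake_session(0.7, 1.5, dip_prob = 0.1, seed = s),
    function(s) gen_cutback(0.93, 1:6, noise_cv = 0.05, seed = s)
  )
  for (gen in pairs) {
    expect_identical(gen(42L), gen(42L))
  }
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(gen_cutback(0.5, 1:4, noise_cv = 0.1, seed = 7))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("vagal spike counts follow the designed Poisson process", {
  # baseline only: mean count = rate x duration
  rec <- gen_vagal_recording(300, 5000, 10, list(), seed = 1)
  n <- length(rec$truth$labels$spike_times)
  expect_lt(abs(n - 3000), 3 * sqrt(3000))

  # zero rate: flat noise, no spikes
  rec0 <- gen_vagal_recording(60, 5000, 0, list(), seed = 1)
  expect_length(rec0$truth$labels$spike_times, 0)

  # 3x multiplier during (120, 180): in-window count near 3x baseline rate
  rec3 <- gen_vagal_recording(300, 5000, 10, list(c(120, 60, 3)), seed = 2)
  st <- rec3$truth$labels$spike_times
  n_win <- sum(st >= 120 & st < 180)
  expect_lt(abs(n_win - 1800), 4 * sqrt(1800))
  n_base <- sum(st < 120)
  expect_lt(abs(n_base - 1200), 4 * sqrt(1200))
})

test_that("vagal generator rejects invalid designs", {
  expect_error(gen_vagal_recording(100, 5000, 10, list(c(90, 60, 2))),
               "outside")
  expect_error(gen_vagal_recording(100, -1, 10), "sampling_rate_hz")
  expect_error(gen_vagal_recording(100, 5000, 10, list(c(10, 20, -1))),
               "multipliers")
})

test_that("calcium population honors designed class counts and margins", {
  expect_length(gen_calcium_population(0, 0, 0, 0, 0, seed = 1)$traces, 0)

  pop <- gen_calcium_population(21, 14, 4, 8, 0, seed = 7)
  expect_length(pop$traces, 47)
  tab <- table(pop$truth$labels$class$class)
  expect_equal(tab[["neither"]], 21)
  expect_equal(tab[["a_only"]], 14)
  expect_equal(tab[["b_only"]], 4)
  expect_equal(tab[["both"]], 8)

  # designed non-viable cells carry the label and fail the gate downstream
  pop_nv <- gen_calcium_population(2, 1, 0, 0, 5, seed = 3)
  expect_equal(sum(pop_nv$truth$labels$class$class == "nonviable"), 5)
  calls <- classify_population(pop_nv$traces)
  expect_equal(sum(!calls$viability$viable), 5)

  # peaks within 1% of the 10% threshold are rejected as ambiguous
  expect_error(gen_calcium_population(1, 1, 0, 0, 0, kcl_peak_frac = 0.105),
               "ambig|threshold")
  expect_error(
    gen_calcium_population(1, 1, 0, 0, 0, nonresponder_peak_frac = 0.095),
    "ambig|threshold")
})

test_that("Cq generator plants effects, dropout and QC casualties as designed", {
  # no dropout, no effects: everything detected
  gm <- gen_cq_matrix(c(10, 10), genes = c("A", "B"), dropout_prob = 0,
                      seed = 1)
  expect_true(all(!is.na(gm$matrix$cq)))

  # +2 log2 effect: empirical mean RQ ratio near 4 (direct computation)
  gm2 <- gen_cq_matrix(c(60, 30), genes = c("G"), de_genes = c(G = 2),
                       dropout_prob = 0, seed = 3)
  rq <- 2^(34 - gm2$matrix$cq[, "G"])
  grp <- gm2$matrix$meta$group
  ratio <- mean(rq[grp == "GFP+"]) / mean(rq[grp == "GFP-"])
  expect_gt(ratio, 3)
  expect_lt(ratio, 5.3)

  # designed QC casualties are exactly the cells the filter removes
  gm3 <- gen_cq_matrix(c(20, 10), genes = c("A"), n_qc_casualties = 7,
                       seed = 3)
  qf <- quality_filter(gm3$matrix)
  expect_equal(nrow(qf$report), 7)
  expect_setequal(qf$report$cell_id, gm3$truth$labels$qc_casualties)

  expect_error(gen_cq_matrix(c(5, 5), genes = c("A"), de_genes = c(Z = 1)),
               "not in the panel")
})

test_that("intake streams are quantized, split by design, and dip transiently", {
  ses <- gen_intake_session(0.5, 2.0, dip_prob = 0, seed = 1)
  for (s in list(ses$sucrose, ses$sucralose)) {
    v <- s$cumulative_g
    expect_true(all(abs(v * 100 - round(v * 100)) < 1e-9))  # 0.01-g grid
    expect_true(all(diff(v) >= 0))  # no dips requested
  }
  cs <- choice_session(ses$sucrose, ses$sucralose)
  expect_equal(compute_preference(cs)$preference_pct, 50)

  ses2 <- gen_intake_session(0.909, 2.0, dip_prob = 0.1, seed = 11)
  raw_inc <- c(diff(ses2$sucrose$cumulative_g),
               diff(ses2$sucralose$cumulative_g))
  expect_gt(sum(raw_inc < 0), 0)  # raw stream carries sensor dips
  cln <- clean_intake(ses2$sucrose)
  expect_true(all(diff(cln$stream$cumulative_g) >= 0))
  # cleaned final reading equals designed truth
  expect_equal(utils::tail(cln$stream$cumulative_g, 1),
               ses2$truth$labels$sucrose_g)
})

test_that("cut-back generator and fit close the loop", {
  # zero attenuation, no noise: constant power
  cb0 <- gen_cutback(0, 1:5, noise_cv = 0, seed = 1)
  expect_true(all(cb0$series$output_power == cb0$series$output_power[1L]))

  # noiseless log-linear series: exact closed-form recovery
  cb <- gen_cutback(0.93, seq(1, 10, by = 0.5), noise_cv = 0, seed = 1)
  expect_equal(fit_loss(cb$series)$alpha_db_per_cm, 0.93, tolerance = 1e-12)

  # Monte-Carlo at 1% noise: fitted alphas center on truth
  alphas <- vapply(1:100, function(s) {
    fit_loss(gen_cutback(0.93, seq(1, 10, 0.5), noise_cv = 0.01,
                         seed = s)$series)$alpha_db_per_cm
  }, numeric(1))
  expect_lt(abs(mean(alphas) - 0.93), 0.01)

  expect_error(gen_cutback(0.5, c(2, 1)), "increasing")
  expect_error(gen_cutback(0.5, 1:3, noise_cv = -1), "noise_cv")
})
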