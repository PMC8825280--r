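# Ratiometric and dF/F response calling, viability gating and overlap
# summaries.

make_flat_trace <- function(ratio_profile, times = seq(0, 208.5, by = 1.5),
                            cell_id = "c1") {
  windows <- data.frame(name = c("glucose", "sucralose"), onset = c(45, 90),
                        duration = c(15, 15), stringsAsFactors = FALSE)
  furared <- rep(100, length(times))
  ratiometric_trace(times, ratio_profile * furared, furared, cell_id,
                    windows, kcl_window = c(150, 30))
}

test_that("compute_ratio is element-wise division with a guarded channel", {
  times <- seq(0, 10, by = 1)
  w <- data.frame(name = "a", onset = 2, duration = 2)
  tr <- ratiometric_trace(times, rep(3, 11), rep(3, 11), "c", w, c(8, 2))
  expect_true(all(compute_ratio(tr) == 1))

  tr2 <- ratiometric_trace(times, 2 * (1:11), as.numeric(1:11), "c", w, c(8, 2))
  expect_true(all(compute_ratio(tr2) == 2))

  expect_error(
    ratiometric_trace(times, rep(1, 11), c(rep(1, 5), 0, rep(1, 5)), "c",
                      w, c(8, 2)),
    "frame")
})

test_that("response calls apply the strict >10% rule around the baseline", {
  times <- seq(0, 208.5, by = 1.5)
  flat <- rep(1, length(times))
  res <- call_response(flat, times, c(45, 15))
  expect_false(res$responded)
  expect_equal(res$peak_fractional_increase, 0)

  up25 <- ifelse(times >= 45 & times <= 60, 1.25, 1)
  expect_true(call_response(up25, times, c(45, 15))$responded)

  up09 <- ifelse(times >= 45 & times <= 60, 1.09, 1)
  expect_false(call_response(up09, times, c(45, 15))$responded)
})

test_that("rebaselining uses the five frames before each window", {
  times <- seq(0, 208.5, by = 1.5)
  # drifted trace: level 1 until 80 s, then 2; a 2.1 peak in the second
  # window is only a 5% rise over the local (rebaselined) level
  r <- ifelse(times < 80, 1, 2)
  r[times >= 90 & times <= 105] <- 2.1
  res <- call_response(r, times, c(90, 15), rebaseline = TRUE)
  expect_false(res$responded)
  expect_equal(res$baseline_used, 2)
  # against the run-initial baseline the same peak is a 110% rise
  res2 <- call_response(r, times, c(90, 15), rebaseline = FALSE,
                        initial_baseline = 1)
  expect_true(res2$responded)
})

test_that("KCl gate excludes designed non-viable cells and only those", {
  times <- seq(0, 208.5, by = 1.5)
  viable <- ifelse(times >= 150 & times <= 180, 1.15, 1)
  dead <- ifelse(times >= 150 & times <= 180, 1.05, 1)
  expect_true(viability_gate(viable, times, c(150, 30))$viable)
  expect_false(viability_gate(dead, times, c(150, 30))$viable)

  pop <- gen_calcium_population(2, 2, 0, 0, 5, seed = 9)
  calls <- classify_population(pop$traces)
  expect_equal(sum(!calls$viability$viable), 5)
  truth_nv <- pop$truth$labels$class$cell_id[
    pop$truth$labels$class$class == "nonviable"]
  expect_setequal(calls$viability$unit_id[!calls$viability$viable], truth_nv)
})

test_that("normalize_to_kcl divides by the KCl peak", {
  expect_equal(normalize_to_kcl(0.3, 0.3), 1)
  expect_equal(normalize_to_kcl(0, 0.3), 0)
  expect_equal(normalize_to_kcl(c(0.1, 0.2), 0.4), c(0.25, 0.5))
  expect_error(normalize_to_kcl(0.1, 0), "kcl_peak")
})

test_that("calls are invariant to a common channel rescaling", {
  pop <- gen_calcium_population(2, 2, 1, 1, 1, seed = 5)
  scaled <- lapply(pop$traces, function(tr) {
    ratiometric_trace(tr$times, tr$fluo4 * 3.7, tr$furared * 3.7,
                      tr$cell_id, tr$stimulus_windows, tr$kcl_window)
  })
  a <- classify_population(pop$traces)
  b <- classify_population(scaled)
  expect_equal(a$calls$responded, b$calls$responded)
  expect_equal(a$viability$viable, b$viability$viable)
})

test_that("raising the threshold never creates a responder", {
  pop <- gen_calcium_population(3, 3, 2, 2, 1, seed = 13)
  lo <- classify_population(pop$traces, threshold_frac = 0.10)
  hi <- classify_population(pop$traces, threshold_frac = 0.20)
  # same viable set here by construction margins; compare call by call
  expect_true(all(!hi$calls$responded | lo$calls$responded))
})

test_that("venn_summary partitions viable units and reports both denominators", {
  pop <- gen_calcium_population(21, 14, 4, 8, 0, seed = 7)
  v <- venn_summary(classify_population(pop$traces), "glucose", "sucralose")
  expect_equal(sum(v$counts), v$n_viable)
  expect_equal(unname(v$counts[c("a_only", "b_only", "both")]),
               c(14, 4, 8))
  expect_equal(v$n_responders, 26)
  expect_equal(sum(v$pct_of_responders), 100, tolerance = 0.1)
  expect_equal(sum(v$pct_of_viable), 100, tolerance = 0.1)

  # no responders among viable units: responder percentages undefined
  pop0 <- gen_calcium_population(10, 0, 0, 0, 0, seed = 2)
  v0 <- venn_summary(classify_population(pop0$traces), "glucose", "sucralose")
  expect_equal(v0$n_responders, 0)
  expect_true(all(is.na(v0$pct_of_responders)))
  expect_equal(unname(v0$pct_of_viable[["neither"]]), 100)
})

test_that("externally supplied booleans feed the same overlap summary", {
  v <- venn_summary(
    response_calls_from_logical(
      responded_a = rep(c(TRUE, FALSE, TRUE), c(8, 4, 6)),
      responded_b = rep(c(FALSE, TRUE, TRUE), c(8, 4, 6)),
      stim_a = "glucose", stim_b = "sucralose"),
    "glucose", "sucralose")
  expect_equal(unname(v$counts[c("a_only", "b_only", "both")]), c(8, 4, 6))
  expect_equal(unname(round(v$pct_of_responders, 1)), c(44.4, 22.2, 33.3))
})

test_that("dF/F series is mean-zero and the >20% rule applies to it", {
  times <- seq(0, 479, by = 0.683)
  w <- data.frame(name = "sucrose", onset = 120, duration = 60)
  flat <- dff_trace(times, rep(50, length(times)), "n1", w)
  d <- compute_dff(flat)
  expect_equal(mean(d), 0)
  expect_false(call_dff_response(d, times, c(120, 60))$responded)

  f <- ifelse(times >= 120 & times <= 180, 100, 50)
  d2 <- compute_dff(dff_trace(times, f, "n2", w))
  expect_equal(mean(d2), 0)
  expect_true(call_dff_response(d2, times, c(120, 60))$responded)

  # generated fixture: calls equal the designed labels
  pop <- gen_dff_population(5, 4, 3, 2, seed = 17)
  calls <- classify_dff_population(pop$traces)
  v <- venn_summary(calls, "sucrose", "sucralose")
  expect_equal(unname(v$counts[c("a_only", "b_only", "both", "neither")]),
               c(4, 3, 2, 5))
})
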