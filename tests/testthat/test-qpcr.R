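# Single-cell RT-qPCR: quality control, relative quantification,
# normalization, differential expression and receptor classes.

toy_cq <- function() {
  genes <- c("Gapdh", "Actb1", "Slc5a1")
  cq <- matrix(c(
    25, 26, 30,   # cell 1: fine
    24, NA, 28,   # cell 2: one housekeeping gene suffices
    NA, NA, 27,   # cell 3: no housekeeping -> dropped
    26, 25, NA,   # cell 4: fine, receptor undetected
    NA, NA, NA    # cell 5: nothing -> dropped
  ), nrow = 5, byrow = TRUE, dimnames = list(sprintf("c%d", 1:5), genes))
  quality <- matrix(1, 5, 3, dimnames = dimnames(cq))
  meta <- data.frame(cell_id = rownames(cq), mouse_id = "m1", group = "GFP+",
                     stringsAsFactors = FALSE)
  cq_matrix(cq, quality, meta)
}

test_that("quality_filter drops housekeeping-negative cells and is idempotent", {
  qf <- quality_filter(toy_cq())
  expect_equal(nrow(qf$matrix$cq), 3)
  expect_setequal(qf$report$cell_id, c("c3", "c5"))

  # all wells high quality and detected: identity
  clean <- qf$matrix
  qf2 <- quality_filter(clean)
  expect_identical(qf2$matrix$cq, clean$cq)
  expect_equal(nrow(qf2$report), 0)

  # low-quality wells are censored to undetected before the cell check
  m <- toy_cq()
  m$quality["c1", "Slc5a1"] <- 0.5
  qf3 <- quality_filter(m)
  expect_true(is.na(qf3$matrix$cq["c1", "Slc5a1"]))
  expect_equal(attr(qf3$report, "n_wells_rejected"), 1)

  expect_error(quality_filter(toy_cq(), housekeeping = c("Gapdh", "Nope")),
               "missing")
})

test_that("cq_to_rq implements the relative-quantity formula exactly", {
  expect_equal(cq_to_rq(34), 1)
  expect_equal(cq_to_rq(24), 1024)
  expect_equal(cq_to_rq(NA_real_), 0.5)

  # log2(RQ) = 34 - Cq identity over random detected values
  set.seed(1)
  cqs <- runif(1e4, 10, 34)
  expect_equal(log2(cq_to_rq(cqs)), 34 - cqs, tolerance = 1e-12)
  # strictly decreasing in Cq
  o <- order(cqs)
  expect_true(all(diff(cq_to_rq(cqs[o])) < 0))

  rq <- cq_to_rq(toy_cq())
  expect_equal(rq$log2, log2(rq$rq))
  expect_true(all(rq$rq[!rq$detected] == 0.5))
})

test_that("per-gene normalization hits mean 0 / sd 1 with documented edge cases", {
  x <- matrix(rnorm_fixed(60, 1, 2), 10, 6,
              dimnames = list(NULL, sprintf("g%d", 1:6)))
  z <- normalize_per_gene(x)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))

  # two-cell gene under the sample-sd convention
  z2 <- normalize_per_gene(matrix(c(3, 5), 2, 1, dimnames = list(NULL, "g")))
  expect_equal(as.numeric(z2), c(-1, 1) / sqrt(2))

  expect_warning(
    zc <- normalize_per_gene(cbind(x, const = rep(2, 10))),
    "zero-variance")
  expect_true(all(zc[, "const"] == 0))
})

test_that("identical groups yield unit fold changes and no discoveries", {
  genes <- c("Gapdh", "Actb1", "A", "B")
  vals <- matrix(rep(c(25, 26, 27, 28), each = 6), 6, 4,
                 dimnames = list(NULL, genes))
  cq <- rbind(vals, vals)
  rownames(cq) <- sprintf("c%d", 1:12)
  meta <- data.frame(cell_id = rownames(cq), mouse_id = "m1",
                     group = rep(c("g1", "g2"), each = 6))
  rq <- cq_to_rq(cq_matrix(cq, matrix(1, 12, 4, dimnames = dimnames(cq)), meta))
  de <- differential_expression(rq, groups = c("g1", "g2"))
  expect_true(all(de$fold_change == 1))
  expect_false(any(de$significant))
})

test_that("a planted +2 log2 effect is detected with fold change near 4", {
  gm <- gen_cq_matrix(c(60, 30), genes = c("Slc5a1", "Tas1r3", "Efnb2"),
                      de_genes = c(Efnb2 = 2), seed = 3)
  rq <- cq_to_rq(quality_filter(gm$matrix)$matrix)
  de <- differential_expression(rq, groups = c("GFP+", "GFP-"))
  row <- de[de$gene == "Efnb2", ]
  expect_true(row$significant)
  expect_gt(row$fold_change, 3)
  expect_lt(row$fold_change, 5.3)
})

test_that("fold-change direction agrees with the t statistic", {
  for (s in c(2, 5, 8)) {
    gm <- gen_cq_matrix(c(30, 30), genes = sprintf("g%d", 1:10),
                        de_genes = c(g1 = 1.5, g2 = -1.5),
                        dropout_prob = 0.1, seed = s)
    rq <- cq_to_rq(gm$matrix)
    de <- differential_expression(rq, groups = c("GFP+", "GFP-"),
                                  fc_basis = "log2")
    ok <- is.finite(de$t_stat) & de$t_stat != 0
    expect_true(all(sign(de$log2_fold_change[ok]) == sign(de$t_stat[ok])))
  }
})

test_that("BH adjustment equals the brute-force implementation exactly", {
  set.seed(4)
  for (i in 1:20) {
    p <- runif(96)^(1 + i %% 3)  # varied shapes, including ties on repeat
    expect_identical(p.adjust(p, method = "BH"), oracle_bh(p))
  }
  gm <- gen_cq_matrix(c(20, 20), genes = sprintf("g%d", 1:30),
                      dropout_prob = 0.1, seed = 6)
  de <- differential_expression(cq_to_rq(gm$matrix),
                                groups = c("GFP+", "GFP-"))
  expect_equal(de$q_value, oracle_bh(de$p_value))
})

test_that("family-wise false-positive fraction under the complete null is ~5%", {
  hits <- vapply(1:200, function(s) {
    gm <- gen_cq_matrix(c(12, 8), genes = sprintf("g%02d", 1:96),
                        dropout_prob = 0, seed = s)
    de <- differential_expression(cq_to_rq(gm$matrix),
                                  groups = c("GFP+", "GFP-"))
    any(de$significant)
  }, logical(1))
  # BH controls P(any rejection) at q = 0.05 under the complete null;
  # binomial 99% band around 0.05 at n = 200
  expect_gt(mean(hits), 0.05 - 0.04)
  expect_lt(mean(hits), 0.05 + 0.05)
})

test_that("receptor classes recover the designed coexpression structure", {
  pop <- gen_receptor_population(3, 50, c(0.20, 0.60, 0.01, 0.19), seed = 2)
  rq <- cq_to_rq(pop$matrix)
  rc <- classify_receptors(rq)
  # per-cell classes equal the generator labels exactly
  lv_map <- c(neither = "neither", a_only = "slc5a1_only",
              b_only = "tas1r3_only", both = "both")
  expect_equal(as.character(rc$cell_class),
               unname(lv_map[pop$truth$labels$class$class]))
  # per-mouse percentages sum to 100 and means sit near the design
  expect_true(all(abs(rowSums(rc$per_mouse) - 100) < 0.1))
  design <- 100 * c(0.20, 0.60, 0.01, 0.19)
  expect_true(all(abs(rc$summary$mean_pct - design) < 12))

  # degenerate designs
  all_both <- gen_receptor_population(2, 20, c(0, 0, 0, 1), seed = 1)
  rc2 <- classify_receptors(cq_to_rq(all_both$matrix))
  expect_equal(rc2$summary$mean_pct[rc2$summary$class == "both"], 100)
  none <- gen_receptor_population(2, 20, c(1, 0, 0, 0), seed = 1)
  rc3 <- classify_receptors(cq_to_rq(none$matrix))
  expect_equal(rc3$summary$mean_pct[rc3$summary$class == "neither"], 100)

  # single mouse: s.e.m. reported as absent
  one <- gen_receptor_population(1, 20, c(0.25, 0.25, 0.25, 0.25), seed = 3)
  rc4 <- classify_receptors(cq_to_rq(one$matrix))
  expect_true(all(is.na(rc4$summary$sem_pct)))
})

test_that("Cq matrices round-trip through the Biomark-style export", {
  gm <- gen_cq_matrix(c(5, 4), genes = c("A", "B"), dropout_prob = 0.2,
                      seed = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cq_export(gm$matrix, path)
  back <- read_cq_export(path)
  expect_equal(back$cq, gm$matrix$cq, tolerance = 1e-9)
  expect_equal(back$meta$group, gm$matrix$meta$group)
})
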