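# Single-cell RT-qPCR pipeline: quality control, relative quantification,
# per-gene normalization, differential expression and receptor-coexpression
# classification of Biomark-style Cq matrices.

#' Construct a single-cell Cq matrix
#'
#' @param cq Numeric cells-by-genes matrix of quantification-cycle values;
#'   `NA` marks an undetected well. Row names are cell ids, column names
#'   gene names.
#' @param quality Matrix of per-well quality scores in `[0, 1]`, same
#'   dimensions as `cq`.
#' @param meta Data frame with one row per cell: `cell_id`, `mouse_id`,
#'   `group`.
#' @return An object of class `cq_matrix`.
#' @export
cq_matrix <- function(cq, quality, meta) {
  stopifnot(is.matrix(cq), is.matrix(quality),
            all(dim(cq) == dim(quality)),
            is.data.frame(meta),
            all(c("cell_id", "mouse_id", "group") %in% names(meta)),
            nrow(meta) == nrow(cq))
  if (any(quality < 0 | quality > 1, na.rm = TRUE)) {
    stop("quality scores must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(cq[!is.na(cq)]))) {
    stop("detected Cq values must be finite", call. = FALSE)
  }
  if (is.null(rownames(cq))) rownames(cq) <- meta$cell_id
  structure(list(cq = cq, quality = quality, meta = meta),
            class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("<cq_matrix> %d cells x %d genes (%.1f%% wells detected)\n",
              nrow(x$cq), ncol(x$cq), 100 * mean(!is.na(x$cq))))
  invisible(x)
}

#' Quality-filter a Cq matrix
#'
#' Wells with a quality score below `quality_threshold` are set to
#' undetected. Cells left with no detected transcript for either
#' housekeeping gene are then dropped. The operation is idempotent.
#'
#' @param m A [cq_matrix()].
#' @param quality_threshold Minimum acceptable well quality (default 0.65).
#' @param housekeeping Housekeeping gene names (default `Gapdh`, `Actb1`);
#'   both must be present in the panel.
#' @return List with `$matrix` (the filtered `cq_matrix`) and `$report`
#'   (data frame of dropped cells and reasons, plus the count of wells
#'   failing the quality threshold as attribute `n_wells_rejected`).
#' @export
quality_filter <- function(m, quality_threshold = 0.65,
                           housekeeping = c("Gapdh", "Actb1")) {
  stopifnot(inherits(m, "cq_matrix"))
  if (nrow(m$cq) == 0L) stop("empty Cq matrix", call. = FALSE)
  if (!all(housekeeping %in% colnames(m$cq))) {
    stop("housekeeping genes missing from the panel: ",
         paste(setdiff(housekeeping, colnames(m$cq)), collapse = ", "),
         call. = FALSE)
  }
  cq <- m$cq
  low_q <- m$quality < quality_threshold & !is.na(cq)
  cq[low_q] <- NA_real_

  hk_detected <- rowSums(!is.na(cq[, housekeeping, drop = FALSE])) > 0
  dropped <- rownames(cq)[!hk_detected]
  report <- data.frame(
    cell_id = dropped,
    reason = rep("no housekeeping gene detected", length(dropped)),
    stringsAsFactors = FALSE)
  attr(report, "n_wells_rejected") <- sum(low_q)

  keep <- hk_detected
  out <- cq_matrix(cq[keep, , drop = FALSE],
                   m$quality[keep, , drop = FALSE],
                   m$meta[keep, , drop = FALSE])
  list(matrix = out, report = report)
}

#' Convert Cq values to relative quantities
#'
#' `RQ = 2^(cq_cutoff - Cq)` with a cutoff of 34 cycles; any undetected well
#' is assigned `RQ = 0.5`. A Cq of 34 therefore maps to RQ 1, and
#' `log2(RQ) = 34 - Cq` exactly for detected wells.
#'
#' @param m A [cq_matrix()] (typically after [quality_filter()]), or a
#'   numeric vector of Cq values with `NA` for undetected.
#' @param cq_cutoff Cycle cutoff (default 34).
#' @param undetected_rq RQ substituted for undetected wells (default 0.5).
#' @return For a matrix input, an object of class `rq_matrix` with `$rq`
#'   (linear), `$log2` (exactly `log2(rq)`), `$detected` (logical matrix of
#'   wells that were measured rather than substituted) and `$meta`. For a
#'   vector input, a numeric vector of RQ values.
#' @export
cq_to_rq <- function(m, cq_cutoff = 34, undetected_rq = 0.5) {
  convert <- function(cq) {
    rq <- 2^(cq_cutoff - cq)
    rq[is.na(cq)] <- undetected_rq
    rq
  }
  if (is.numeric(m)) return(convert(m))
  stopifnot(inherits(m, "cq_matrix"))
  rq <- convert(m$cq)
  structure(
    list(rq = rq, log2 = log2(rq), detected = !is.na(m$cq),
         meta = m$meta, cq_cutoff = cq_cutoff, undetected_rq = undetected_rq),
    class = "rq_matrix"
  )
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat(sprintf("<rq_matrix> %d cells x %d genes (cutoff %g, undetected -> %g)\n",
              nrow(x$rq), ncol(x$rq), x$cq_cutoff, x$undetected_rq))
  invisible(x)
}

#' Z-score log2 relative quantities within each gene
#'
#' Centers and scales each gene column of the log2 RQ matrix to mean 0 and
#' standard deviation 1. The sample (n - 1) standard-deviation convention is
#' used (matching [scale()]), so a two-cell gene `(a, b)` with `a != b` maps
#' to `c(-1, 1) / sqrt(2)`.
#'
#' @param rq An `rq_matrix` (see [cq_to_rq()]) or a numeric log2 matrix.
#' @return Numeric matrix of z-scores; zero-variance genes become columns of
#'   zeros with a warning.
#' @export
normalize_per_gene <- function(rq) {
  x <- if (inherits(rq, "rq_matrix")) rq$log2 else rq
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) stop("need at least 2 cells per gene", call. = FALSE)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  zero_var <- sdv == 0
  if (any(zero_var)) {
    warning(sprintf("%d zero-variance gene(s) set to all-zero columns: %s",
                    sum(zero_var),
                    paste(colnames(x)[zero_var], collapse = ", ")),
            call. = FALSE)
    sdv[zero_var] <- 1
  }
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  z[, zero_var] <- 0
  z
}

#' Two-group differential expression on a relative-quantity matrix
#'
#' Per gene, a two-tailed two-sample t-test (Welch by default) on log2 RQ
#' values, Benjamini-Hochberg adjustment across the panel, and a linear fold
#' change computed as the ratio of group means of linear RQ (set
#' `fc_basis = "log2"` for `2^(difference of mean log2 RQ)`).
#'
#' @param rq An `rq_matrix` (see [cq_to_rq()]).
#' @param groups Character of length 2: the group labels to compare
#'   (numerator first). Defaults to the two labels present in
#'   `rq$meta$group`.
#' @param q_cutoff Significance cutoff on the adjusted p-value (default
#'   0.05).
#' @param var_equal Pooled-variance t-test if `TRUE` (default Welch).
#' @param fc_basis `"linear"` (default) or `"log2"`.
#' @return Data frame of class `de_result`: `gene`, `fold_change`,
#'   `log2_fold_change`, `t_stat`, `p_value`, `q_value`, `significant`.
#' @export
differential_expression <- function(rq, groups = NULL, q_cutoff = 0.05,
                                    var_equal = FALSE,
                                    fc_basis = c("linear", "log2")) {
  stopifnot(inherits(rq, "rq_matrix"))
  fc_basis <- match.arg(fc_basis)
  g <- rq$meta$group
  if (is.null(groups)) {
    groups <- unique(g)
    if (length(groups) != 2L) {
      stop("specify `groups`: metadata does not contain exactly two labels",
           call. = FALSE)
    }
  }
  i1 <- which(g == groups[1L]); i2 <- which(g == groups[2L])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("need at least 2 cells per group", call. = FALSE)
  }
  genes <- colnames(rq$rq)
  res <- lapply(genes, function(gene) {
    x1 <- rq$log2[i1, gene]; x2 <- rq$log2[i2, gene]
    tt <- tryCatch(stats::t.test(x1, x2, var.equal = var_equal),
                   error = function(e) NULL)  # constant data
    fc <- if (fc_basis == "linear") {
      mean(rq$rq[i1, gene]) / mean(rq$rq[i2, gene])
    } else {
      2^(mean(x1) - mean(x2))
    }
    data.frame(gene = gene, fold_change = fc, log2_fold_change = log2(fc),
               t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_value = if (is.null(tt)) 1 else tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= q_cutoff
  class(out) <- c("de_result", class(out))
  out
}

#' Classify receptor coexpression per cell and per mouse
#'
#' A gene counts as expressed in a cell iff it was detected (i.e. its RQ is
#' a measured value, not the undetected substitution). Cells are partitioned
#' into `neither`, `<gene_a>_only`, `<gene_b>_only` and `both`; percentages
#' are computed within each mouse and then averaged across mice.
#'
#' @param rq An `rq_matrix` (see [cq_to_rq()]).
#' @param gene_a,gene_b Panel gene names (defaults `Slc5a1`, `Tas1r3`: the
#'   sodium-glucose cotransporter and the sweet-taste receptor subunit).
#' @return An object of class `receptor_class`: `$cell_class` (factor per
#'   cell), `$per_mouse` (mouse-by-class percentage data frame) and
#'   `$summary` (per class: across-mice `mean_pct` and `sem_pct`; the s.e.m.
#'   is `NA` with a single mouse).
#' @export
classify_receptors <- function(rq, gene_a = "Slc5a1", gene_b = "Tas1r3") {
  stopifnot(inherits(rq, "rq_matrix"))
  if (!all(c(gene_a, gene_b) %in% colnames(rq$rq))) {
    stop("both receptor genes must be in the panel", call. = FALSE)
  }
  a <- rq$detected[, gene_a]; b <- rq$detected[, gene_b]
  lv <- c("neither", paste0(tolower(gene_a), "_only"),
          paste0(tolower(gene_b), "_only"), "both")
  cls <- factor(ifelse(a & b, lv[4L],
                ifelse(a & !b, lv[2L],
                ifelse(!a & b, lv[3L], lv[1L]))), levels = lv)
  mouse <- rq$meta$mouse_id
  per_mouse <- do.call(rbind, lapply(split(cls, mouse), function(x) {
    100 * table(x) / length(x)
  }))
  per_mouse <- as.data.frame.matrix(per_mouse)
  summary <- data.frame(
    class = lv,
    mean_pct = vapply(lv, function(l) mean(per_mouse[[l]]), numeric(1)),
    sem_pct = vapply(lv, function(l) {
      if (nrow(per_mouse) < 2L) NA_real_ else sem(per_mouse[[l]])
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(cell_class = cls, per_mouse = per_mouse, summary = summary,
                 gene_a = gene_a, gene_b = gene_b),
            class = "receptor_class")
}

#' @export
print.receptor_class <- function(x, ...) {
  cat(sprintf("<receptor_class> %s / %s over %d cells, %d mice\n",
              x$gene_a, x$gene_b, length(x$cell_class), nrow(x$per_mouse)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-14s %.1f%%", x$summary$class[i], x$summary$mean_pct[i]))
    if (!is.na(x$summary$sem_pct[i])) {
      cat(sprintf(" ± %.1f%%", x$summary$sem_pct[i]))
    }
    cat("\n")
  }
  invisible(x)
}
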