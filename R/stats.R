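# Cohort statistics: detection-limit substitution, ROI-to-sample averaging,
# and Spearman correlation of hormone levels with image metrics.

#' Default lower-limit-of-detection table
#'
#' Assay detection limits and the fixed values substituted for censored
#' readings, per menstrual phase. Follicular-phase assays report values below
#' 22 pg/mL (estradiol) and 0.05 ng/mL (progesterone) as below-LLD and these
#' are substituted at 22 pg/mL and 0.05 ng/mL; luteal-phase assays have LLDs
#' of 20 pg/mL and 0.09 ng/mL with substitutes of approximately half the LLD,
#' 10 pg/mL and 0.05 ng/mL.
#'
#' @return Nested list keyed by phase (`FOL`, `LUT`) with elements
#'   `estradiol_lld`, `estradiol_sub`, `progesterone_lld`,
#'   `progesterone_sub`.
#' @export
lld_defaults <- function() {
  list(FOL = list(estradiol_lld = 22, estradiol_sub = 22,
                  progesterone_lld = 0.05, progesterone_sub = 0.05),
       LUT = list(estradiol_lld = 20, estradiol_sub = 10,
                  progesterone_lld = 0.09, progesterone_sub = 0.05))
}

#' Substitute fixed values for below-LLD hormone readings
#'
#' Rows flagged below the lower limit of detection receive the phase-specific
#' substitute value; detected values pass through unchanged. The operation is
#' idempotent.
#'
#' @param hormones Data frame with columns `phase`, `estradiol_pg_ml`,
#'   `estradiol_below_lld`, `progesterone_ng_ml`, `progesterone_below_lld`.
#' @param lld Substitution table as from [lld_defaults()].
#' @return The data frame with substituted values.
#' @export
substitute_lld <- function(hormones, lld = lld_defaults()) {
  stopifnot(is.data.frame(hormones))
  req <- c("phase", "estradiol_pg_ml", "estradiol_below_lld",
           "progesterone_ng_ml", "progesterone_below_lld")
  missing_cols <- setdiff(req, names(hormones))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(as.character(hormones$phase)), names(lld))
  if (length(bad)) stop("unknown phase: ", paste(bad, collapse = ", "))
  for (ph in unique(as.character(hormones$phase))) {
    i <- hormones$phase == ph
    hormones$estradiol_pg_ml[i & hormones$estradiol_below_lld] <-
      lld[[ph]]$estradiol_sub
    hormones$progesterone_ng_ml[i & hormones$progesterone_below_lld] <-
      lld[[ph]]$progesterone_sub
  }
  hormones
}

#' Average per-ROI metrics to one record per sample
#'
#' Unweighted arithmetic mean of every numeric metric column per sample (and
#' channel, when present), as the sample-level value used for statistics. A
#' missing metric in some ROI is averaged over the available ROIs with a
#' warning. The ROI count is recorded in `n_rois`.
#'
#' @param per_roi Data frame of per-ROI metrics containing `sample_id` and
#'   optionally `channel`.
#' @return Data frame with one row per sample (per channel).
#' @export
average_rois <- function(per_roi) {
  stopifnot(is.data.frame(per_roi), "sample_id" %in% names(per_roi),
            nrow(per_roi) >= 1L)
  by_cols <- intersect(c("sample_id", "channel"), names(per_roi))
  num_cols <- names(per_roi)[vapply(per_roi, is.numeric, logical(1))]
  if (!length(num_cols)) stop("no numeric metric columns to average")
  if (anyNA(per_roi[num_cols])) {
    warning("missing metric values; averaging over available ROIs")
  }
  key <- interaction(per_roi[by_cols], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(per_roi)), key)
  rows <- lapply(groups, function(i) {
    out <- per_roi[i[1L], by_cols, drop = FALSE]
    for (cn in num_cols) out[[cn]] <- mean(per_roi[[cn]][i], na.rm = TRUE)
    out$n_rois <- length(i)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# All permutations of 1..n as an (n! x n) integer matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(rep(k, nrow(p)), p + (p >= k))
  }))
}

#' Spearman rank correlation with exact small-sample permutation p-value
#'
#' The coefficient is the Pearson correlation of mid-ranks (average ranks for
#' ties). The two-sided p-value comes from exhaustive enumeration of all n!
#' permutations when n <= 9 (`"exact_permutation"`), or from the large-sample
#' t approximation with n - 2 degrees of freedom otherwise; `"auto"` switches
#' between the two at n = 9. No multiple-testing correction is applied.
#'
#' @param x,y Paired numeric vectors, n >= 3, neither constant.
#' @param p_method `"auto"`, `"exact_permutation"` or `"large_sample"`.
#' @return List of class `correlation_result` with `rho`, `p_value`, `n` and
#'   `p_method`.
#' @export
spearman_cor <- function(x, y,
                         p_method = c("auto", "exact_permutation",
                                      "large_sample")) {
  p_method <- match.arg(p_method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("undefined correlation: constant input")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (p_method == "auto") {
    p_method <- if (n <= 9L) "exact_permutation" else "large_sample"
  }
  p <- if (p_method == "exact_permutation") {
    if (n > 9L) stop("exact permutation limited to n <= 9")
    perms <- all_permutations(n)
    cross <- matrix(ry[perms], nrow(perms), n) %*% rx
    rho_perm <- (cross - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      .Machine$double.xmin
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  structure(list(rho = as.numeric(rho), p_value = as.numeric(p), n = n,
                 p_method = p_method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.3f, p = %.4g (%s), n = %d\n",
              x$rho, x$p_value, x$p_method, x$n))
  invisible(x)
}

#' Correlate hormone levels with sample-level image metrics
#'
#' One Spearman correlation per (channel, metric, hormone), with pairwise
#' deletion of incomplete pairs and the per-result n recorded. Metrics with
#' fewer than 3 complete pairs are skipped with a warning. No multiple-testing
#' correction is applied by default; set `adjust = "BH"` for
#' Benjamini-Hochberg adjusted p-values in an extra column.
#'
#' @param samples Data frame of sample-level records (one row per sample and
#'   channel) as from [average_rois()] merged with substituted hormone values.
#' @param hormones Hormone columns to correlate (default estradiol and
#'   progesterone).
#' @param metrics Metric columns; defaults to the standard image metrics
#'   present in `samples`.
#' @param p_method Passed to [spearman_cor()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tidy data frame with columns `channel`, `metric`, `hormone`,
#'   `phase`, `rho`, `p`, `n` (and `p_adj` when `adjust = "BH"`).
#' @export
correlate_cohort <- function(samples,
                             hormones = c("estradiol_pg_ml",
                                          "progesterone_ng_ml"),
                             metrics = NULL,
                             p_method = "auto",
                             adjust = c("none", "BH")) {
  stopifnot(is.data.frame(samples))
  adjust <- match.arg(adjust)
  if (is.null(metrics)) {
    metrics <- intersect(c("mfi_epithelium", "mfi_intermediate", "height_um",
                           "pct_accessible", "pct_intact",
                           "pct_fragmented_intermediate"),
                         names(samples))
  }
  missing_cols <- setdiff(c(hormones, metrics), names(samples))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  channels <- if ("channel" %in% names(samples)) {
    unique(samples$channel)
  } else NA_character_
  phase <- if ("phase" %in% names(samples)) {
    paste(sort(unique(as.character(samples$phase))), collapse = "+")
  } else NA_character_
  rows <- list()
  for (ch in channels) {
    sub <- if (is.na(ch)) samples else samples[samples$channel == ch, ]
    for (h in hormones) {
      for (m in metrics) {
        ok <- is.finite(sub[[h]]) & is.finite(sub[[m]])
        if (sum(ok) < 3L) {
          warning(sprintf("skipping %s vs %s: fewer than 3 complete pairs",
                          h, m))
          next
        }
        res <- tryCatch(spearman_cor(sub[[h]][ok], sub[[m]][ok],
                                     p_method = p_method),
                        error = function(e) NULL)
        if (is.null(res)) {
          warning(sprintf("skipping %s vs %s: %s", h, m, "undefined correlation"))
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, metric = m, hormone = h, phase = phase,
          rho = res$rho, p = res$p_value, n = res$n)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channel = character(0), metric = character(0),
               hormone = character(0), phase = character(0),
               rho = numeric(0), p = numeric(0), n = integer(0))
  if (adjust == "BH" && nrow(out)) out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}
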