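# Differential-expression pre-screen: per-probe Welch t test,
# Benjamini-Hochberg adjustment, and a fold-change + significance filter
# that reduces the feature space handed to the GA-SVM.
#
# The test is a plain Welch two-sample t with Satterthwaite degrees of
# freedom rather than an empirical-Bayes moderated t: with dozens of samples
# per probe the moderation effect on the filter is marginal and the screen's
# role here is dimension reduction, not inference.

#' Welch two-sample t test for one probe
#'
#' @param case_values,control_values Numeric vectors (each of length >= 2).
#' @return Named numeric vector `c(t_stat, p_value)`; the statistic is
#'   oriented case minus control.  When both groups have zero variance and
#'   equal means the statistic is defined as 0 with p = 1; with unequal
#'   means it is signed infinite with p = 0.
#' @export
welch_t <- function(case_values, control_values) {
  if (length(case_values) < 2L || length(control_values) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(case_values)) || !all(is.finite(control_values))) {
    stop("values must be finite", call. = FALSE)
  }
  res <- row_welch(rbind(c(case_values, control_values)),
                   seq_along(case_values),
                   length(case_values) + seq_along(control_values))
  c(t_stat = res$t[1L], p_value = res$p[1L])
}

# vectorized Welch t over the rows of a matrix; returns t, p, df and the
# case-minus-control mean difference per row
row_welch <- function(x, case_idx, ctrl_idx) {
  n1 <- length(case_idx)
  n2 <- length(ctrl_idx)
  x1 <- x[, case_idx, drop = FALSE]
  x2 <- x[, ctrl_idx, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  t <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    tied <- degenerate & diff == 0
    t[tied] <- 0
    p[tied] <- 1
    apart <- degenerate & diff != 0
    t[apart] <- sign(diff[apart]) * Inf
    p[apart] <- 0
  }
  list(t = t, p = p, df = df, diff = diff)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin, validating wrapper around `stats::p.adjust(method = "BH")`:
#' with the inputs sorted ascending, the adjusted value at rank i is
#' `min_{j >= i} p_(j) * m / j`, capped at 1, returned in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("'p_values' must be numeric", call. = FALSE)
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Screen differentially expressed probes
#'
#' Runs a per-probe Welch t test of case vs control, adjusts the p-values by
#' Benjamini-Hochberg, computes the log2 fold change as mean(case) -
#' mean(control) of the stored log2 values, and keeps the probes passing
#' both the fold-change and adjusted-significance filter.
#'
#' @param x Expression matrix (probes x samples, log2 scale).
#' @param labels Named `-1`/`+1` vector covering the samples of `x`.
#' @param fc_threshold Fold-change cutoff (default 1).  On the default
#'   `fc_scale = "log2"` a probe passes when `|log2_fc| >= fc_threshold`,
#'   i.e. at least a 2-fold linear change at the default; with
#'   `fc_scale = "linear"` when `max(r, 1/r) >= fc_threshold` for the linear
#'   ratio `r = 2^log2_fc`.
#' @param alpha Adjusted-p cutoff; a probe passes when `adj_p < alpha`.
#' @param fc_scale Scale on which `fc_threshold` is interpreted.
#' @return A list with `results` (data.frame: `probe_id`, `t_stat`,
#'   `p_value`, `adj_p`, `log2_fc`, `keep`) and `filtered` (the matrix
#'   restricted to kept probes, original order).
#' @export
screen_degs <- function(x, labels, fc_threshold = 1.0, alpha = 0.05,
                        fc_scale = c("log2", "linear")) {
  fc_scale <- match.arg(fc_scale)
  x <- validate_expression_matrix(x)
  y <- check_labels(x, labels)
  assert_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1L ||
      is.na(fc_threshold) || fc_threshold < 0) {
    stop("'fc_threshold' must be a nonnegative number", call. = FALSE)
  }
  case_idx <- which(y == CLASS_CODES[["case"]])
  ctrl_idx <- which(y == CLASS_CODES[["control"]])
  if (length(case_idx) < 2L || length(ctrl_idx) < 2L) {
    stop("each class needs at least 2 samples for the screen", call. = FALSE)
  }
  w <- row_welch(x, case_idx, ctrl_idx)
  adj <- bh_adjust(w$p)
  fc_pass <- if (fc_scale == "log2") {
    abs(w$diff) >= fc_threshold
  } else {
    pmax(2^w$diff, 2^(-w$diff)) >= fc_threshold
  }
  keep <- fc_pass & adj < alpha
  results <- data.frame(
    probe_id = rownames(x),
    t_stat = w$t,
    p_value = w$p,
    adj_p = adj,
    log2_fc = w$diff,
    keep = keep,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(results = results, filtered = x[keep, , drop = FALSE])
}
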