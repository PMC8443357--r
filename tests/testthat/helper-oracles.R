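# Independent brute-force oracles and small fixture builders shared across
# the suite.  The oracles deliberately use naive algorithms so they cannot
# share a code path with the implementations they check.

# All-pairs Mann-Whitney AUC: for every (case, control) pair credit 1 if the
# case outranks the control on case-oriented scores, 0.5 on a tie.
auc_bruteforce <- function(scores, truth) {
  s <- -scores  # case-oriented: cases should score high
  pos <- s[truth == -1]
  neg <- s[truth == +1]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(pos) * length(neg))
}

# Double-loop Benjamini-Hochberg step-up: with p sorted ascending,
# adj_(i) = min(1, min_{j >= i} (m / j) * p_(j)), back in input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  out <- numeric(m)
  for (i in seq_len(m)) {
    mn <- Inf
    for (j in i:m) mn <- min(mn, (m / j) * ps[j])
    out[o[i]] <- min(1, mn)
  }
  out
}

# Two well-separated point clouds in two dimensions, four samples per class,
# as an expression matrix (2 probes x 8 samples) plus labels.
separable_toy <- function(gap = 6) {
  base <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  pts <- rbind(base, base + gap)
  x <- t(pts)
  rownames(x) <- c("probe_a", "probe_b")
  colnames(x) <- sprintf("s%02d", seq_len(8))
  y <- stats::setNames(rep(c(-1L, 1L), each = 4L), colnames(x))
  list(x = x, y = y)
}

# Write a small expression matrix / label table pair to temp files.
write_toy_files <- function(x, y, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ep <- file.path(dir, "expr.tsv")
  lp <- file.path(dir, "labels.tsv")
  write_expression(x, ep)
  write_labels(y, lp)
  list(expression = ep, labels = lp, dir = dir)
}
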