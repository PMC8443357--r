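# Synthetic two-class expression data with planted differential probes.
#
# The generator emulates the shape of a whole-blood microarray case/control
# cohort (44 cases vs 30 controls by default) on the log2 scale: every probe
# gets a baseline mean drawn uniformly from a typical log2-intensity range,
# Gaussian measurement noise is added per sample, and a chosen subset of
# probes carries a constant additive log2 shift in the case class.

#' Specify a synthetic two-class expression dataset
#'
#' Defaults mirror a 44-case / 30-control cohort with a compact probe panel
#' (500 probes, 25 of them shifted by 2 log2 units, i.e. 4-fold) so that
#' full pipeline runs finish in seconds.
#'
#' @param n_cases,n_controls Samples per class (each >= 2).
#' @param n_probes Total number of probes.
#' @param n_informative Number of probes carrying a true class shift
#'   (`<= n_probes`).
#' @param shift_delta Additive case-minus-control shift for informative
#'   probes, in log2 units.
#' @param noise_sd Per-sample Gaussian noise standard deviation, log2 units
#'   (> 0).
#' @param baseline_range Length-2 numeric, uniform range of per-probe
#'   baseline means (log2 units).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cases = 44, n_controls = 30, n_probes = 500,
                           n_informative = 25, shift_delta = 2.0,
                           noise_sd = 0.7, baseline_range = c(4, 12),
                           seed = 1) {
  spec <- list(
    n_cases = assert_count(n_cases, "n_cases", min = 2L),
    n_controls = assert_count(n_controls, "n_controls", min = 2L),
    n_probes = assert_count(n_probes, "n_probes", min = 1L),
    n_informative = assert_count(n_informative, "n_informative", min = 0L),
    shift_delta = assert_scalar_number(shift_delta, "shift_delta"),
    noise_sd = assert_scalar_number(noise_sd, "noise_sd"),
    baseline_range = baseline_range,
    seed = assert_count(seed, "seed")
  )
  if (spec$n_informative > spec$n_probes) {
    stop("'n_informative' cannot exceed 'n_probes'", call. = FALSE)
  }
  if (spec$noise_sd <= 0) stop("'noise_sd' must be > 0", call. = FALSE)
  if (!is.numeric(baseline_range) || length(baseline_range) != 2L ||
      baseline_range[1L] >= baseline_range[2L]) {
    stop("'baseline_range' must be an increasing (low, high) pair",
         call. = FALSE)
  }
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Per probe g a baseline mean mu_g ~ Uniform(baseline_range) is drawn;
#' control values are Normal(mu_g, noise_sd) and case values are
#' Normal(mu_g + shift_g, noise_sd), with shift_g = `shift_delta` for the
#' `n_informative` probes sampled without replacement and 0 otherwise.
#'
#' @param spec A [synthetic_spec()] (a plain list with the same fields is
#'   coerced).
#' @return A list with `x` (probes x samples matrix), `y` (named `-1`/`+1`
#'   labels, cases first), and `truth` (data.frame of `probe_id`,
#'   `shift`, `informative`).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  probe_ids <- sprintf("probe_%0*d", nchar(spec$n_probes), seq_len(spec$n_probes))
  sample_ids <- c(sprintf("case_%02d", seq_len(spec$n_cases)),
                  sprintf("ctrl_%02d", seq_len(spec$n_controls)))
  n <- spec$n_cases + spec$n_controls
  out <- with_seed(derive_seed(spec$seed, "synth"), {
    mu <- stats::runif(spec$n_probes, spec$baseline_range[1L],
                       spec$baseline_range[2L])
    informative <- sort(sample.int(spec$n_probes, spec$n_informative))
    shift <- numeric(spec$n_probes)
    shift[informative] <- spec$shift_delta
    noise <- matrix(stats::rnorm(spec$n_probes * n, sd = spec$noise_sd),
                    nrow = spec$n_probes)
    vals <- mu + noise
    if (spec$n_cases > 0) {
      vals[, seq_len(spec$n_cases)] <- vals[, seq_len(spec$n_cases)] + shift
    }
    list(vals = vals, shift = shift, informative = informative)
  })
  x <- expression_matrix(out$vals, probe_ids, sample_ids)
  y <- phenotype_labels(sample_ids,
                        rep(c("psoriasis", "control"),
                            c(spec$n_cases, spec$n_controls)))
  truth <- data.frame(
    probe_id = probe_ids,
    shift = out$shift,
    informative = seq_len(spec$n_probes) %in% out$informative,
    stringsAsFactors = FALSE
  )
  list(x = x, y = y, truth = truth, spec = spec)
}

#' Write a synthetic dataset to disk in the package's TSV formats
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`expression`, `labels`, `truth`).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  write_expression(dataset$x, paths$expression)
  write_labels(dataset$y, paths$labels)
  utils::write.table(dataset$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
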