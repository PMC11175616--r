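#' Fragment-analysis peak trace
#'
#' Peaks are in repeat units (integer CAG counts; fragment-size calibration
#' happens upstream) with non-negative heights. The main allele anchors the
#' expansion index; per the published method it comes from the matched tail
#' trace's highest peak, so when it is not supplied the trace's own highest
#' peak is used with a warning.
#'
#' @param position integer repeat-unit positions.
#' @param height peak heights (arbitrary fluorescence units, >= 0).
#' @param main_allele anchoring repeat-unit position (e.g. the tail modal
#'   peak).
#' @param sample_id sample label.
#' @return an object of class `peak_trace`.
#' @export
peak_trace <- function(position, height, main_allele = NULL,
                       sample_id = "sample") {
  stopifnot(length(position) == length(height), all(height >= 0))
  if (length(position) == 0L) stop("empty trace", call. = FALSE)
  if (is.null(main_allele)) {
    main_allele <- position[which.max(height)]
    warning("no tail-anchored main allele supplied; using the trace's highest peak")
  }
  structure(list(sample_id = sample_id,
                 position = as.numeric(position),
                 height = as.numeric(height),
                 main_allele = as.numeric(main_allele)),
            class = "peak_trace")
}

#' @export
print.peak_trace <- function(x, ...) {
  cat(sprintf("<peak_trace> %s: %d peaks, main allele at %g repeat units\n",
              x$sample_id, length(x$position), x$main_allele))
  invisible(x)
}

#' Threshold peaks and normalize heights to fractions
#'
#' Retains peaks whose height is at least `threshold_frac` of the tallest
#' peak (the 10 percent relative-height noise filter) and returns their
#' heights normalized to fractions summing to 1.
#'
#' @param trace a `peak_trace`.
#' @param threshold_frac relative height threshold in (0, 1).
#' @return data.frame with `position`, `height`, `fraction`.
#' @export
threshold_peaks <- function(trace, threshold_frac = 0.10) {
  stopifnot(inherits(trace, "peak_trace"),
            threshold_frac > 0, threshold_frac < 1)
  keep <- trace$height >= threshold_frac * max(trace$height)
  h <- trace$height[keep]
  data.frame(position = trace$position[keep], height = h,
             fraction = h / sum(h))
}

#' Expansion index of a peak trace
#'
#' Height-weighted mean repeat-unit gain over the main allele: with retained
#' peak fractions f_i and repeat changes delta_i = position_i - main_allele,
#' the index is `sum over delta_i > 0 of f_i * delta_i`. An
#' interruption-stabilized repeat with all mass at the modal allele scores
#' 0.
#'
#' @param trace a `peak_trace`.
#' @param threshold_frac relative height threshold (default 0.10).
#' @return expansion index in repeat units.
#' @export
expansion_index <- function(trace, threshold_frac = 0.10) {
  p <- threshold_peaks(trace, threshold_frac)
  d <- p$position - trace$main_allele
  sum(p$fraction[d > 0] * d[d > 0])
}

#' Contraction index of a peak trace
#'
#' The mirror quantity over peaks left of the main allele:
#' `sum over delta_i < 0 of f_i * |delta_i|`. Reported separately; it never
#' enters the expansion index.
#'
#' @inheritParams expansion_index
#' @return contraction index in repeat units (>= 0).
#' @export
contraction_index <- function(trace, threshold_frac = 0.10) {
  p <- threshold_peaks(trace, threshold_frac)
  d <- p$position - trace$main_allele
  sum(p$fraction[d < 0] * -d[d < 0])
}

#' Read peak tables and a sample sheet into instability samples
#'
#' @param peaks_csv CSV with columns `sample_id`, `position_units`,
#'   `height`.
#' @param samples_csv CSV with columns `sample_id`, `treatment`, `tail_cag`,
#'   `age`, `sex`, `batch` (and optionally `main_allele`).
#' @return data.frame of covariates with a list-column `trace` of
#'   `peak_trace` objects (anchored at `main_allele` when present, else
#'   `tail_cag`).
#' @export
read_instability_tables <- function(peaks_csv, samples_csv) {
  pk <- utils::read.csv(peaks_csv, stringsAsFactors = FALSE)
  sm <- utils::read.csv(samples_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "position_units", "height") %in% names(pk)),
            all(c("sample_id", "treatment", "tail_cag", "age", "sex",
                  "batch") %in% names(sm)))
  sm$trace <- lapply(sm$sample_id, function(id) {
    sub <- pk[pk$sample_id == id, , drop = FALSE]
    anchor <- if ("main_allele" %in% names(sm))
      sm$main_allele[sm$sample_id == id][1] else
      sm$tail_cag[sm$sample_id == id][1]
    peak_trace(sub$position_units, sub$height, main_allele = anchor,
               sample_id = id)
  })
  sm
}

#' Linear regression of expansion index on treatment and covariates
#'
#' Ordinary least squares of the expansion index on treatment, tail CAG,
#' age, sex and experimental batch. Categorical covariates are
#' reference-coded with PBS, female, and the first batch level as
#' references. Errors on rank deficiency, naming the collinear columns.
#'
#' @param samples data.frame with columns `expansion_index`, `treatment`
#'   (levels PBS/BE), `tail_cag`, `age`, `sex`, `batch`.
#' @return data.frame coefficient table (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`) with the `lm` fit as attribute `fit`.
#' @export
instability_regression <- function(samples) {
  req <- c("expansion_index", "treatment", "tail_cag", "age", "sex", "batch")
  stopifnot(all(req %in% names(samples)))
  samples$treatment <- factor(samples$treatment)
  if (nlevels(samples$treatment) < 2L)
    stop("treatment must have both levels", call. = FALSE)
  if ("PBS" %in% levels(samples$treatment))
    samples$treatment <- stats::relevel(samples$treatment, ref = "PBS")
  samples$sex <- if ("female" %in% samples$sex)
    stats::relevel(factor(samples$sex), ref = "female") else factor(samples$sex)
  samples$batch <- factor(samples$batch)
  form <- expansion_index ~ treatment + tail_cag + age
  if (nlevels(samples$sex) > 1L) form <- stats::update(form, . ~ . + sex)
  if (nlevels(samples$batch) > 1L) form <- stats::update(form, . ~ . + batch)
  fit <- stats::lm(form, data = samples)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  out <- data.frame(term = rownames(cf), estimate = cf[, 1],
                    std.error = cf[, 2], statistic = cf[, 3],
                    p.value = cf[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}
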