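#' Age-at-onset model
#'
#' Either a parametric exponential-decay model, `onset = alpha + exp(beta -
#' gamma * CAG)` (strictly decreasing in CAG for gamma > 0), or a lookup
#' table of mean onsets by CAG length. The default coefficients are
#' simulation defaults from the published onset-CAG literature family, not
#' estimates re-derived from any cohort.
#'
#' @param alpha asymptotic onset (years).
#' @param beta unitless intercept of the exponential term.
#' @param gamma per-CAG decay rate (> 0).
#' @param residual_sd optional residual SD (years), carried as metadata.
#' @return an object of class `onset_model`.
#' @export
onset_model <- function(alpha = 21.5, beta = 9.56, gamma = 0.146,
                        residual_sd = NA_real_) {
  stopifnot(gamma > 0)
  structure(list(type = "parametric", alpha = alpha, beta = beta,
                 gamma = gamma, residual_sd = residual_sd),
            class = "onset_model")
}

#' @rdname onset_model
#' @param onset named numeric vector or data.frame-like mapping CAG length
#'   to mean onset (years); names (or `cag`) are CAG lengths.
#' @export
onset_table <- function(onset) {
  if (is.data.frame(onset)) {
    tab <- stats::setNames(onset$onset, onset$cag)
  } else {
    tab <- onset
  }
  stopifnot(!is.null(names(tab)), all(!is.na(as.numeric(names(tab)))))
  structure(list(type = "table", table = tab, residual_sd = NA_real_),
            class = "onset_model")
}

#' @export
print.onset_model <- function(x, ...) {
  if (x$type == "parametric")
    cat(sprintf("<onset_model> onset = %.3g + exp(%.3g - %.3g * CAG)\n",
                x$alpha, x$beta, x$gamma))
  else
    cat(sprintf("<onset_model> lookup table over CAG {%s}\n",
                paste(names(x$table), collapse = ", ")))
  invisible(x)
}

#' Expected age-at-onset for a CAG repeat length
#'
#' @param model an `onset_model`.
#' @param cag uninterrupted CAG length(s); for a table model every value
#'   must be present in the table.
#' @return expected onset in years (vectorized).
#' @export
expected_onset <- function(model, cag) {
  stopifnot(inherits(model, "onset_model"))
  if (model$type == "parametric") {
    return(model$alpha + exp(model$beta - model$gamma * cag))
  }
  key <- as.character(cag)
  if (!all(key %in% names(model$table)))
    stop("CAG length(s) absent from onset table: ",
         paste(setdiff(key, names(model$table)), collapse = ", "),
         call. = FALSE)
  unname(model$table[key])
}

#' Fit the exponential onset model to canonical-repeat records
#'
#' Least-squares fit of `onset = alpha + exp(beta - gamma * CAG)`. gamma is
#' profiled: for each candidate decay rate the remaining parameters solve a
#' linear regression on `exp(-gamma * CAG)`, and the profile is minimized by
#' golden-section refinement around the best grid point. This avoids the
#' start-value sensitivity of a direct nonlinear optimizer on this family.
#'
#' @param records data.frame with numeric columns `cag` and `onset`.
#' @param gamma_grid candidate decay rates for the profile scan.
#' @return an `onset_model` with fitted coefficients and `residual_sd`.
#' @export
fit_onset_model <- function(records, gamma_grid = seq(0.02, 0.5, by = 0.005)) {
  cag <- records$cag; onset <- records$onset
  if (length(unique(cag)) < 3L)
    stop("need at least 3 distinct CAG values to fit the onset model",
         call. = FALSE)
  prof <- function(g) {
    x <- exp(-g * cag)
    f <- stats::lm.fit(cbind(1, x), onset)
    rss <- sum(f$residuals^2)
    list(rss = rss, alpha = f$coefficients[1], b = f$coefficients[2])
  }
  rss <- vapply(gamma_grid, function(g) prof(g)$rss, numeric(1))
  i <- which.min(rss)
  lo <- gamma_grid[max(1L, i - 1L)]; hi <- gamma_grid[min(length(gamma_grid), i + 1L)]
  opt <- stats::optimize(function(g) prof(g)$rss, c(lo, hi), tol = 1e-8)
  g <- opt$minimum
  p <- prof(g)
  if (p$b <= 0)
    stop("onset model fit failed: exponential term coefficient is not positive",
         call. = FALSE)
  n <- length(onset)
  onset_model(alpha = unname(p$alpha), beta = unname(log(p$b)), gamma = g,
              residual_sd = sqrt(p$rss / max(1L, n - 3L)))
}

#' Residual sum of squares at a candidate CAG offset
#'
#' `SS = sum((observed onset - expected onset at CAG + offset)^2)`.
#'
#' @param records data.frame with columns `cag`, `onset`.
#' @param model an `onset_model`.
#' @param offset signed CAG offset applied to every record.
#' @return SS in years^2.
#' @export
residual_ss <- function(records, model, offset = 0) {
  pred <- expected_onset(model, records$cag + offset)
  sum((records$onset - pred)^2)
}

#' Estimate the structure-class CAG offset by grid search
#'
#' Evaluates [residual_ss()] over an integer grid of candidate offsets and
#' returns the minimizer, the published procedure of gradually shifting the
#' CAG length until the sum of squares is smallest. Ties are broken toward
#' the smaller |offset| (parsimony).
#'
#' @param records cohort records of a single structure class (`cag`,
#'   `onset`).
#' @param model the canonical-repeat `onset_model`.
#' @param grid integer offsets to evaluate.
#' @return object of class `offset_fit`: `grid`, `ss`, `best_offset`.
#' @export
estimate_offset <- function(records, model, grid = -10:10) {
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  stopifnot(length(grid) >= 1L)
  ss <- vapply(grid, function(o) residual_ss(records, model, o), numeric(1))
  best <- grid[order(ss, abs(grid))][1L]
  structure(list(grid = grid, ss = stats::setNames(ss, grid),
                 best_offset = best),
            class = "offset_fit")
}

#' @export
print.offset_fit <- function(x, ...) {
  cat(sprintf("<offset_fit> best offset %+d (SS %.1f) over grid %d..%d\n",
              x$best_offset, x$ss[as.character(x$best_offset)],
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Write an offset fit as JSON (plus optional SS-vs-offset TSV)
#' @param fit an `offset_fit`.
#' @param path JSON output path.
#' @param tsv optional TSV path for the SS profile.
#' @return `path`, invisibly.
#' @export
write_offset_fit <- function(fit, path, tsv = NULL) {
  jsonlite::write_json(list(grid = fit$grid, ss = unname(fit$ss),
                            best_offset = fit$best_offset),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv))
    utils::write.table(data.frame(offset = fit$grid, ss = unname(fit$ss)),
                       tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Predicted onset delay from an in-silico edit
#'
#' Applies [apply_conversion()] at `edit_site`, maps both alleles to their
#' canonical-equivalent effective CAG via the class offsets, and returns the
#' difference in expected onset (edited minus original). Positive values are
#' onset delays.
#'
#' @param allele the unedited `repeat_allele`.
#' @param edit_site 1-based CAG index to convert.
#' @param offsets class-offset map (see [effective_cag()]).
#' @param model an `onset_model` supporting both effective CAG values.
#' @return delay in years.
#' @export
onset_delay <- function(allele, edit_site, offsets = c(LOI = 3, DI = -1),
                        model) {
  edited <- apply_conversion(allele, edit_site)
  expected_onset(model, effective_cag(edited, offsets)) -
    expected_onset(model, effective_cag(allele, offsets))
}
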