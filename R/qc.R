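#' Per-sample staggered standard curve
#'
#' For a sample spiked with a staggered mimic pool, regresses
#' log10(percentage of reads within the mimic subcomposition) on
#' log10(copies added), by ordinary least squares. A slope near 1 with high
#' R-squared indicates consistent quantification across mimics and
#' concentrations; systematic departures flag bias anywhere between PCR and
#' bioinformatics.
#'
#' @param mimic_counts named numeric vector of reads per mimic in the sample.
#' @param copies named numeric vector of spike copies per mimic (names
#'   matched to `mimic_counts`).
#' @param exclude mimic ids left out of the fit (e.g. constructs with known
#'   primer-binding differences for a given primer set).
#' @return a `standard_curve_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `n_points`, `excluded`, `flag` (`""` or `"too_few_points"`).
#' @export
staggered_curve <- function(mimic_counts, copies, exclude = character(0)) {
  stopifnot(!is.null(names(mimic_counts)), !is.null(names(copies)))
  copies <- copies[names(mimic_counts)]
  if (any(is.na(copies))) {
    stop("copies missing for mimic(s): ",
         paste(names(mimic_counts)[is.na(copies)], collapse = ", "),
         call. = FALSE)
  }
  usable <- setdiff(names(mimic_counts)[mimic_counts > 0], exclude)
  dropped <- union(exclude, names(mimic_counts)[mimic_counts == 0])
  if (length(usable) < 3L) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n_points = length(usable),
                          excluded = dropped, flag = "too_few_points"),
                     class = "standard_curve_fit"))
  }
  pct <- 100 * mimic_counts[usable] / sum(mimic_counts[usable])
  fit <- lm(log10(pct) ~ log10(copies[usable]))
  r2 <- withCallingHandlers(
    summary(fit)$r.squared,
    # exact power-law inputs legitimately fit perfectly
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    n_points = length(usable),
    excluded = dropped,
    flag = ""
  ), class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  if (nzchar(x$flag)) {
    cat("Standard curve: flagged (", x$flag, "), n =", x$n_points, "\n")
  } else {
    cat(sprintf("Standard curve: slope %.3f, R^2 %.4f (n = %d)\n",
                x$slope, x$r_squared, x$n_points))
  }
  invisible(x)
}

#' Rectangular-hyperbola dose-response fit
#'
#' Least-squares fit of the two-parameter rectangular hyperbola
#' `y = a * x / (b + x)` (Michaelis-Menten form) to spike-in reads at fixed
#' sequencing depth versus spike copies. At fixed depth the expected reads
#' saturate: `a` is the asymptotic read count and `b` the spike level at
#' half-saturation. Fit via Levenberg-Marquardt least squares
#' ([minpack.lm::nlsLM()], robust on exactly-generated zero-residual data);
#' non-convergence or degenerate data yields a flagged result instead of an
#' error.
#'
#' @param spike_levels spike copies per observation (>= 3 distinct values).
#' @param reads mimic read counts at fixed depth.
#' @return a `hyperbola_fit`: list with `asymptote`, `half_saturation`,
#'   `residuals`, `rss`, `flag`.
#' @export
hyperbola_fit <- function(spike_levels, reads) {
  stopifnot(length(spike_levels) == length(reads), all(spike_levels > 0),
            all(reads >= 0))
  if (length(unique(spike_levels)) < 3L) {
    stop("need >= 3 distinct spike levels", call. = FALSE)
  }
  flagged <- function(flag) {
    structure(list(asymptote = NA_real_, half_saturation = NA_real_,
                   residuals = rep(NA_real_, length(reads)), rss = NA_real_,
                   flag = flag), class = "hyperbola_fit")
  }
  if (sd(reads) == 0) return(flagged("degenerate_constant_reads"))
  df <- data.frame(x = spike_levels, y = reads)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Vm * x / (K + x), data = df,
                      start = list(Vm = max(reads), K = stats::median(spike_levels)),
                      lower = c(Vm = 1e-12, K = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged("no_convergence"))
  p <- coef(fit)
  if (p[["Vm"]] <= 0 || p[["K"]] <= 0) return(flagged("invalid_parameters"))
  structure(list(asymptote = unname(p[["Vm"]]),
                 half_saturation = unname(p[["K"]]),
                 residuals = unname(resid(fit)),
                 rss = sum(resid(fit)^2),
                 flag = ""), class = "hyperbola_fit")
}

#' @export
print.hyperbola_fit <- function(x, ...) {
  if (nzchar(x$flag)) {
    cat("Hyperbola fit: flagged (", x$flag, ")\n")
  } else {
    cat(sprintf("Hyperbola fit: asymptote %.1f reads, half-saturation %.3g copies\n",
                x$asymptote, x$half_saturation))
  }
  invisible(x)
}

#' Per-sample spike-in QC flags
#'
#' Operationalizes the exclusion rules of spike-in experiments: too few
#' mimic reads for stable quantification (`low_spike_reads`), mimic reads
#' swamping the library (`spike_saturation`), and, when standard-curve fits
#' are supplied, slopes or R-squared outside the configured bands
#' (`slope_out_of_band`, `low_r_squared`). Pure function of its inputs.
#'
#' @param assign an [assign_features()] result.
#' @param spike a [spike_config()] (declared-mimic bookkeeping; unused mimics
#'   do not trigger flags).
#' @param fits optional named list (per sample) of
#'   [staggered_curve()] results.
#' @param min_mimic_reads threshold below which total mimic reads flag the
#'   sample (default 50).
#' @param max_mimic_fraction mimic read fraction above which the sample is
#'   saturation-flagged (default 0.95).
#' @param slope_band,min_r_squared acceptance bands for standard-curve fits.
#' @return data.frame: `sample`, `mimic_reads`, `mimic_fraction`, `flags`
#'   (comma-separated, empty when clean).
#' @export
qc_report <- function(assign, spike, fits = NULL,
                      min_mimic_reads = 50L, max_mimic_fraction = 0.95,
                      slope_band = c(0.9, 1.1), min_r_squared = 0.97) {
  stopifnot(inherits(assign, "assignment_result"))
  samples <- colnames(assign$mimic_counts)
  rows <- lapply(samples, function(s) {
    mreads <- sum(assign$mimic_counts[, s])
    frac <- mreads / assign$total_counts[[s]]
    flags <- character(0)
    if (mreads < min_mimic_reads) flags <- c(flags, "low_spike_reads")
    if (frac > max_mimic_fraction) flags <- c(flags, "spike_saturation")
    if (!is.null(fits) && s %in% names(fits)) {
      f <- fits[[s]]
      if (nzchar(f$flag)) {
        flags <- c(flags, f$flag)
      } else {
        if (f$slope < slope_band[1] || f$slope > slope_band[2]) {
          flags <- c(flags, "slope_out_of_band")
        }
        if (f$r_squared < min_r_squared) flags <- c(flags, "low_r_squared")
      }
    }
    data.frame(sample = s, mimic_reads = mreads, mimic_fraction = frac,
               flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
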