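#' Apply the partner-dilution concentration correction
#'
#' When the partner protein is added from a 10X stock to the titration
#' series, the effective protein concentrations are reduced; the
#' correction multiplies every concentration by 0.9. Without the partner
#' the series is returned unchanged.
#'
#' @param concentrations Numeric vector of concentrations in nM
#'   (nonnegative).
#' @param partner_present Logical; was the partner protein present?
#' @return The (possibly adjusted) concentration vector.
#' @examples
#' adjust_concentrations(c(4000, 0), partner_present = TRUE)
#' @export
adjust_concentrations <- function(concentrations, partner_present) {
  stopifnot(all(concentrations >= 0), is.logical(partner_present))
  if (isTRUE(partner_present)) concentrations * 0.9 else concentrations
}

#' Fit a one-site specific binding isotherm
#'
#' Nonlinear least-squares fit of `Y = Bmax * X / (Kd + X)` to a single
#' titration (no nonspecific/background term). Positivity of both
#' parameters is enforced by fitting on the log scale. Starting values are
#' `Kd0` = the concentration whose signal is nearest half-maximal and
#' `Bmax0` = the maximum observed signal.
#'
#' @param titration A tibble with columns `concentration_nM` and `signal`
#'   (one replicate; >= 5 distinct concentrations, at least one positive
#'   signal).
#' @param partner_present If `TRUE`, concentrations are multiplied by 0.9
#'   via [adjust_concentrations()] before fitting.
#' @return An object of class `one_site_fit`: list with elements `kd`,
#'   `bmax`, `fitted`, `residuals`, `data`, `converged`.
#' @examples
#' tt <- simulate_titration(true_kd = 10, noise_sd = 0, n_replicates = 1,
#'                          seed = 1)
#' fit_one_site(tt)
#' @export
fit_one_site <- function(titration, partner_present = FALSE) {
  x <- adjust_concentrations(titration$concentration_nM, partner_present)
  y <- titration$signal
  if (length(unique(x)) < 5L) {
    stop("need at least 5 distinct concentrations to fit", call. = FALSE)
  }
  if (all(y <= 0)) stop("all signals are zero or negative", call. = FALSE)

  bmax0 <- max(y)
  kd0 <- x[which.min(abs(y - bmax0 / 2))]
  if (kd0 <= 0) kd0 <- min(x[x > 0])

  resid_fn <- function(p) y - exp(p[2]) * x / (exp(p[1]) + x)
  fit <- minpack.lm::nls.lm(
    par = c(lkd = log(kd0), lbmax = log(bmax0)),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  est <- exp(fit$par)
  conv <- fit$info %in% 1:3  # ftol/ptol convergence codes
  if (!conv) {
    stop("one-site fit did not converge (Kd estimate ",
         signif(est[["lkd"]], 3), " nM; ", fit$message, ")", call. = FALSE)
  }
  res <- resid_fn(fit$par)
  structure(
    list(kd = unname(est[["lkd"]]), bmax = unname(est[["lbmax"]]),
         fitted = y - res, residuals = res,
         data = tibble::tibble(concentration_nM = x, signal = y),
         converged = conv),
    class = "one_site_fit"
  )
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat("One-site specific binding fit\n")
  cat("  Kd   =", signif(x$kd, 3), "nM\n")
  cat("  Bmax =", signif(x$bmax, 3), "\n")
  invisible(x)
}

#' @rdname fit_one_site
#' @param x A `one_site_fit` object.
#' @export
tidy.one_site_fit <- function(x, ...) {
  tibble::tibble(term = c("kd", "bmax"),
                 estimate = c(x$kd, x$bmax))
}

#' @rdname fit_one_site
#' @export
glance.one_site_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, bmax = x$bmax,
                 rss = sum(x$residuals^2),
                 n = nrow(x$data),
                 converged = x$converged)
}

#' Fit every replicate of a titration table
#'
#' Splits a long titration table by replicate, fits each with
#' [fit_one_site()], and returns the per-replicate estimates.
#'
#' @param titrations Tibble with columns `replicate_id`,
#'   `concentration_nM`, `signal` (as from [simulate_titration()] or
#'   [read_titrations()]).
#' @param partner_present Passed to [fit_one_site()].
#' @return Tibble with columns `replicate_id`, `kd`, `bmax`.
#' @export
fit_titrations <- function(titrations, partner_present = FALSE) {
  titrations |>
    dplyr::group_by(.data$replicate_id) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_one_site(d, partner_present = partner_present)
      tibble::tibble(kd = f$kd, bmax = f$bmax)
    }) |>
    dplyr::ungroup()
}

#' Aggregate replicate Kd estimates
#'
#' Mean and standard error of the mean over independent per-replicate
#' fits, as conventionally reported for technical-replicate EMSAs.
#'
#' @param fits Tibble with a `kd` column (one row per replicate) or a
#'   numeric vector of Kds; >= 2 replicates required (SEM is undefined for
#'   one).
#' @return Tibble with `kd_mean`, `kd_sem`, `n_replicates`.
#' @examples
#' aggregate_replicates(c(9, 12, 15))
#' @export
aggregate_replicates <- function(fits) {
  kds <- if (is.data.frame(fits)) fits$kd else fits
  if (length(kds) < 2L) {
    stop("need >= 2 replicate fits (SEM undefined for a single replicate)",
         call. = FALSE)
  }
  tibble::tibble(kd_mean = mean(kds),
                 kd_sem = stats::sd(kds) / sqrt(length(kds)),
                 n_replicates = length(kds))
}

#' Relative affinity (Krel) with respect to a reference RNA
#'
#' `Krel = Kd / Kd_reference`, computed from mean Kds measured under the
#' same protein condition. Values above 1 indicate weaker binding than the
#' reference. Conventionally reported to 2 significant figures.
#'
#' @param kd_mean Mean Kd of the RNA of interest (nM).
#' @param reference_kd_mean Mean Kd of the reference RNA (nM), same
#'   protein condition.
#' @return The unrounded Krel.
#' @examples
#' compute_krel(22.0, 10.3)   # ~2.1
#' @export
compute_krel <- function(kd_mean, reference_kd_mean) {
  stopifnot(all(kd_mean > 0), all(reference_kd_mean > 0))
  kd_mean / reference_kd_mean
}

#' Krel column for a table of mean Kds
#'
#' Adds a `krel` column to a tibble of mean Kds, dividing each by the mean
#' Kd of the named reference RNA within each condition group.
#'
#' @param kd_table Tibble with columns `rna`, `kd_mean` and optionally a
#'   grouping column named by `condition`.
#' @param reference RNA label used as the Krel reference.
#' @param condition Optional column name identifying the protein
#'   condition; Krel is computed within each condition.
#' @return `kd_table` with a `krel` column appended.
#' @export
krel_table <- function(kd_table, reference, condition = NULL) {
  grouped <- if (is.null(condition)) kd_table else
    dplyr::group_by(kd_table, .data[[condition]])
  out <- dplyr::mutate(grouped, krel = {
    ref <- .data$kd_mean[.data$rna == reference]
    if (length(ref) != 1L) {
      stop("reference RNA '", reference,
           "' must appear exactly once per condition", call. = FALSE)
    }
    compute_krel(.data$kd_mean, ref)
  })
  dplyr::ungroup(out)
}

#' Normalise reporter luminescence to cell density
#'
#' Plate-reader reporter activity normalised to absorbance at 660 nm to
#' account for differences in cell count.
#'
#' @param luminescence Raw luminescence values (>= 0).
#' @param a660 Absorbance at 660 nm (> 0).
#' @return `luminescence / a660`.
#' @examples
#' normalize_reporter(1000, 0.5)
#' @export
normalize_reporter <- function(luminescence, a660) {
  if (any(a660 <= 0)) stop("a660 must be > 0", call. = FALSE)
  if (any(luminescence < 0)) stop("luminescence must be >= 0", call. = FALSE)
  luminescence / a660
}
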