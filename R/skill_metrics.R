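# Model-skill metric suite used for algorithm optimization and validation,
# plus the Taylor- and target-diagram coordinate operators built on it.

#' Compute the model-skill metric suite
#'
#' Given model retrievals `mod` and reference (field) values `ref`, computes
#' the statistics used throughout algorithm tuning and validation:
#' \describe{
#'   \item{r2}{squared Pearson correlation of mod vs ref.}
#'   \item{r2_adj}{adjusted r2, \eqn{r^2 - (1-r^2)\,\beta_n/(N-\beta_n-1)},
#'     where \eqn{\beta_n} is the number of regressors.  Note this form
#'     differs from the textbook adjusted R^2 (which multiplies by
#'     \eqn{(N-1)/(N-\beta_n-1)}); it is implemented as published.}
#'   \item{rmsd}{root mean square difference, \eqn{\sqrt{\sum(mod-ref)^2/N}}.}
#'   \item{rmsd_centered}{centered (unbiased) RMSD: the RMSD after removing
#'     both means; divisor N, so that rmsd^2 = rmsd_centered^2 + bias^2
#'     holds exactly.}
#'   \item{rmsd_centered_signed}{rmsd_centered times the sign of
#'     STD(mod) - STD(ref).}
#'   \item{bias}{mean(mod - ref).}
#'   \item{bias_norm}{bias / STD(ref) (sample STD, N-1 divisor).}
#'   \item{pct_bias}{100 * mean(mod - ref) / mean(ref).}
#'   \item{mapd}{100 * mean(|mod - ref| / ref), over nonzero refs; the number
#'     of pairs excluded for a zero reference is reported as `n_zero_ref`.}
#' }
#' Pairs with a missing value in either vector are dropped listwise; `n`
#' reflects the survivors.
#'
#' @param mod,ref numeric vectors of equal length (>= 3 complete pairs).
#' @param n_regressors number of regressors \eqn{\beta_n} for the adjusted
#'   r2 (default 0).
#' @return Object of class `skill_report`: list with fields `n`, `std_mod`,
#'   `std_ref` (sample SD), `r2`, `r2_adj`, `rmsd`, `rmsd_centered`,
#'   `rmsd_centered_signed`, `bias`, `bias_norm`, `pct_bias`, `mapd`,
#'   `n_zero_ref`.
#' @export
#' @examples
#' compute_skill(c(1, 2, 3), c(1, 1, 3))
compute_skill <- function(mod, ref, n_regressors = 0) {
  stopifnot(length(mod) == length(ref))
  ok <- is.finite(mod) & is.finite(ref)
  mod <- mod[ok]; ref <- ref[ok]
  n <- length(mod)
  if (n < 3L)
    stop("insufficient-data: fewer than 3 complete pairs", call. = FALSE)
  d <- mod - ref
  bias <- mean(d)
  rmsd <- sqrt(mean(d^2))
  dm <- mod - mean(mod); dr <- ref - mean(ref)
  rmsd_c <- sqrt(mean((dm - dr)^2))
  std_mod <- stats::sd(mod); std_ref <- stats::sd(ref)
  sgn <- sign(std_mod - std_ref); if (sgn == 0) sgn <- 1
  r <- if (std_mod > 0 && std_ref > 0) stats::cor(mod, ref) else NA_real_
  r2 <- if (is.na(r)) NA_real_ else r^2
  # identical vectors have zero variance; the pattern match is perfect
  if (is.na(r2) && isTRUE(all.equal(mod, ref))) r2 <- 1
  r2_adj <- if (is.na(r2)) NA_real_ else
    r2 - (1 - r2) * (n_regressors / (n - n_regressors - 1))
  nz <- ref != 0
  mapd <- if (any(nz)) 100 * mean(abs(d[nz] / ref[nz])) else NA_real_
  structure(
    list(n = n, std_mod = std_mod, std_ref = std_ref, r = r,
         r2 = r2, r2_adj = r2_adj,
         rmsd = rmsd, rmsd_centered = rmsd_c,
         rmsd_centered_signed = sgn * rmsd_c,
         bias = bias,
         bias_norm = if (std_ref > 0) bias / std_ref else NA_real_,
         pct_bias = if (mean(ref) != 0) 100 * bias / mean(ref) else NA_real_,
         mapd = mapd, n_zero_ref = sum(!nz)),
    class = "skill_report")
}

#' @export
print.skill_report <- function(x, ...) {
  cat(sprintf("skill report (n = %d)\n", x$n))
  cat(sprintf("  r2 = %.4f  r2' = %.4f\n", x$r2, x$r2_adj))
  cat(sprintf("  RMSD = %.4g  centered RMSD = %.4g (signed %.4g)\n",
              x$rmsd, x$rmsd_centered, x$rmsd_centered_signed))
  cat(sprintf("  bias = %.4g  Bias* = %.4g  %%Bias = %.3g%%  MAPD = %.3g%%\n",
              x$bias, x$bias_norm, x$pct_bias, x$mapd))
  invisible(x)
}

#' @export
as.data.frame.skill_report <- function(x, ...) {
  data.frame(n = x$n, std_mod = x$std_mod, std_ref = x$std_ref, r2 = x$r2,
             r2_adj = x$r2_adj, rmsd = x$rmsd,
             rmsd_centered = x$rmsd_centered,
             rmsd_centered_signed = x$rmsd_centered_signed, bias = x$bias,
             bias_norm = x$bias_norm, pct_bias = x$pct_bias, mapd = x$mapd)
}

#' Taylor-diagram coordinates
#'
#' Standard deviations, correlation, and centered RMSD for placing a model
#' on a Taylor diagram.  Because the diagram's geometry rests on the law
#' \eqn{RMSD'^2 = \sigma_m^2 + \sigma_r^2 - 2\sigma_m\sigma_r r}, the
#' standard deviations returned here use the same divisor (N) as the
#' centered RMSD, so the law holds exactly; the means (and hence any bias)
#' are removed by construction.
#'
#' @param mod,ref numeric vectors (missing pairs dropped listwise).
#' @return list with `std_mod`, `std_ref`, `std_ratio`, `correlation`,
#'   `rmsd_centered`, `degenerate` (TRUE when either variance is zero).
#' @export
taylor_coordinates <- function(mod, ref) {
  ok <- is.finite(mod) & is.finite(ref)
  mod <- mod[ok]; ref <- ref[ok]
  n <- length(mod)
  if (n < 3L) stop("insufficient-data", call. = FALSE)
  dm <- mod - mean(mod); dr <- ref - mean(ref)
  sm <- sqrt(mean(dm^2)); sr <- sqrt(mean(dr^2))
  degenerate <- sm == 0 || sr == 0
  r <- if (degenerate) NA_real_ else sum(dm * dr) / (n * sm * sr)
  list(std_mod = sm, std_ref = sr,
       std_ratio = if (sr > 0) sm / sr else NA_real_,
       correlation = r,
       rmsd_centered = sqrt(mean((dm - dr)^2)),
       degenerate = degenerate)
}

#' Target-diagram coordinates
#'
#' x is the signed centered RMSD and y the normalized bias, both normalized
#' by the reference standard deviation, so that the distance from the origin
#' is the normalized total RMSD (checked internally).
#'
#' @param report a [compute_skill()] result.
#' @return list with `x`, `y`, `total_rmsd_norm`.
#' @export
target_coordinates <- function(report) {
  stopifnot(inherits(report, "skill_report"))
  if (!is.finite(report$std_ref) || report$std_ref <= 0)
    stop("degenerate reference (zero variance)", call. = FALSE)
  x <- report$rmsd_centered_signed / report$std_ref
  y <- report$bias_norm
  tot <- report$rmsd / report$std_ref
  if (abs(x^2 + y^2 - tot^2) > 1e-8 * max(1, tot^2))
    warning("target-diagram distance identity violated beyond tolerance")
  list(x = x, y = y, total_rmsd_norm = tot)
}
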