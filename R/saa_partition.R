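# Partitioning of combined dissolved + detrital absorption retrieved by
# semi-analytical inversions (QAA/GIOP-style) into its detrital and
# dissolved parts, and spectral expansion of the dissolved part.

#' Partition combined dissolved+detrital absorption at 410 nm
#'
#' Semi-analytical inversions retrieve only the sum \eqn{a_{dg}(410) =
#' a_d(410) + a_g(410)} because the two components share a near-identical
#' spectral shape.  The detrital part is estimated empirically from the
#' combined absorption and total backscattering,
#' \deqn{a_d(410) = 0.06822\,a_{dg}(410) + 1.623\,b_{bt}(550) + 0.0002123,}
#' and the dissolved part follows by subtraction.  A negative remainder is
#' floored at zero and flagged (the intercept alone exceeds an
#' \eqn{a_{dg}} of zero).
#'
#' @param adg410 combined dissolved+detrital absorption at 410 nm, m^-1
#'   (>= 0).
#' @param bbt550 total backscattering at 550 nm, m^-1 (>= 0).
#' @return data.frame with columns `ad410`, `ag410` (m^-1), `floored`.
#'   Vectorized over inputs.
#' @export
#' @examples
#' partition_adg(0.1, 0.01)
partition_adg <- function(adg410, bbt550) {
  if (length(bbt550) == 1L) bbt550 <- rep(bbt550, length(adg410))
  if (length(adg410) == 1L) adg410 <- rep(adg410, length(bbt550))
  stopifnot(length(adg410) == length(bbt550))
  if (any(adg410 < 0, na.rm = TRUE) || any(bbt550 < 0, na.rm = TRUE))
    stop("invalid-argument: adg410 and bbt550 must be >= 0", call. = FALSE)
  ad <- 0.06822 * adg410 + 1.623 * bbt550 + 0.0002123
  ag <- adg410 - ad
  floored <- !is.na(ag) & ag < 0
  ag[floored] <- 0
  data.frame(ad410 = ad, ag410 = ag, floored = floored)
}

#' Expand partitioned CDOM absorption to other wavelengths
#'
#' Expands \eqn{a_g(410)} spectrally via the exponential model with
#' \eqn{\lambda_0 = 410} nm, using a spectral slope (typically the empirical
#' 412--555 nm retrieval).  The partition is defined at 410 nm; no 410-to-412
#' shift is applied to align with the 412 nm regression products.  Slopes
#' outside the 0.005--0.05 nm^-1 plausibility band are flagged with a
#' warning but still evaluated.
#'
#' @param ag410 dissolved absorption at 410 nm, m^-1 (>= 0).
#' @param sg spectral slope, nm^-1.
#' @param wavelengths target wavelengths, nm.
#' @return An [absorption_spectrum()] over `wavelengths`.
#' @export
#' @examples
#' expand_partitioned_ag(0.0767, 0.018, c(410, 443, 490))
expand_partitioned_ag <- function(ag410, sg, wavelengths) {
  stopifnot(length(ag410) == 1L, length(sg) == 1L)
  if (ag410 < 0) stop("invalid-argument: ag410 must be >= 0", call. = FALSE)
  if (!is.finite(sg)) stop("invalid-argument: sg must be finite", call. = FALSE)
  if (sg <= 0.005 || sg >= 0.05)
    warning("spectral slope ", sg,
            " nm^-1 outside the 0.005-0.05 plausibility band")
  eval_cdom_model(ag410, 410, sg, wavelengths)
}
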