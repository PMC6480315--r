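# Monthly climatology and ratio-anomaly operators, the normalized Chl-CDOM
# residual for testing departures from Case 1 covariance, and the
# anomaly-vs-climate-index correlation.

check_monthly <- function(series) {
  st <- as.data.frame(series)
  stopifnot(all(c("year", "month", "value") %in% names(st)))
  if (is.null(st$id)) st$id <- "all"
  if (any(st$month < 1 | st$month > 12))
    stop("month must be in 1..12", call. = FALSE)
  if (anyDuplicated(st[c("id", "year", "month")]))
    stop("duplicate (id, year, month) entries", call. = FALSE)
  st
}

#' Monthly climatology of a time series
#'
#' Mean value per calendar month over all years (missing-aware), per spatial
#' id when one is present; the mission-era per-month averages that anomalies
#' are taken against.
#'
#' @param series data.frame with columns `year`, `month` (1--12), `value`,
#'   optional `id`.
#' @return data.frame `id`, `month`, `clim` (NA for empty months).
#' @export
monthly_climatology <- function(series) {
  st <- check_monthly(series)
  out <- expand.grid(id = unique(st$id), month = 1:12,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(st$id, st$month)
  means <- tapply(st$value, key, mean, na.rm = TRUE)
  out$clim <- as.numeric(means[paste(out$id, out$month)])
  out$clim[is.nan(out$clim)] <- NA_real_
  out[order(out$id, out$month), ]
}

#' Monthly ratio anomaly
#'
#' Each value divided by its own calendar month's climatological mean, the
#' standard ratio anomaly.  A zero or missing climatology yields a missing
#' anomaly with a reason.  Invariant to rescaling the whole series.
#'
#' @inheritParams monthly_climatology
#' @return The input data.frame with columns `anomaly` and `reason` added.
#' @export
monthly_anomaly <- function(series) {
  st <- check_monthly(series)
  cl <- monthly_climatology(st)
  idx <- match(paste(st$id, st$month), paste(cl$id, cl$month))
  denom <- cl$clim[idx]
  st$anomaly <- ifelse(!is.na(denom) & denom != 0, st$value / denom, NA_real_)
  st$reason <- ifelse(is.na(denom), "no-climatology",
                      ifelse(denom == 0, "zero-climatology", ""))
  st
}

#' Normalized Chl-minus-CDOM residual field
#'
#' Per-pixel residual of median-normalized chlorophyll and CDOM absorption
#' composites,
#' \deqn{\overline{Chl} - \overline{CDOM} = Chl_i/\mathrm{median}(Chl) -
#'   a_{g,i}(\lambda)/\mathrm{median}(a_g(\lambda)),}
#' with each median taken over the valid pixels of the entire composite.
#' Zero where the two properties covary exactly; departures measure failure
#' of the Case 1 covariance assumption.  Missing wherever either input is
#' missing.
#'
#' @param chl,ag numeric matrices (or vectors) of identical shape; NA =
#'   missing.
#' @return Matrix (or vector) of residuals.
#' @export
chl_cdom_residual <- function(chl, ag) {
  stopifnot(length(chl) == length(ag))
  med_chl <- stats::median(chl[is.finite(chl)])
  med_ag <- stats::median(ag[is.finite(ag)])
  if (!is.finite(med_chl) || !is.finite(med_ag))
    stop("all-missing input composite", call. = FALSE)
  if (med_chl <= 0 || med_ag <= 0)
    stop("composite medians must be positive", call. = FALSE)
  res <- chl / med_chl - ag / med_ag
  res[!is.finite(chl) | !is.finite(ag)] <- NA_real_
  res
}

#' Mean of a gridded field over a lat/lon box
#'
#' Unweighted mean of valid pixels inside a caller-supplied box; optional
#' cos(latitude) area weighting.
#'
#' @param field list with `lat`, `lon` vectors and `values` matrix
#'   (lat x lon).
#' @param lat_range,lon_range length-2 numeric bounds (inclusive).
#' @param area_weight use cos(latitude) weights (default FALSE).
#' @return Scalar mean.
#' @export
box_mean <- function(field, lat_range, lon_range, area_weight = FALSE) {
  ii <- which(field$lat >= lat_range[1] & field$lat <= lat_range[2])
  jj <- which(field$lon >= lon_range[1] & field$lon <= lon_range[2])
  if (!length(ii) || !length(jj)) stop("empty box", call. = FALSE)
  v <- field$values[ii, jj, drop = FALSE]
  w <- matrix(if (area_weight) cos(field$lat[ii] * pi / 180) else 1,
              nrow = length(ii), ncol = length(jj))
  ok <- is.finite(v)
  if (!any(ok)) return(NA_real_)
  sum(v[ok] * w[ok]) / sum(w[ok])
}

#' Correlate a monthly anomaly with a climate index
#'
#' Pearson correlation of month-aligned anomaly and index values (e.g. a
#' CDOM anomaly against the multivariate ENSO index), with a two-sided
#' p-value from [stats::cor.test()].  The p-value assumes independent
#' months; no autocorrelation correction is applied.
#'
#' @param anomaly_series data.frame `year`, `month`, `anomaly` (or `value`).
#' @param index_series data.frame `year`, `month`, `value`.
#' @return list `r`, `p`, `n`.
#' @export
index_correlation <- function(anomaly_series, index_series) {
  a <- as.data.frame(anomaly_series)
  if (is.null(a$anomaly)) a$anomaly <- a$value
  b <- as.data.frame(index_series)
  idx <- match(paste(a$year, a$month), paste(b$year, b$month))
  ok <- !is.na(idx) & is.finite(a$anomaly) & is.finite(b$value[idx])
  n <- sum(ok)
  if (n < 12L)
    stop("insufficient-data: fewer than 12 overlapping months", call. = FALSE)
  ct <- stats::cor.test(a$anomaly[ok], b$value[idx[ok]], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
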