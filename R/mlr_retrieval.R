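# Empirical MLR retrieval algorithms: ln-ln multiple linear regressions of
# CDOM absorption, CDOM spectral slope, and DOC against four reflectance
# bands (443/488/531/547 nm on MODIS, 443/490/510/555 nm on SeaWiFS), plus
# the DOC regression against ag(355) and salinity.

.registry_env <- new.env(parent = emptyenv())

# polynomial rolling hash over the canonicalized registry content
registry_checksum <- function(df) {
  num <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 15))
  s <- paste(df$sensor, df$product, df$transform,
             num(df$lambda1), num(df$lambda2), num(df$lambda3), num(df$lambda4),
             num(df$beta0), num(df$beta1), num(df$beta2),
             num(df$beta3), num(df$beta4), num(df$threshold),
             sep = "|", collapse = ";")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

#' Load the MLR coefficient registry
#'
#' Reads the delimited coefficient registry shipped with the package (or a
#' user-supplied file in the same layout): one row per published regression,
#' giving sensor, product, response transform, predictor bands, coefficients
#' beta0--beta4, and the 99th-percentile retrieval threshold where one was
#' published.  The shipped registry holds 31 rows: 6 absorption bands x 2
#' sensors, 8 slope windows x 2 sensors, 2 reflectance-only DOC rows, and the
#' absorption-plus-salinity DOC row.  The shipped copy is verified against an
#' embedded checksum; a tampered file raises a registry-corrupt error.
#'
#' @param path registry file; default is the shipped copy.
#' @param verify check row count and checksum (default TRUE for the shipped
#'   copy, applied to any path).
#' @return data.frame of registry rows.
#' @export
load_registry <- function(path = NULL, verify = is.null(path)) {
  shipped <- is.null(path)
  if (shipped)
    path <- system.file("extdata", "mlr_registry.csv", package = "oceancdom",
                        mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sensor", "product", "transform", "lambda1", "lambda2",
              "lambda3", "lambda4", "beta0", "beta1", "beta2", "beta3",
              "beta4", "threshold")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("registry-corrupt: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (verify) {
    if (nrow(df) != 31L)
      stop("registry-corrupt: expected 31 rows, found ", nrow(df),
           call. = FALSE)
    if (registry_checksum(df) != 1157480102)
      stop("registry-corrupt: checksum mismatch", call. = FALSE)
  }
  df
}

registry <- function() {
  if (is.null(.registry_env$df)) .registry_env$df <- load_registry()
  .registry_env$df
}

normalize_product <- function(product) {
  p <- tolower(gsub("[@ ]", "", product))
  if (grepl("^doc", p)) {
    p <- gsub("-", "_", p)
    if (!grepl("^doc_", p)) p <- sub("^doc", "doc_", p)
    return(p)
  }
  p <- gsub("_", "-", p)
  p <- sub("^ag-", "ag", p)
  p <- sub("^sg-", "sg", p)
  p
}

#' Look up published MLR coefficients
#'
#' @param sensor `"modis"` or `"seawifs"` (`"any"` rows, such as the
#'   absorption-plus-salinity DOC algorithm, match either sensor).
#' @param product e.g. `"ag412"`, `"sg275-295"`, `"doc_mlr1"`, `"doc_mlr2"`.
#' @return Object of class `mlr_coefficients`: list with `sensor`, `product`,
#'   `transform` (`"log_log"` or `"linear"`), `bands` (predictor wavelengths,
#'   NA for non-reflectance predictors), `beta` (named vector, intercept
#'   first), `threshold` (NA when none published), `note`.
#' @export
#' @examples
#' get_coefficients("modis", "ag412")
get_coefficients <- function(sensor, product) {
  sensor <- tolower(sensor)
  prod <- normalize_product(product)
  df <- registry()
  hit <- df[(df$sensor == sensor | df$sensor == "any") & df$product == prod, ]
  if (nrow(hit) == 0L)
    stop("not-found: no registry row for (", sensor, ", ", product, ")",
         call. = FALSE)
  row <- hit[1L, ]
  beta <- c(row$beta0, row$beta1, row$beta2, row$beta3, row$beta4)
  keep <- !is.na(beta)
  beta <- beta[keep]
  names(beta) <- paste0("beta", seq_along(beta) - 1L)
  preds <- if (prod == "doc_mlr2") c("ag355", "salinity")
           else paste0("rrs", c(row$lambda1, row$lambda2, row$lambda3,
                                row$lambda4)[keep[-1]])
  structure(list(sensor = row$sensor, product = prod,
                 transform = row$transform,
                 bands = as.numeric(c(row$lambda1, row$lambda2,
                                      row$lambda3, row$lambda4)),
                 predictors = preds, beta = beta,
                 threshold = row$threshold, note = row$note),
            class = "mlr_coefficients")
}

#' @export
print.mlr_coefficients <- function(x, ...) {
  cat(sprintf("MLR coefficients: %s %s (%s)\n", x$sensor, x$product,
              x$transform))
  print(x$beta)
  if (!is.na(x$threshold)) cat("threshold:", x$threshold, "\n")
  invisible(x)
}

#' Apply an MLR retrieval
#'
#' Evaluates the regression.  Under the `log_log` transform the retrieval is
#' \eqn{\exp(\beta_0 + \sum_i \beta_i \ln p_i)}; under `linear` it is
#' \eqn{\beta_0 + \sum_i \beta_i p_i}.  Retrievals above the published
#' threshold (the 99th percentile of global application, where one exists)
#' are outside the scope of the global algorithm: the value is set to missing
#' and `clipped` is flagged.  Non-positive predictors under `log_log` yield
#' an `undefined` flag, never an error, so gridded application continues.
#'
#' @param coefs an `mlr_coefficients` object (see [get_coefficients()]).
#' @param predictors numeric vector of predictor values in registry order, or
#'   a matrix/data.frame with one row per case.
#' @return data.frame with columns `value`, `clipped`, `undefined`, plus
#'   attributes `product` and `sensor`.
#' @export
#' @examples
#' cf <- get_coefficients("modis", "ag412")
#' apply_mlr(cf, c(0.008, 0.006, 0.003, 0.0025))
apply_mlr <- function(coefs, predictors) {
  stopifnot(inherits(coefs, "mlr_coefficients"))
  x <- if (is.null(dim(predictors))) matrix(as.numeric(predictors), nrow = 1L)
       else as.matrix(predictors)
  npred <- length(coefs$beta) - 1L
  if (ncol(x) != npred)
    stop("expected ", npred, " predictors, got ", ncol(x), call. = FALSE)
  b0 <- coefs$beta[1L]
  b <- coefs$beta[-1L]
  if (identical(coefs$transform, "log_log")) {
    undefined <- apply(x, 1L, function(r) any(!is.finite(r) | r <= 0))
    value <- rep(NA_real_, nrow(x))
    ok <- !undefined
    if (any(ok)) value[ok] <- exp(b0 + drop(log(x[ok, , drop = FALSE]) %*% b))
  } else {
    undefined <- apply(x, 1L, function(r) any(!is.finite(r)))
    value <- b0 + drop(x %*% b)
    value[undefined] <- NA_real_
  }
  clipped <- !is.na(coefs$threshold) & !undefined & !is.na(value) &
             value > coefs$threshold
  value[clipped] <- NA_real_
  structure(data.frame(value = value, clipped = clipped,
                       undefined = undefined),
            product = coefs$product, sensor = coefs$sensor)
}

sensor_bands <- function(sensor) {
  switch(tolower(sensor),
         modis = c(443, 488, 531, 547),
         seawifs = c(443, 490, 510, 555),
         stop("unknown sensor: ", sensor, call. = FALSE))
}

rrs_from_record <- function(record, bands) {
  if (is.data.frame(record)) record <- as.list(record[1L, ])
  nm <- paste0("rrs", bands)
  if (!all(nm %in% names(record))) {
    miss <- setdiff(nm, names(record))
    stop("missing reflectance bands: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  as.numeric(unlist(record[nm]))
}

#' Retrieve the CDOM absorption spectrum from reflectance
#'
#' Applies the per-band absorption regressions (275, 355, 380, 412, 443, and
#' 488 nm for MODIS / 490 nm for SeaWiFS) to one reflectance record.  Bands
#' are retrieved independently.
#'
#' @param sensor `"modis"` or `"seawifs"`.
#' @param record named list / one-row data.frame with columns `rrs443`,
#'   `rrs488`, ... for the sensor's bands (sr^-1).
#' @return data.frame with columns `band`, `value` (m^-1), `clipped`,
#'   `undefined`.
#' @export
retrieve_ag_spectrum <- function(sensor, record) {
  bands <- sensor_bands(sensor)
  rrs <- rrs_from_record(record, bands)
  out_bands <- c(275, 355, 380, 412, 443,
                 if (tolower(sensor) == "modis") 488 else 490)
  rows <- lapply(out_bands, function(b) {
    res <- apply_mlr(get_coefficients(sensor, paste0("ag", b)), rrs)
    cbind(band = b, res)
  })
  do.call(rbind, rows)
}

#' Retrieve CDOM spectral slope from reflectance
#'
#' @inheritParams retrieve_ag_spectrum
#' @param window slope window label, e.g. `"275-295"` (see [slope_windows()]).
#' @return data.frame `value` (nm^-1), `clipped`, `undefined`.
#' @export
retrieve_sg <- function(sensor, record, window) {
  rrs <- rrs_from_record(record, sensor_bands(sensor))
  if (is.numeric(window)) window <- window_label(window)
  apply_mlr(get_coefficients(sensor, paste0("sg", window)), rrs)
}

#' Retrieve DOC from CDOM absorption and salinity
#'
#' The linear regression DOC = 192.718 + 26.790 ag(355) - 3.558 S, with DOC
#' in umol L^-1, ag(355) in m^-1, salinity in psu.  Salinity outside 0--42
#' psu flags a warning but still evaluates.
#'
#' @param ag355 CDOM absorption at 355 nm, m^-1 (>= 0).
#' @param salinity practical salinity, psu.
#' @return data.frame `value` (umol L^-1), `clipped`, `undefined`,
#'   `salinity_out_of_range`.
#' @export
#' @examples
#' retrieve_doc_mlr2(0.1, 35)
retrieve_doc_mlr2 <- function(ag355, salinity) {
  if (any(ag355 < 0, na.rm = TRUE))
    stop("ag355 must be >= 0", call. = FALSE)
  out_of_range <- !is.na(salinity) & (salinity < 0 | salinity > 42)
  if (any(out_of_range))
    warning("salinity outside 0-42 psu for ", sum(out_of_range), " record(s)")
  res <- apply_mlr(get_coefficients("any", "doc_mlr2"),
                   cbind(ag355, salinity))
  res$salinity_out_of_range <- out_of_range
  res
}

#' Fit a multiple linear regression retrieval
#'
#' Ordinary least squares in the transformed space of the retrieval form:
#' under `log_log` both predictors and response are log-transformed before
#' the fit (all values must be positive), under `linear` neither is.
#' Rank-deficient designs raise a degenerate-design error naming the
#' collinear columns.
#'
#' @param predictors data.frame or matrix of predictor columns (named).
#' @param response numeric response vector.
#' @param transform `"log_log"` or `"linear"`.
#' @param sensor,product labels stored on the resulting coefficients.
#' @return Object of class `mlr_fit`: list with `coefficients` (an
#'   `mlr_coefficients`), `skill` (the Eq-style metric suite of fitted vs
#'   observed response on the natural scale; see [compute_skill()]), and the
#'   underlying `lm` fit.  Methods: `print`, `coef`, `predict`.
#' @export
fit_mlr <- function(predictors, response,
                    transform = c("log_log", "linear"),
                    sensor = "custom", product = "custom") {
  transform <- match.arg(transform)
  x <- as.matrix(predictors)
  if (is.null(colnames(x))) colnames(x) <- paste0("p", seq_len(ncol(x)))
  y <- as.numeric(response)
  if (nrow(x) < ncol(x) + 2L)
    stop("insufficient-data: need at least n_regressors + 2 rows",
         call. = FALSE)
  if (transform == "log_log") {
    if (any(x <= 0) || any(y <= 0))
      stop("log_log transform requires strictly positive data", call. = FALSE)
    xt <- log(x); yt <- log(y)
  } else {
    xt <- x; yt <- y
  }
  design <- cbind(`(Intercept)` = 1, xt)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    bad <- colnames(design)[qd$pivot[(qd$rank + 1L):ncol(design)]]
    stop("degenerate-design: collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  lmfit <- stats::lm.fit(design, yt)
  beta <- lmfit$coefficients
  names(beta) <- paste0("beta", seq_along(beta) - 1L)
  coefs <- structure(
    list(sensor = sensor, product = product, transform = transform,
         bands = rep(NA_real_, 4L), predictors = colnames(x),
         beta = beta, threshold = NA_real_, note = "fitted"),
    class = "mlr_coefficients")
  fitted_nat <- if (transform == "log_log") exp(lmfit$fitted.values)
                else lmfit$fitted.values
  structure(list(coefficients = coefs,
                 skill = compute_skill(fitted_nat, y,
                                       n_regressors = ncol(x)),
                 fitted = fitted_nat, response = y),
            class = "mlr_fit")
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat("Fitted MLR retrieval (", x$coefficients$transform, " form)\n", sep = "")
  print(x$coefficients$beta)
  cat(sprintf("fit skill: r2' = %.4f, RMSD = %.4g, MAPD = %.3g%%\n",
              x$skill$r2_adj, x$skill$rmsd, x$skill$mapd))
  invisible(x)
}

#' @export
coef.mlr_fit <- function(object, ...) object$coefficients$beta

#' @export
predict.mlr_fit <- function(object, newdata, ...) {
  apply_mlr(object$coefficients, newdata)$value
}
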