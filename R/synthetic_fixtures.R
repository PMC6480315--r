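# Seeded generators producing every input class the toolkit consumes, with
# planted ground truth, so all modules are exercisable offline.  One global
# seed fans out to per-generator substreams so adding a generator never
# perturbs another's draws.

#' Derive an independent substream seed from a global seed
#'
#' @param seed global integer seed.
#' @param stream generator name.
#' @return Integer seed below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  h <- 0
  for (b in utf8ToInt(as.character(stream)))
    h <- (h * 131 + b) %% 1048573
  as.integer((as.numeric(seed) * 1048576 + h) %% 2147483629)
}

#' Generate synthetic CDOM absorption spectra with planted truth
#'
#' Draws exponential CDOM spectra referenced at 412 nm: spectral slopes
#' uniform within the 0.005--0.05 nm^-1 plausibility band, amplitudes
#' lognormal about 0.12 m^-1 (a typical global-database mean at 412 nm,
#' sdlog 0.6), optional additive Gaussian noise, and optional planted QC
#' violations with labels:
#' \describe{
#'   \item{contamination}{a +0.007 m^-1 bump at 676 nm.}
#'   \item{slope_low / slope_high}{slope planted outside 0.005--0.05.}
#'   \item{red_band}{a +0.06 m^-1 offset beyond 680 nm (triggers the red
#'     bounds).}
#' }
#'
#' @param n number of spectra.
#' @param seed global seed (fanned out internally).
#' @param wavelengths sample grid, nm.
#' @param noise_sigma additive Gaussian noise SD, m^-1.
#' @param violations character vector recycled over spectra, entries from
#'   `"none"`, `"contamination"`, `"slope_low"`, `"slope_high"`,
#'   `"red_band"`; default all `"none"`.
#' @return list with `spectra` (list of [absorption_spectrum()]) and `truth`
#'   (data.frame `id`, `a412`, `s_g`, `violation`).
#' @export
gen_cdom_spectra <- function(n, seed, wavelengths = 245:715,
                             noise_sigma = 0, violations = "none") {
  set.seed(substream_seed(seed, "cdom"))
  violations <- rep_len(violations, n)
  s_g <- stats::runif(n, 0.005, 0.05)
  s_g[violations == "slope_low"] <- stats::runif(sum(violations == "slope_low"),
                                                 0.001, 0.004)
  s_g[violations == "slope_high"] <- stats::runif(sum(violations == "slope_high"),
                                                  0.055, 0.08)
  a412 <- stats::rlnorm(n, log(0.12), 0.6)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    a <- a412[i] * exp(-s_g[i] * (wavelengths - 412))
    if (noise_sigma > 0) a <- a + stats::rnorm(length(a), 0, noise_sigma)
    if (violations[i] == "contamination")
      a[abs(wavelengths - 676) <= 1] <- a[abs(wavelengths - 676) <= 1] + 0.007
    if (violations[i] == "red_band")
      a[wavelengths > 680] <- a[wavelengths > 680] + 0.06
    spectra[[i]] <- absorption_spectrum(wavelengths, a)
  }
  list(spectra = spectra,
       truth = data.frame(id = seq_len(n), a412 = a412, s_g = s_g,
                          violation = violations))
}

#' Generate a synthetic reflectance/retrieval regression dataset
#'
#' Draws ln-reflectances from a full-rank multivariate normal with band
#' means tuned to open-ocean magnitudes (~0.002--0.01 sr^-1) and moderate
#' inter-band correlation, then generates the response through the given
#' regression with optional ln-space Gaussian noise.  With
#' `degenerate = TRUE` one band is made an exact linear combination of
#' another (in ln space), planting a rank-deficient design.
#'
#' @param coefs an `mlr_coefficients` object with a `log_log` transform.
#' @param n rows.
#' @param seed global seed.
#' @param noise_sigma ln-space noise SD.
#' @param degenerate plant exact collinearity (default FALSE).
#' @return data.frame of predictor columns (named after `coefs$predictors`)
#'   and `response`; attribute `truth` holds the planted beta vector.
#' @export
gen_rrs_dataset <- function(coefs, n, seed, noise_sigma = 0,
                            degenerate = FALSE) {
  stopifnot(inherits(coefs, "mlr_coefficients"),
            identical(coefs$transform, "log_log"))
  set.seed(substream_seed(seed, "rrs"))
  npred <- length(coefs$beta) - 1L
  # ln-space spread ~0.6 (global Rrs spans about an order of magnitude per
  # band) with moderate inter-band correlation
  mu <- log(seq(0.008, 0.002, length.out = npred))
  sd_ln <- 0.6
  rho <- 0.4
  sigma <- sd_ln^2 * (rho + (1 - rho) * diag(npred))
  z <- matrix(stats::rnorm(n * npred), n, npred) %*% chol(sigma)
  ln_rrs <- sweep(z, 2L, mu, `+`)
  if (degenerate && npred >= 2L) ln_rrs[, 2L] <- 2 * ln_rrs[, 1L]
  ln_y <- coefs$beta[1L] + drop(ln_rrs %*% coefs$beta[-1L])
  if (noise_sigma > 0) ln_y <- ln_y + stats::rnorm(n, 0, noise_sigma)
  out <- as.data.frame(exp(ln_rrs))
  names(out) <- coefs$predictors
  out$response <- exp(ln_y)
  attr(out, "truth") <- coefs$beta
  out
}

#' Generate paired station tables with planted match-up outcomes
#'
#' Builds a primary (CDOM-like) station table and a secondary (DOC-like)
#' table containing, for each primary station, either a planted in-window
#' partner (inside the shelf-dependent time/depth/distance window) or a
#' planted out-of-window partner, plus planted too-deep samples that the
#' surface rules must discard.  Half the stations sit on the shelf (bottom
#' depth <= 1000 m), half off it.  Secondary DOC values are generated as
#' DOC = 192.718 + 26.790 ag355 - 3.558 S plus noise so retrieval
#' validation closes the loop.
#'
#' @param seed global seed.
#' @param n_pairs planted matchable pairs.
#' @param n_nonmatch planted out-of-window partners.
#' @param n_deep planted too-deep primary samples.
#' @param doc_noise_sd noise on generated DOC, umol L^-1.
#' @return list with `primary`, `secondary` data.frames and `truth`
#'   (data.frame `id`, `shelf`, `expect_match`, `expect_deep_discard`).
#' @export
gen_station_tables <- function(seed, n_pairs = 20, n_nonmatch = 10,
                               n_deep = 6, doc_noise_sd = 2) {
  set.seed(substream_seed(seed, "stations"))
  n <- n_pairs + n_nonmatch + n_deep
  t0 <- as.POSIXct("2010-06-01 00:00:00", tz = "UTC")
  shelf <- rep(c(TRUE, FALSE), length.out = n)
  bottom <- ifelse(shelf, stats::runif(n, 50, 900),
                   stats::runif(n, 1500, 5000))
  kind <- rep(c("match", "nonmatch", "deep"), c(n_pairs, n_nonmatch, n_deep))
  depth <- ifelse(kind == "deep",
                  ifelse(shelf, stats::runif(n, 6, 30),
                         stats::runif(n, 11, 40)),
                  stats::runif(n, 0, 2))
  primary <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    time = t0 + (seq_len(n) * 86400) + stats::runif(n, 0, 3600),
    lat = stats::runif(n, -60, 60),
    lon = stats::runif(n, -179, 179),
    depth = depth, bottom_depth = bottom,
    ag355 = stats::rlnorm(n, log(0.25), 0.5),
    salinity = stats::runif(n, 30, 37))
  # partners: perturb within / beyond the applicable window
  within <- kind == "match"
  sec_idx <- which(kind != "deep")
  dt_h <- ifelse(shelf, 1, 3); dz <- ifelse(shelf, 2.5, 5)
  dkm <- ifelse(shelf, 1, 5)
  mk_partner <- function(i, inside) {
    f <- if (inside) stats::runif(1, 0.1, 0.8) else stats::runif(1, 1.5, 3)
    dlat <- (dkm[i] * f) / 111.32
    data.frame(
      id = sprintf("S%03d", i),
      time = primary$time[i] + 3600 * dt_h[i] * f,
      lat = primary$lat[i] + dlat,
      lon = primary$lon[i],
      depth = min(primary$depth[i] + dz[i] * f * 0.5, 4.9),
      bottom_depth = primary$bottom_depth[i],
      doc = 192.718 + 26.790 * primary$ag355[i] -
            3.558 * primary$salinity[i] + stats::rnorm(1, 0, doc_noise_sd))
  }
  secondary <- do.call(rbind, lapply(sec_idx, function(i)
    mk_partner(i, within[i])))
  list(primary = primary, secondary = secondary,
       truth = data.frame(id = primary$id, shelf = shelf,
                          expect_match = within,
                          expect_deep_discard = kind == "deep"))
}

#' Generate satellite pixel arrays spanning the match-up gate matrix
#'
#' Engineers one pixel-array case per combination of the four match-up gates
#' (time within 8 h; >50% of non-land pixels valid; at least 5 valid pixels;
#' CV < 0.25), each labelled with the gates it is built to fail, so
#' label/verdict agreement can be checked exhaustively.
#'
#' @param seed global seed.
#' @param station_time POSIXct field sampling time the arrays refer to.
#' @return list of cases; each case is a list with `label` (character vector
#'   of gates planted to fail, empty = pass), `arrays` (list of one
#'   [pixel_array()]), and `station_time`.
#' @export
gen_pixel_arrays <- function(seed,
                             station_time = as.POSIXct("2010-06-01 12:00:00",
                                                       tz = "UTC")) {
  set.seed(substream_seed(seed, "pixels"))
  combos <- expand.grid(time = c(FALSE, TRUE), fraction = c(FALSE, TRUE),
                        count = c(FALSE, TRUE), cv = c(FALSE, TRUE))
  cases <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    fail <- combos[k, ]
    base <- 0.005
    vals <- matrix(base * (1 + stats::rnorm(25, 0, 0.02)), 5, 5)
    land <- matrix(FALSE, 5, 5)
    flags <- matrix(FALSE, 5, 5)
    if (fail$cv) {
      # alternating two-level field: CV ~ 0.33 and no pixel beyond 1.5 SD
      vals <- matrix(base * rep(c(1, 2), length.out = 25), 5, 5)
    }
    if (fail$count) {
      # only 4 non-land pixels, all valid: fraction passes, count fails
      land[] <- TRUE
      land[1, 1:4] <- FALSE
    } else if (fail$fraction) {
      # 25 non-land, 12 valid (48%): fraction fails (count would pass)
      flags[] <- TRUE
      flags[1:12] <- FALSE
    }
    dt_h <- if (fail$time) 9 else 2
    overpass <- station_time + dt_h * 3600
    label <- names(fail)[unlist(fail)]
    cases[[k]] <- list(
      label = label,
      arrays = list(pixel_array(443, vals, land, flags, overpass)),
      station_time = station_time)
  }
  cases
}
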