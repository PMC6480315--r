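# Database-assembly rules for global bio-optical algorithm databases:
# record-level CDOM QC, population outlier filters, IOP/reflectance bounds,
# surface binning, in-situ record matching, and satellite pixel-array
# match-up.

qc_verdict <- function(kept, reasons = character(0)) {
  if (!kept && length(reasons) == 0L)
    stop("internal: rejection without a reason", call. = FALSE)
  structure(list(kept = kept, reasons = reasons), class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(if (x$kept) "kept" else "rejected", "\n")
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Test a CDOM spectrum for particle contamination
#'
#' In-situ (flow-through) CDOM measurements are prone to particle and bubble
#' contamination, which shows up as a phytoplankton absorption peak at
#' 676 nm.  A record is rejected when absorption at 676 nm rises by at least
#' 0.006 m^-1 (inclusive) above the 650--715 nm absorption baseline.  The
#' baseline at 676 nm is linearly interpolated between the mean of samples
#' in 650--665 nm and the mean of samples in 705--715 nm.
#'
#' @param spectrum an [absorption_spectrum()] covering 650--715 nm including
#'   676 nm (2.5 nm matching tolerance).  Missing coverage makes the test
#'   not evaluable: the record is kept with the reason recorded.
#' @return A `qc_verdict` with a `bump` attribute (the excess at 676 nm)
#'   when evaluable.
#' @export
check_particle_contamination <- function(spectrum) {
  stopifnot(inherits(spectrum, "absorption_spectrum"))
  lam <- spectrum$wavelength; a <- spectrum$absorption
  lo <- lam >= 650 & lam <= 665
  hi <- lam >= 705 & lam <= 715
  m676 <- band_match(lam, a, 676, tolerance = 2.5)
  if (!any(lo) || !any(hi) || !m676$matched)
    return(qc_verdict(TRUE, "contamination-not-evaluable"))
  x1 <- mean(lam[lo]); y1 <- mean(a[lo])
  x2 <- mean(lam[hi]); y2 <- mean(a[hi])
  baseline <- y1 + (y2 - y1) * (676 - x1) / (x2 - x1)
  bump <- m676$value - baseline
  v <- if (bump >= 0.006) qc_verdict(FALSE, "particle-contamination")
       else qc_verdict(TRUE)
  attr(v, "bump") <- bump
  v
}

#' Record-level CDOM quality control
#'
#' Rejects a CDOM record when any of the following trigger; all triggered
#' reasons are enumerated:
#' \itemize{
#'   \item any fitted spectral slope outside 0.005--0.05 nm^-1
#'     (`slope-range`);
#'   \item \eqn{a_g(676) > 0.1} m^-1 (`red-676`);
#'   \item \eqn{a_g(715) > 0.05} m^-1 (`red-715`);
#'   \item mean \eqn{a_g(\lambda > 680\,nm) > 0.05} m^-1 (`red-mean-680`).
#' }
#'
#' @param spectrum an [absorption_spectrum()], or NULL for slope-only QC.
#' @param slopes a single `slope_fit`, a list of them (e.g.
#'   [fit_all_slopes()] output), or a numeric vector of slopes in nm^-1; may
#'   be NULL.
#' @return A `qc_verdict`.
#' @export
qc_cdom_record <- function(spectrum = NULL, slopes = NULL) {
  reasons <- character(0)
  svals <- numeric(0)
  if (inherits(slopes, "slope_fit")) svals <- slopes$s_g
  else if (is.list(slopes))
    svals <- vapply(slopes, function(f) f$s_g, numeric(1))
  else if (is.numeric(slopes)) svals <- slopes
  if (length(svals) && any(svals < 0.005 | svals > 0.05, na.rm = TRUE))
    reasons <- c(reasons, "slope-range")
  if (!is.null(spectrum)) {
    lam <- spectrum$wavelength; a <- spectrum$absorption
    m676 <- band_match(lam, a, 676, tolerance = 2.5)
    if (m676$matched && m676$value > 0.1) reasons <- c(reasons, "red-676")
    m715 <- band_match(lam, a, 715, tolerance = 2.5)
    if (m715$matched && m715$value > 0.05) reasons <- c(reasons, "red-715")
    red <- lam > 680
    if (any(red) && mean(a[red]) > 0.05) reasons <- c(reasons, "red-mean-680")
  }
  if (length(svals) == 0L && is.null(spectrum))
    stop("need at least one slope or a spectrum", call. = FALSE)
  qc_verdict(length(reasons) == 0L, reasons)
}

#' Population-level outlier filter
#'
#' Whole-database outlier screens.  Modes:
#' \describe{
#'   \item{slope}{reject values more than 2 sample standard deviations from
#'     the median, or outside the 2nd--98th percentiles.}
#'   \item{red_extreme}{reject extreme outliers more than 4 standard
#'     deviations from the median (red-wavelength screen).}
#'   \item{doc}{reject values outside the 1st--99th percentiles.}
#'   \item{upper95}{reject values above the 95th percentile (the upper-tail
#'     reflectance screen).}
#' }
#' With fewer than 10 finite records the filter passes everything through
#' with a warning.  Statistics use all finite values; NA values are kept
#' (not judged).  The filter is applied in a single pass.
#'
#' @param values numeric vector.
#' @param mode one of `"slope"`, `"red_extreme"`, `"doc"`, `"upper95"`.
#' @return Logical keep-mask the length of `values`.
#' @export
population_outlier_filter <- function(values,
                                      mode = c("slope", "red_extreme",
                                               "doc", "upper95")) {
  mode <- match.arg(mode)
  ok <- is.finite(values)
  if (sum(ok) < 10L) {
    warning("fewer than 10 records; population filter passed through")
    return(rep(TRUE, length(values)))
  }
  v <- values[ok]
  med <- stats::median(v)
  s <- stats::sd(v)
  keep <- rep(TRUE, length(values))
  keep[ok] <- switch(mode,
    slope = {
      q <- stats::quantile(v, c(0.02, 0.98), names = FALSE)
      abs(v - med) <= 2 * s & v >= q[1] & v <= q[2]
    },
    red_extreme = abs(v - med) <= 4 * s,
    doc = {
      q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
      v >= q[1] & v <= q[2]
    },
    upper95 = v <= stats::quantile(v, 0.95, names = FALSE))
  keep
}

#' Bounds QC on IOPs and reflectances of one station record
#'
#' Applies the physical-plausibility bounds per constituent: detrital
#' absorption above 12 m^-1, particulate absorption above 20 m^-1, or total
#' backscattering above 0.15 m^-1 at *any* wavelength drops that constituent
#' at all wavelengths; remote-sensing reflectance above 0.075 sr^-1 or below
#' -0.001 sr^-1 in any band drops the reflectance record.
#'
#' @param record named list or one-row data.frame; constituent columns are
#'   recognized by prefix + integer-nm suffix: `ad###`, `ap###`, `bbt###`,
#'   `rrs###`.
#' @return data.frame with columns `constituent`, `present`, `kept`,
#'   `reason`.
#' @export
qc_iop_rrs_bounds <- function(record) {
  if (is.data.frame(record)) record <- as.list(record[1L, ])
  vals <- function(prefix) {
    nm <- grep(paste0("^", prefix, "[0-9]+$"), names(record), value = TRUE)
    as.numeric(unlist(record[nm]))
  }
  rule <- function(constituent, v, bad, reason) {
    present <- length(v) > 0 && any(is.finite(v))
    kept <- !present || !any(bad(v[is.finite(v)]))
    data.frame(constituent = constituent, present = present, kept = kept,
               reason = if (kept) "" else reason)
  }
  rbind(
    rule("ad",  vals("ad"),  function(v) v > 12,    "ad-exceeds-12"),
    rule("ap",  vals("ap"),  function(v) v > 20,    "ap-exceeds-20"),
    rule("bbt", vals("bbt"), function(v) v > 0.15,  "bbt-exceeds-0.15"),
    rule("rrs", vals("rrs"), function(v) v > 0.075 | v < -0.001,
         "rrs-out-of-bounds"))
}

#' Nearest-neighbor bottom-depth lookup
#'
#' Looks up the bottom depth at a station from a regular lat/lon bathymetry
#' grid by great-circle nearest neighbor; ties go to the northwest node
#' (larger latitude, then smaller longitude).
#'
#' @param lat,lon station coordinates, decimal degrees (east-positive
#'   longitude).
#' @param grid list with `lat` (vector), `lon` (vector), `depth` (matrix
#'   `length(lat)` x `length(lon)`, positive down in m).
#' @return Bottom depth in m.
#' @export
bottom_depth_lookup <- function(lat, lon, grid) {
  stopifnot(is.list(grid), all(c("lat", "lon", "depth") %in% names(grid)))
  dlat <- if (length(grid$lat) > 1) min(abs(diff(grid$lat))) else 1
  dlon <- if (length(grid$lon) > 1) min(abs(diff(grid$lon))) else 1
  if (lat < min(grid$lat) - dlat / 2 || lat > max(grid$lat) + dlat / 2 ||
      lon < min(grid$lon) - dlon / 2 || lon > max(grid$lon) + dlon / 2)
    stop("not-found: point outside bathymetry grid", call. = FALSE)
  nodes <- expand.grid(i = seq_along(grid$lat), j = seq_along(grid$lon))
  d <- geosphere::distHaversine(cbind(lon, lat),
                                cbind(grid$lon[nodes$j], grid$lat[nodes$i]))
  best <- d <= min(d) + 1e-6
  cand <- nodes[best, , drop = FALSE]
  # tie-break: northwest = max lat, then min lon
  cand <- cand[order(-grid$lat[cand$i], grid$lon[cand$j]), , drop = FALSE]
  grid$depth[cand$i[1], cand$j[1]]
}

# local equirectangular projection (km) about a reference point
project_km <- function(lat, lon, lat0, lon0) {
  kmdeg <- 111.32
  cbind(x = (lon - lon0) * kmdeg * cos(lat0 * pi / 180),
        y = (lat - lat0) * kmdeg)
}

#' Surface-average and spatially bin station records
#'
#' Keeps only surface samples: on the continental shelf (bottom depth <=
#' 1000 m) samples deeper than 5 m are discarded; off the shelf, deeper than
#' 10 m (both strict: a sample at exactly the cutoff is kept).  Surviving
#' samples of the same cast (`id`) are averaged into one surface record;
#' optionally, records are then binned to a 0.5 km grid (local
#' equirectangular projection about the centroid) per calendar day and
#' averaged, collapsing transects.
#'
#' @param stations data.frame with at least `id`, `lat`, `lon`, `depth`,
#'   and `bottom_depth` (may contain NA); any other numeric columns are
#'   averaged, `time` (POSIXct or numeric) is averaged within groups.
#' @param grid optional bathymetry grid (see [bottom_depth_lookup()]) used
#'   to fill missing `bottom_depth`.  Records with no resolvable bottom
#'   depth are passed through with `flag_no_bottom_depth = TRUE`.
#' @param bin_transects bin surviving records to a 0.5 km grid per day
#'   (default TRUE).
#' @param bin_km bin size in km.
#' @return data.frame of surface records; attribute `n_discarded_deep`
#'   counts depth-rule removals.
#' @export
surface_bin <- function(stations, grid = NULL, bin_transects = TRUE,
                        bin_km = 0.5) {
  st <- as.data.frame(stations)
  stopifnot(all(c("id", "lat", "lon", "depth") %in% names(st)))
  if (is.null(st$bottom_depth)) st$bottom_depth <- NA_real_
  fill <- which(is.na(st$bottom_depth))
  if (length(fill) && !is.null(grid))
    st$bottom_depth[fill] <- vapply(fill, function(i)
      tryCatch(bottom_depth_lookup(st$lat[i], st$lon[i], grid),
               error = function(e) NA_real_), numeric(1))
  st$flag_no_bottom_depth <- is.na(st$bottom_depth)
  # depth rule: strict; unresolvable bottom depth treated as off-shelf limit
  shelf <- !is.na(st$bottom_depth) & st$bottom_depth <= 1000
  cutoff <- ifelse(shelf, 5, 10)
  keep <- st$depth <= cutoff
  n_deep <- sum(!keep)
  st <- st[keep, , drop = FALSE]
  agg <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    out <- df[1L, , drop = FALSE]
    out[num] <- lapply(df[num], function(v) mean(v, na.rm = TRUE))
    if (inherits(df$time, "POSIXct")) out$time <- mean(df$time)
    out$n_averaged <- nrow(df)
    out
  }
  st <- do.call(rbind, lapply(split(st, st$id), agg))
  rownames(st) <- NULL
  if (bin_transects && nrow(st) > 1L) {
    xy <- project_km(st$lat, st$lon, mean(st$lat), mean(st$lon))
    day <- if (inherits(st$time, "POSIXct")) format(st$time, "%Y-%m-%d")
           else "all"
    cell <- paste(floor(xy[, "x"] / bin_km), floor(xy[, "y"] / bin_km), day)
    st <- do.call(rbind, lapply(split(st, cell), agg))
    rownames(st) <- NULL
  }
  attr(st, "n_discarded_deep") <- n_deep
  st
}

#' Match two station tables under shelf-dependent windows
#'
#' Pairs each record of `a` with records of `b` lying within the coincidence
#' window: within 1 h, 2.5 m depth, and 1 km in continental-shelf waters
#' (bottom depth <= 1000 m), and within 3 h, 5 m depth, and 5 km off the
#' shelf.  Multiple matches form an ensemble: members more than 1.5 sample
#' standard deviations from the ensemble mean are discarded (single pass),
#' and the ensemble is retained only if its coefficient of variation is
#' <= 0.25; the retained members are averaged.
#'
#' @param a,b surface-binned data.frames with `id`, `time` (POSIXct), `lat`,
#'   `lon`, `depth`, and (`a` at least) `bottom_depth`.
#' @param value_col name of the column of `b` whose ensemble is averaged.
#' @param shelf_criteria,offshelf_criteria named lists
#'   `list(hours=, depth_m=, km=)` overriding the default windows.
#' @return data.frame with one row per `a` record: `id`, `n_candidates`,
#'   `n_used`, `value` (ensemble mean; NA when unmatched or rejected), `cv`,
#'   `accepted`, `reason`.
#' @export
match_records <- function(a, b, value_col,
                          shelf_criteria = list(hours = 1, depth_m = 2.5,
                                                km = 1),
                          offshelf_criteria = list(hours = 3, depth_m = 5,
                                                   km = 5)) {
  stopifnot(value_col %in% names(b))
  out <- data.frame(id = a$id, n_candidates = 0L, n_used = 0L,
                    value = NA_real_, cv = NA_real_, accepted = FALSE,
                    reason = "no-match")
  for (i in seq_len(nrow(a))) {
    shelf <- !is.na(a$bottom_depth[i]) && a$bottom_depth[i] <= 1000
    cr <- if (shelf) shelf_criteria else offshelf_criteria
    dt <- abs(as.numeric(difftime(b$time, a$time[i], units = "hours")))
    dz <- abs(b$depth - a$depth[i])
    dd <- geosphere::distHaversine(cbind(a$lon[i], a$lat[i]),
                                   cbind(b$lon, b$lat)) / 1000
    cand <- which(dt <= cr$hours & dz <= cr$depth_m & dd <= cr$km)
    out$n_candidates[i] <- length(cand)
    if (!length(cand)) next
    v <- b[[value_col]][cand]
    v <- v[is.finite(v)]
    if (!length(v)) { out$reason[i] <- "no-finite-values"; next }
    if (length(v) > 1L) {
      mu <- mean(v); s <- stats::sd(v)
      if (s > 0) v <- v[abs(v - mu) <= 1.5 * s]
    }
    mu <- mean(v)
    cv <- if (length(v) > 1L && mu != 0) stats::sd(v) / abs(mu) else 0
    out$n_used[i] <- length(v)
    out$cv[i] <- cv
    if (cv <= 0.25) {
      out$value[i] <- mu
      out$accepted[i] <- TRUE
      out$reason[i] <- ""
    } else out$reason[i] <- "ensemble-cv"
  }
  out
}

#' Construct a satellite pixel-extract array
#'
#' @param band band center, nm.
#' @param values 5x5 numeric matrix of reflectances (sr^-1), NA allowed.
#' @param land_mask,flag_mask 5x5 logical matrices (TRUE = masked).
#' @param overpass_time POSIXct overpass time.
#' @return Object of class `pixel_array`.
#' @export
pixel_array <- function(band, values, land_mask = NULL, flag_mask = NULL,
                        overpass_time) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(5L, 5L)))
    stop("pixel array must be 5x5", call. = FALSE)
  if (is.null(land_mask)) land_mask <- matrix(FALSE, 5, 5)
  if (is.null(flag_mask)) flag_mask <- matrix(FALSE, 5, 5)
  stopifnot(is.logical(land_mask), is.logical(flag_mask),
            all(dim(land_mask) == c(5, 5)), all(dim(flag_mask) == c(5, 5)))
  structure(list(band = band, values = values, land_mask = land_mask,
                 flag_mask = flag_mask, overpass_time = overpass_time),
            class = "pixel_array")
}

#' Satellite pixel-array match-up
#'
#' Evaluates a set of per-band 5x5 pixel extracts against a field station,
#' applying in order: (1) the time gate, overpass within 8 h of sampling
#' (inclusive); (2) per-band nulling of negative pixels and outliers more
#' than 1.5 sample standard deviations from the array mean; (3) validity
#' gates, more than 50% of non-land pixels still valid (strict) and no fewer
#' than five valid pixels; (4) the band mean is retained only when the
#' coefficient of variation of the remaining pixels is below 0.25 (strict).
#'
#' @param arrays list of [pixel_array()] objects sharing one overpass time.
#' @param station_time POSIXct field sampling time.
#' @return Object of class `matchup_result`: list with `accepted` (any band
#'   retained), `time_delta_h`, `reasons`, and `bands`, a data.frame of
#'   `band`, `n_valid`, `n_nonland`, `mean_rrs`, `cv`, `retained`, `reason`.
#' @export
matchup_satellite <- function(arrays, station_time) {
  if (inherits(arrays, "pixel_array")) arrays <- list(arrays)
  stopifnot(length(arrays) >= 1L)
  times <- unique(vapply(arrays, function(a) as.numeric(a$overpass_time),
                         numeric(1)))
  if (length(times) != 1L)
    stop("arrays must share one overpass time", call. = FALSE)
  dt <- abs(times - as.numeric(station_time)) / 3600
  bands <- data.frame(band = vapply(arrays, `[[`, numeric(1), "band"),
                      n_valid = NA_integer_, n_nonland = NA_integer_,
                      mean_rrs = NA_real_, cv = NA_real_,
                      retained = FALSE, reason = "")
  if (dt > 8) {
    bands$reason <- "time"
    return(structure(list(accepted = FALSE, time_delta_h = dt,
                          reasons = "time", bands = bands),
                     class = "matchup_result"))
  }
  for (k in seq_along(arrays)) {
    a <- arrays[[k]]
    nonland <- !a$land_mask
    valid <- nonland & !a$flag_mask & is.finite(a$values)
    v <- a$values[valid]
    if (length(v) > 1L) {
      mu <- mean(v); s <- stats::sd(v)
      drop <- v < 0 | (s > 0 & abs(v - mu) > 1.5 * s)
      v <- v[!drop]
    } else v <- v[v >= 0]
    n_nonland <- sum(nonland)
    bands$n_nonland[k] <- n_nonland
    bands$n_valid[k] <- length(v)
    if (length(v) <= 0.5 * n_nonland) {
      bands$reason[k] <- "valid-fraction"
      next
    }
    if (length(v) < 5L) {
      bands$reason[k] <- "valid-count"
      next
    }
    mu <- mean(v)
    cv <- if (mu != 0) stats::sd(v) / abs(mu) else Inf
    bands$cv[k] <- cv
    if (cv < 0.25) {
      bands$mean_rrs[k] <- mu
      bands$retained[k] <- TRUE
    } else bands$reason[k] <- "cv"
  }
  reasons <- unique(bands$reason[bands$reason != ""])
  structure(list(accepted = any(bands$retained), time_delta_h = dt,
                 reasons = reasons, bands = bands),
            class = "matchup_result")
}

#' @export
print.matchup_result <- function(x, ...) {
  cat(sprintf("satellite match-up: %s (dt = %.2f h)\n",
              if (x$accepted) "accepted" else "rejected", x$time_delta_h))
  print(x$bands)
  invisible(x)
}
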