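red_spectrum <- function(base = 0.01, bump676 = 0) {
  lam <- 650:715
  a <- rep(base, length(lam))
  a[lam == 676] <- a[lam == 676] + bump676
  absorption_spectrum(lam, a)
}

test_that("particle contamination triggers at a 0.006 bump, inclusive", {
  expect_false(check_particle_contamination(red_spectrum(bump676 = 0.007))$kept)
  expect_true(check_particle_contamination(red_spectrum())$kept)
  # exactly at the threshold: rejected (inclusive rule)
  v <- check_particle_contamination(red_spectrum(bump676 = 0.006))
  expect_false(v$kept)
  expect_identical(v$reasons, "particle-contamination")
  expect_equal(attr(v, "bump"), 0.006, tolerance = 1e-12)
  # a sloping baseline is interpolated, not assumed flat
  lam <- 650:715
  a <- 0.04 - 0.0004 * (lam - 650)  # declining red tail
  a[lam == 676] <- a[lam == 676] + 0.004  # small bump under threshold
  expect_true(check_particle_contamination(absorption_spectrum(lam, a))$kept)
  # missing red coverage: kept, not evaluable
  v <- check_particle_contamination(eval_cdom_model(0.1, 412, 0.02, 400:600))
  expect_true(v$kept)
  expect_identical(v$reasons, "contamination-not-evaluable")
})

test_that("record-level CDOM rules reject with enumerated reasons", {
  expect_identical(qc_cdom_record(slopes = 0.004)$reasons, "slope-range")
  expect_identical(qc_cdom_record(slopes = 0.06)$reasons, "slope-range")
  expect_true(qc_cdom_record(slopes = c(0.018, 0.03))$kept)
  lam <- 650:715
  hot676 <- absorption_spectrum(lam, ifelse(lam == 676, 0.11, 0.01))
  expect_identical(qc_cdom_record(hot676)$reasons, "red-676")
  hot715 <- absorption_spectrum(lam, ifelse(lam == 715, 0.06, 0.01))
  expect_identical(qc_cdom_record(hot715)$reasons, "red-715")
  hotred <- absorption_spectrum(lam, ifelse(lam > 680, 0.06, 0.01))
  expect_true("red-mean-680" %in% qc_cdom_record(hotred)$reasons)
  # all triggered reasons enumerate together
  v <- qc_cdom_record(absorption_spectrum(lam, rep(0.2, length(lam))),
                      slopes = 0.001)
  expect_setequal(v$reasons,
                  c("slope-range", "red-676", "red-715", "red-mean-680"))
  clean <- qc_cdom_record(eval_cdom_model(0.05, 650, 0.01, 650:715),
                          slopes = 0.018)
  expect_true(clean$kept)
})

test_that("population filters reject planted outliers only", {
  set.seed(81)
  v <- rnorm(1000, 10, 1)
  v[1] <- 10 + 5 * sd(v)  # far outlier
  keep_slope <- population_outlier_filter(v, "slope")
  keep_red <- population_outlier_filter(v, "red_extreme")
  expect_false(keep_slope[1])
  expect_false(keep_red[1])
  # red_extreme (4 SD) is strictly more permissive than the 2 SD screen
  expect_true(all(keep_slope[!keep_red] == FALSE))
  # identical values: zero spread, all kept
  expect_true(all(population_outlier_filter(rep(3, 50), "slope")))
  # doc mode clips the 1st/99th percentile tails
  keep_doc <- population_outlier_filter(v, "doc")
  q <- quantile(v, c(0.01, 0.99))
  expect_identical(unname(keep_doc), unname(v >= q[1] & v <= q[2]))
  # upper95 screens the upper tail only
  keep95 <- population_outlier_filter(v, "upper95")
  expect_identical(unname(keep95), unname(v <= quantile(v, 0.95)))
  expect_true(all(keep95[v < median(v)]))
  expect_warning(population_outlier_filter(1:5, "slope"), "fewer than 10")
})

test_that("IOP and reflectance bounds drop the whole constituent", {
  rec <- list(id = "s1", ad412 = 13, ad443 = 0.5, ap412 = 1, bbt550 = 0.01,
              rrs443 = 0.005, rrs555 = 0.004)
  v <- qc_iop_rrs_bounds(rec)
  expect_false(v$kept[v$constituent == "ad"])
  expect_identical(v$reason[v$constituent == "ad"], "ad-exceeds-12")
  expect_true(v$kept[v$constituent == "ap"])
  expect_true(v$kept[v$constituent == "rrs"])
  rec$rrs555 <- -0.002
  v <- qc_iop_rrs_bounds(rec)
  expect_false(v$kept[v$constituent == "rrs"])
  rec2 <- list(ap443 = 21, bbt550 = 0.2, rrs443 = 0.08)
  v <- qc_iop_rrs_bounds(rec2)
  expect_identical(v$kept[v$present], rep(FALSE, 3))
  clean <- list(ad412 = 1, ap412 = 2, bbt550 = 0.1, rrs443 = 0.01)
  expect_true(all(qc_iop_rrs_bounds(clean)$kept))
})

test_that("bottom-depth lookup matches a brute-force nearest-neighbor scan", {
  grid <- list(lat = seq(30, 32, by = 0.05), lon = seq(-70, -68, by = 0.05))
  set.seed(82)
  grid$depth <- matrix(runif(length(grid$lat) * length(grid$lon), 10, 5000),
                       nrow = length(grid$lat))
  # exactly on a node
  expect_identical(bottom_depth_lookup(30.5, -69.5, grid),
                   grid$depth[which(grid$lat == 30.5),
                              which(grid$lon == -69.5)])
  # random points vs brute force
  nodes <- expand.grid(i = seq_along(grid$lat), j = seq_along(grid$lon))
  for (k in 1:20) {
    lat <- runif(1, 30, 32); lon <- runif(1, -70, -68)
    d <- geosphere::distHaversine(cbind(lon, lat),
                                  cbind(grid$lon[nodes$j], grid$lat[nodes$i]))
    expect_identical(bottom_depth_lookup(lat, lon, grid),
                     grid$depth[nodes$i[which.min(d)],
                                nodes$j[which.min(d)]])
  }
  # midway tie resolves to the northwest node
  g2 <- list(lat = c(30, 31), lon = c(-70, -69),
             depth = matrix(c(1, 2, 3, 4), 2, 2))
  expect_identical(bottom_depth_lookup(30.5, -70, g2), g2$depth[2, 1])
  expect_error(bottom_depth_lookup(50, -69.5, grid), "not-found")
})

test_that("surface rules keep shallow samples by the shelf-dependent cutoffs", {
  st <- rbind(
    station_row("a", "2010-06-01 10:00:00", 30, -70, 6, 800),    # shelf, deep
    station_row("b", "2010-06-01 10:00:00", 30, -70, 5, 800),    # shelf, at limit
    station_row("c", "2010-06-02 10:00:00", 31, -60, 8, 2000),   # off-shelf, kept
    station_row("d", "2010-06-03 10:00:00", 32, -50, 11, 2000))  # off-shelf, deep
  out <- surface_bin(st, bin_transects = FALSE)
  expect_setequal(out$id, c("b", "c"))
  expect_identical(attr(out, "n_discarded_deep"), 2L)
})

test_that("profiles average within the surface layer and transects bin to 0.5 km", {
  prof <- rbind(
    station_row("cast1", "2010-06-01 10:00:00", 30, -70, 2, 800, ag412 = 0.10),
    station_row("cast1", "2010-06-01 10:10:00", 30, -70, 4, 800, ag412 = 0.14))
  out <- surface_bin(prof, bin_transects = FALSE)
  expect_identical(nrow(out), 1L)
  expect_equal(out$ag412, 0.12)
  expect_identical(out$n_averaged, 2L)
  # two transect samples ~100 m apart fall in one 0.5 km cell
  tra <- rbind(
    station_row("t1", "2010-06-01 10:00:00", 30.0000, -70, 1, 800, ag412 = 0.1),
    station_row("t2", "2010-06-01 10:05:00", 30.0008, -70, 1, 800, ag412 = 0.2),
    station_row("t3", "2010-06-01 10:10:00", 30.2000, -70, 1, 800, ag412 = 0.4))
  out <- surface_bin(tra, bin_transects = TRUE)
  expect_identical(nrow(out), 2L)
  expect_true(any(abs(out$ag412 - 0.15) < 1e-12))
})

test_that("record matching honors the shelf-dependent windows", {
  a <- station_row("a1", "2010-06-01 12:00:00", 30, -70, 1, 800)
  # in-window shelf partner: 50 min, 2 m, 0.8 km
  b_in <- station_row("b1", "2010-06-01 12:50:00", 30 + 0.8 / 111.32, -70,
                      3, 800, doc = 100)
  expect_true(match_records(a, b_in, "doc")$accepted)
  # 2 h exceeds the 1 h shelf limit
  b_late <- b_in; b_late$time <- utc("2010-06-01 14:00:00")
  expect_false(match_records(a, b_late, "doc")$accepted)
  # same deltas off-shelf fall inside the wider window
  a_off <- a; a_off$bottom_depth <- 2000
  expect_true(match_records(a_off, b_late, "doc")$accepted)
  # 2 km exceeds the 1 km shelf radius
  b_far <- b_in; b_far$lat <- 30 + 2 / 111.32
  expect_false(match_records(a, b_far, "doc")$accepted)
  # 3 m depth delta exceeds 2.5 m on the shelf
  b_deep <- b_in; b_deep$depth <- 4.1
  expect_false(match_records(a, b_deep, "doc")$accepted)
})

test_that("match ensembles are screened at 1.5 SD and CV 0.25", {
  a <- station_row("a1", "2010-06-01 12:00:00", 30, -70, 1, 800)
  mk_b <- function(vals) {
    do.call(rbind, lapply(seq_along(vals), function(i)
      station_row(paste0("b", i), "2010-06-01 12:10:00", 30, -70, 1, 800,
                  doc = vals[i])))
  }
  m <- match_records(a, mk_b(c(100, 101, 99)), "doc")
  expect_true(m$accepted)
  expect_equal(m$value, 100)
  expect_equal(m$cv, sd(c(100, 101, 99)) / 100, tolerance = 1e-12)
  # wildly dispersed ensemble fails the CV gate
  m2 <- match_records(a, mk_b(c(10, 100, 300)), "doc")
  expect_false(m2$accepted)
  expect_identical(m2$reason, "ensemble-cv")
  # a >1.5 SD member is discarded before averaging
  m3 <- match_records(a, mk_b(c(100, 101, 99, 100, 160)), "doc")
  expect_identical(m3$n_used, 4L)
  expect_equal(m3$value, 100)
})

test_that("satellite match-up applies its gates in order", {
  t0 <- utc("2010-06-01 12:00:00")
  uniform <- matrix(0.005, 5, 5)
  # uniform positive array inside the time gate: accepted, CV 0
  r <- matchup_satellite(pixel_array(443, uniform,
                                     overpass_time = t0 + 2 * 3600), t0)
  expect_true(r$accepted)
  expect_equal(r$bands$mean_rrs, 0.005)
  expect_equal(r$bands$cv, 0)
  # 8 h exactly passes (inclusive); 9 h fails
  expect_true(matchup_satellite(pixel_array(443, uniform,
                                            overpass_time = t0 + 8 * 3600),
                                t0)$accepted)
  r9 <- matchup_satellite(pixel_array(443, uniform,
                                      overpass_time = t0 + 9 * 3600), t0)
  expect_false(r9$accepted)
  expect_identical(r9$reasons, "time")
  # 12 valid of 25 non-land is 48%: fails the >50% rule
  flags <- matrix(TRUE, 5, 5); flags[1:12] <- FALSE
  rf <- matchup_satellite(pixel_array(443, uniform, flag_mask = flags,
                                      overpass_time = t0 + 3600), t0)
  expect_false(rf$accepted)
  expect_identical(rf$reasons, "valid-fraction")
  # 4 valid pixels of 4 non-land: fraction passes, count fails
  land <- matrix(TRUE, 5, 5); land[1, 1:4] <- FALSE
  rc <- matchup_satellite(pixel_array(443, uniform, land_mask = land,
                                      overpass_time = t0 + 3600), t0)
  expect_false(rc$accepted)
  expect_identical(rc$reasons, "valid-count")
  # negative pixels are nulled before the gates
  vneg <- uniform; vneg[1:10] <- -0.001
  rn <- matchup_satellite(pixel_array(443, vneg,
                                      overpass_time = t0 + 3600), t0)
  expect_identical(rn$bands$n_valid, 15L)
  expect_true(rn$accepted)
  # high-CV array rejected for CV
  vcv <- matrix(0.005 * rep(c(1, 2), length.out = 25), 5, 5)
  rv <- matchup_satellite(pixel_array(443, vcv,
                                      overpass_time = t0 + 3600), t0)
  expect_false(rv$accepted)
  expect_identical(rv$reasons, "cv")
})

test_that("accepted match-ups re-satisfy every gate predicate", {
  cases <- gen_pixel_arrays(seed = 5)
  for (cs in cases) {
    r <- matchup_satellite(cs$arrays, cs$station_time)
    if (r$accepted) {
      expect_lte(r$time_delta_h, 8)
      b <- r$bands[r$bands$retained, ]
      expect_true(all(b$n_valid >= 5))
      expect_true(all(b$n_valid > 0.5 * b$n_nonland))
      expect_true(all(b$cv < 0.25))
    }
  }
})

test_that("QC is order-stable under record permutation", {
  set.seed(83)
  v <- rnorm(200, 5, 1); v[c(3, 50)] <- c(20, -10)
  keep <- population_outlier_filter(v, "slope")
  perm <- sample(200)
  expect_identical(population_outlier_filter(v[perm], "slope"), keep[perm])
})
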