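# shared fixtures built in code

# straight-line MLR evaluation, independent of apply_mlr's vectorized path
mlr_oracle <- function(beta, x, transform) {
  acc <- beta[[1]]
  for (i in seq_along(x))
    acc <- acc + beta[[i + 1]] * (if (transform == "log_log") log(x[[i]])
                                  else x[[i]])
  if (transform == "log_log") exp(acc) else acc
}

utc <- function(s) as.POSIXct(s, tz = "UTC")

# minimal station data.frame for match-up tests
station_row <- function(id, time, lat, lon, depth, bottom_depth, ...) {
  data.frame(id = id, time = utc(time), lat = lat, lon = lon, depth = depth,
             bottom_depth = bottom_depth, ...)
}

# golden copy of the published coefficient tables, transcribed independently
# of the shipped registry file
golden_registry <- function() {
  txt <- "
sensor product beta0 beta1 beta2 beta3 beta4 threshold
modis ag275 0.089 -0.540 -1.142 3.444 -1.875 4.825
modis ag355 -2.246 -1.186 -0.558 2.912 -1.336 0.9104
modis ag380 -2.263 -0.300 -1.882 3.831 -1.787 0.4341
modis ag412 -2.535 -0.563 -1.294 1.606 0.170 0.36419
modis ag443 -3.287 -0.727 -0.922 1.278 0.261 0.1984
modis ag488 -3.722 -0.377 -1.429 1.424 0.300 0.1114
seawifs ag275 -2.477 -2.880 2.225 0.480 -0.252 4.825
seawifs ag355 -4.199 -2.563 1.214 0.955 -0.040 0.9104
seawifs ag380 -4.544 -1.808 0.175 1.181 0.001 0.4341
seawifs ag412 -6.004 -0.861 -0.006 -0.346 0.515 0.36419
seawifs ag443 -6.410 -0.743 -0.145 -0.367 0.547 0.1984
seawifs ag490 -7.014 -0.736 0.142 -0.796 0.678 0.1114
modis sg275-295 -3.289 0.270 -0.335 1.051 -0.921 NA
modis sg290-600 -3.471 0.127 -0.251 1.025 -0.843 NA
modis sg300-600 -3.607 0.044 -0.153 0.881 -0.722 NA
modis sg350-400 -3.924 -0.242 0.055 0.935 -0.710 NA
modis sg350-600 -3.908 -0.204 0.098 0.609 -0.463 NA
modis sg380-600 -3.912 -0.152 0.127 0.236 -0.173 NA
modis sg412-600 -4.219 -0.180 0.137 0.168 -0.131 NA
modis sg412-555 4.195 -0.162 0.147 0.096 -0.084 NA
seawifs sg275-295 -3.012 0.427 -0.459 0.357 -0.228 NA
seawifs sg290-600 -3.425 0.131 -0.085 0.145 -0.130 NA
seawifs sg300-600 -3.615 0.004 0.014 0.160 -0.129 NA
seawifs sg350-400 -3.968 -0.298 0.178 0.301 -0.150 NA
seawifs sg350-600 -4.058 -0.288 0.091 0.356 -0.138 NA
seawifs sg380-600 -4.072 -0.226 0.088 0.208 -0.051 NA
seawifs sg412-600 -4.498 -0.466 0.690 -0.202 -0.015 NA
seawifs sg412-555 -4.533 -0.455 0.683 -0.214 -0.012 NA
modis doc_mlr1 4.923 0.641 -2.424 3.503 1.692 NA
seawifs doc_mlr1 5.272 0.526 -2.982 2.623 0.089 NA
any doc_mlr2 192.718 26.790 -3.558 NA NA NA"
  read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}
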