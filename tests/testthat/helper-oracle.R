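# Independent solar oracle: Spencer (1971) Fourier series for declination
# and equation of time.  A different derivation from the package's
# almanac-series implementation, so agreement is a genuine cross-check.

spencer_solar <- function(date) {
  doy <- as.POSIXlt(as.Date(date))$yday + 1
  g <- 2 * pi * (doy - 1) / 365
  decl <- (0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
             0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
             0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)) * 180 / pi
  eot <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  data.frame(declination = decl, equation_of_time = eot)
}

# oracle twilight times built on the Spencer series (same spherical
# trigonometry, independent solar terms)
spencer_twilight <- function(lat, lon, date, elev = 0) {
  sp <- spencer_solar(date)
  phi <- lat * pi / 180
  delta <- sp$declination * pi / 180
  cosH <- (sin(elev * pi / 180) - sin(phi) * sin(delta)) /
    (cos(phi) * cos(delta))
  if (abs(cosH) > 1) return(c(NA, NA))
  H <- acos(cosH) * 180 / pi
  noon <- 12 - sp$equation_of_time / 60 - lon / 15
  c(sunrise = noon - H / 15, sunset = noon + H / 15)
}

# twilight series for a fixed site over a date span
site_twilights <- function(lat, lon, from, n, elev = -3.5) {
  twilight_times(lat, lon, seq(as.Date(from), by = "day", length.out = n),
                 elev)
}
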