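# Shared fixture builders. Everything is generated in code; nothing binary.

ktd_site <- function() site(55.45, 10.66, 2)

# small, fully explicit click series: n consecutive minutes from a start
tiny_series <- function(counts, start = "2016-06-06 12:00:00") {
  t0 <- parse_utc(start)
  click_series(t0 + (seq_along(counts) - 1) * 60, counts)
}

# solar oracle table frozen before the build (independent NOAA-spreadsheet
# implementation); minutes on the local clock at Kerteminde, UTC+2
solar_oracle <- function() {
  read.csv(system.file("extdata", "solar_reference_kerteminde_2016.csv",
                       package = "dielPAM"))
}

# complete-enumeration two-tailed randomisation p for small pooled samples
enumeration_p <- function(a, b) {
  pooled <- c(a, b)
  obs <- abs(median(a) - median(b))
  idx <- utils::combn(length(pooled), length(a))
  stats <- apply(idx, 2, function(i) {
    abs(median(pooled[i]) - median(pooled[-i]))
  })
  mean(stats >= obs - 1e-12)
}
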