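# Shared fixtures and independent oracle implementations used across files.
# Expensive pipeline runs are computed once per session and cached.

fixture_env <- new.env()

easy_run <- function() {
  if (is.null(fixture_env$easy)) {
    fixture_env$easy <- run_pipeline(pipeline_config(preset = "easy",
                                                     seed = 11))
  }
  fixture_env$easy
}

# Independent Lorentzian evaluation (closed form), used to plant peaks
# without going through the package's generator.
lor <- function(x, center, amplitude, fwhm) {
  amplitude / (1 + ((x - center) / (fwhm / 2))^2)
}

# Single flat-valued spectrum on the default axis.
flat_spectrum <- function(value = 0, axis = default_axis()) {
  raman_spectrum(axis, rep(value, length(axis)))
}

# Brute-force Mann-Whitney AUC: concordant pairs get 1, ties 0.5.
auc_paircount <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Exhaustive per-band argmax scan, independent of extract_features().
scan_band_positions <- function(shift, intensity) {
  edges <- c(1000, 1030, 1152, 1174, 1195, 1280, 1350, 1410, 1450,
             1522, 1545, 1800, 2300)
  out <- numeric(12)
  for (b in 1:12) {
    if (b < 12) {
      idx <- which(shift >= edges[b] & shift < edges[b + 1])
    } else {
      idx <- which(shift >= edges[b] & shift <= edges[b + 1])
    }
    best <- idx[1]
    for (i in idx) if (intensity[i] > intensity[best]) best <- i
    out[b] <- shift[best]
  }
  out
}
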