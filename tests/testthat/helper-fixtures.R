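# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small labelled CEFAS dataset: 2-minute session, recorded, calibrated,
# featurised, labelled, cleaned.
small_cefas_dataset <- function() {
  cached("small_cefas", function() {
    plan <- cheetah_session_plan("small", seed = 42)
    ses <- compose_session(plan)
    dev <- cheetah_devices()$cefas
    rec <- apply_device(ses$trace, dev)
    corr <- estimate_correction(rec, calibration_reference(c(0, 10)))
    cal <- apply_correction(rec, corr)
    feats <- derive_features(cal)
    labs <- align_labels(cal, ses$intervals)
    suppressMessages(drop_unassignable(label_features(feats, labs, "CEFAS")))
  })
}

# A well-separated 4-class coarse dataset (balanced-ish activity levels).
coarse_dataset <- function() {
  cached("coarse_ds", function() {
    ds <- small_cefas_dataset()
    ds$behaviour <- collapse_labels(ds$behaviour, "coarse")
    ds
  })
}

# Feature frame with exactly one informative predictor (static_heave).
planted_dataset <- function(n = 600, seed = 7) {
  withr::with_seed(seed, {
    cls <- rep(c("a", "b"), length.out = n)
    m <- matrix(rnorm(n * 14), n, 14,
                dimnames = list(NULL, accelcat:::rf_predictors()))
    m[, "static_heave"] <- ifelse(cls == "a", 0, 6) + rnorm(n, 0, 0.3)
    out <- tibble::as_tibble(as.data.frame(m))
    out$behaviour <- cls
    out
  })
}

# Closed-form Pearson chi-squared for a 2x2 table (independent oracle).
chisq_2x2_oracle <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Brute-force centred rolling mean with shrinking edges; even windows
# extend one sample further forward.
rolling_oracle <- function(x, w) {
  n <- length(x)
  left <- floor((w - 1) / 2)
  right <- (w - 1) - left
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - left):min(n, i + right)])
  }, numeric(1))
}

# Dominant positive-frequency spectral peak of a demeaned signal.
dominant_freq <- function(x, rate, min_freq = 0.3) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))[seq_len(floor(n / 2))]
  fr <- (seq_len(floor(n / 2)) - 1) * rate / n
  keep <- fr >= min_freq
  fr[keep][which.max(sp[keep])]
}
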