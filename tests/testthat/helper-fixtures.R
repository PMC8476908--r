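# Shared fixtures, memoised so several test files can reuse one simulation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_cohort <- function(n_patients = 2, size = 48, noise = 0.005, seed = 1) {
  key <- sprintf("cohort_%d_%d_%g_%d", n_patients, size, noise, seed)
  cached(key, generate_cohort(
    reduced_config(size = size, n_patients = n_patients,
                   noise_sigma_frac = noise, master_seed = seed)))
}

# The study-scale noise-free cohort used by the recovery checks: 40
# synthetic patients at the reduced 64-px panel (full physical field of
# view, pitch scaled accordingly).
study_cohort <- function() {
  cached("study_cohort_40_64",
         generate_cohort(reduced_config(size = 64, n_patients = 40,
                                        noise_sigma_frac = 0,
                                        master_seed = 1)))
}

study_features_ml3 <- function() {
  cached("study_features_ml3", build_feature_matrix(study_cohort(), "ml3"))
}

# A deterministic pseudo-random dose-like matrix in [0, 200].
dose_matrix <- function(h, w = h, seed = 1) {
  withr::with_seed(seed, matrix(runif(h * w, 0, 200), h, w))
}

# Hand-built feature tibble: `n_pat` patients x `per_pat` samples with
# feature columns supplied as a named list of vectors.
toy_features <- function(n_pat, per_pat, features, labels) {
  n <- n_pat * per_pat
  stopifnot(all(lengths(features) == n), all(lengths(labels) == n))
  tibble::tibble(
    patient_id = rep(sprintf("P%02d", seq_len(n_pat)), each = per_pat),
    serial = rep(seq_len(per_pat) + 1L, n_pat),
    !!!labels, !!!features)
}

# Minimal synthetic explicit-VR little-endian DICOM RT Image writer (test
# fixture only; mirrors the subset the package reader supports).
write_synthetic_dicom <- function(path, pixels, pitch_mm = 0.336,
                                  slope = 0.01, intercept = 0) {
  stopifnot(max(pixels) <= 65535, min(pixels) >= 0)
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  tag <- function(group, elem) { u16(group); u16(elem) }
  short_el <- function(group, elem, vr, payload_raw) {
    if (length(payload_raw) %% 2 == 1)
      payload_raw <- c(payload_raw, as.raw(if (vr %in% c("DS", "UI", "CS"))
        0x20 else 0x00))
    tag(group, elem); writeChar(vr, con, eos = NULL)
    u16(length(payload_raw)); writeBin(payload_raw, con)
  }
  str_el <- function(group, elem, vr, s)
    short_el(group, elem, vr, charToRaw(s))
  us_el <- function(group, elem, x) {
    tag(group, elem); writeChar("US", con, eos = NULL); u16(2); u16(x)
  }
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  str_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1") # explicit VR LE
  str_el(0x0008, 0x0060, "CS", "RTIMAGE")
  us_el(0x0028, 0x0010, nrow(pixels))
  us_el(0x0028, 0x0011, ncol(pixels))
  str_el(0x0028, 0x0030, "DS", sprintf("%g\\%g", pitch_mm, pitch_mm))
  us_el(0x0028, 0x0100, 16L)
  str_el(0x0028, 0x1052, "DS", sprintf("%g", intercept))
  str_el(0x0028, 0x1053, "DS", sprintf("%g", slope))
  str_el(0x3002, 0x0011, "DS", sprintf("%g\\%g", pitch_mm, pitch_mm))
  # pixel data, OW with 4-byte length, row-major order
  tag(0x7fe0, 0x0010); writeChar("OW", con, eos = NULL); u16(0)
  u32(2 * length(pixels))
  writeBin(as.integer(t(pixels)), con, size = 2, endian = "little")
  invisible(path)
}
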