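# Internal helpers shared across modules.

# Mean Earth radius used for all metric conversions (m).
EARTH_RADIUS <- 6371000

# Seconds in one climatological month (365.25 d / 12).
MONTH_SECONDS <- 365.25 * 86400 / 12

# degrees of latitude per metre of northward displacement
.deg_per_m_lat <- function(earth_radius = EARTH_RADIUS) {
  180 / (pi * earth_radius)
}

# degrees of longitude per metre of eastward displacement at latitude `lat`
.deg_per_m_lon <- function(lat, earth_radius = EARTH_RADIUS) {
  180 / (pi * earth_radius * cos(lat * pi / 180))
}

.stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "capdrift_error_validation")
}

.stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "capdrift_error_format")
}

.stop_io <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "capdrift_error_io")
}

.check_increasing <- function(x, name) {
  if (length(x) < 2) {
    .stop_validation("axis '%s' needs at least 2 points, got %d", name, length(x))
  }
  if (anyNA(x)) .stop_validation("axis '%s' contains NA", name)
  if (any(diff(x) <= 0)) {
    .stop_validation("axis '%s' must be strictly increasing", name)
  }
  invisible(x)
}

# full-precision number formatting so text round-trips are bit exact
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Status codes shared by the sampler and the tracker.
STATUS_OK <- 0L
STATUS_OUT_OF_DOMAIN <- 1L
STATUS_GROUNDED <- 2L

.status_label <- function(code) {
  c("ok", "out_of_domain", "grounded")[code + 1L]
}

# particle lifecycle states
PSTATE_ACTIVE <- 0L
PSTATE_REMOVED <- 1L
PSTATE_GROUNDED <- 2L

.pstate_label <- function(code) {
  c("active", "removed_boundary", "grounded")[code + 1L]
}
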