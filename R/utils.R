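# Internal helpers shared across modules: calendar indexing, circular
# smoothing on the annual cycle, saturation vapour pressure, seed streams.

# Map dates onto a 365-bin calendar-day index. In leap years Feb 29 shares
# the bin of Feb 28 so that every year occupies the same 365 positions.
doy365 <- function(dates) {
  d <- as.POSIXlt(dates)
  yday <- d$yday + 1L # 1-based
  leap <- (d$year + 1900L) %% 4L == 0L &
    ((d$year + 1900L) %% 100L != 0L | (d$year + 1900L) %% 400L == 0L)
  adj <- ifelse(leap & yday >= 60L, yday - 1L, yday)
  pmin(adj, 365L)
}

# Gaussian-weighted circular moving average on a length-365 vector.
# `window` is the full window length in days (odd), `sigma` in days.
circular_smooth <- function(x, window = 15L, sigma = 5) {
  stopifnot(length(x) == 365L, window %% 2L == 1L)
  half <- (window - 1L) %/% 2L
  w <- stats::dnorm(-half:half, 0, sigma)
  w <- w / sum(w)
  idx <- outer(seq_len(365L), -half:half, function(i, k) ((i + k - 1L) %% 365L) + 1L)
  as.numeric(matrix(x[idx], nrow = 365L) %*% w)
}

# Saturation vapour pressure over water (hPa), Magnus form.
saturation_vp <- function(temp_c) {
  6.112 * exp(17.62 * temp_c / (243.12 + temp_c))
}

# Vapour pressure (hPa) from air temperature and relative humidity (%).
vapour_pressure <- function(temp_c, rh) {
  rh / 100 * saturation_vp(temp_c)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive an independent 32-bit sub-seed for a named generator stream from
# the master seed, so adding one generator call never shifts another stream.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(met = 1L, scenario = 1L, mortality = 2L, pipeline = 3L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  s <- (as.double(seed) %% 2147483647) * 48271 + offsets[[stream]] * 16807
  as.integer(s %% 2147483647)
}

# Evaluate a function under a temporary RNG state seeded from a stream.
with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
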