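# Internal helpers shared across modules.

# Clamp a numeric vector into [lo, hi].
.clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Round half away from zero (base round() rounds half to even).
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# Deterministic replicate-seed splitting: documented scheme so batches are
# reproducible across platforms. Keeps seeds in 32-bit integer range.
.replicateSeed <- function(baseSeed, k) {
  as.integer((as.numeric(baseSeed) + 99991 * as.numeric(k)) %% 2147483647)
}

# Growable event buffer (amortised doubling; data.frame assembly at the end).
.newEventBuffer <- function(capacity = 256L) {
  buf <- new.env(parent = emptyenv())
  buf$n <- 0L
  buf$iteration <- integer(capacity)
  buf$cellId <- integer(capacity)
  buf$event <- character(capacity)
  buf$fromType <- character(capacity)
  buf$toType <- character(capacity)
  buf$x <- integer(capacity)
  buf$y <- integer(capacity)
  buf$z <- integer(capacity)
  buf
}

.pushEvent <- function(buf, iteration, cellId, event, fromType, toType, x, y, z) {
  n <- buf$n + 1L
  if (n > length(buf$iteration)) {
    grow <- function(v) c(v, vector(mode = mode(v), length = length(v)))
    for (f in c("iteration", "cellId", "event", "fromType", "toType", "x", "y", "z"))
      assign(f, grow(get(f, envir = buf)), envir = buf)
  }
  buf$iteration[n] <- iteration
  buf$cellId[n] <- cellId
  buf$event[n] <- event
  buf$fromType[n] <- fromType
  buf$toType[n] <- toType
  buf$x[n] <- x
  buf$y[n] <- y
  buf$z[n] <- z
  buf$n <- n
  invisible(buf)
}

.eventsAsDataFrame <- function(buf) {
  idx <- seq_len(buf$n)
  data.frame(
    iteration = buf$iteration[idx], cell_id = buf$cellId[idx],
    event = buf$event[idx], from_type = buf$fromType[idx],
    to_type = buf$toType[idx], x = buf$x[idx], y = buf$y[idx], z = buf$z[idx],
    stringsAsFactors = FALSE
  )
}
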