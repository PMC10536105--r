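# Independent brute-force oracles kept deliberately naive (explicit loops,
# no shared code with the package internals).

# Classify every pixel of a frame by explicit per-pixel distance checks.
# Returns a character matrix "A1"/"A2"/"A3"/"bg".
bf_classify_pixels <- function(center, R1, R2, R3, shape) {
  out <- matrix("bg", shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      dd <- sqrt((r - 0.5 - center[1])^2 + (c - 0.5 - center[2])^2)
      out[r, c] <-
        if (dd < R1) "A1" else if (dd < R2) "A2" else if (dd < R3) "A3"
        else "bg"
    }
  }
  out
}

# Bounding box (half-open, 0-based) of pixels >= thr, by explicit scan.
bf_bright_bbox <- function(px, thr) {
  r0 <- Inf; r1 <- -Inf; c0 <- Inf; c1 <- -Inf
  for (r in seq_len(nrow(px))) for (c in seq_len(ncol(px)))
    if (px[r, c] >= thr) {
      r0 <- min(r0, r - 1); r1 <- max(r1, r)
      c0 <- min(c0, c - 1); c1 <- max(c1, c)
    }
  if (!is.finite(r0)) return(NULL)
  c(r0, c0, r1, c1)
}

# Closed-form simple linear regression of E on x = ln d.
bf_loglinear <- function(d, E) {
  x <- log(d)
  a <- sum((x - mean(x)) * (E - mean(E))) / sum((x - mean(x))^2)
  b <- mean(E) - a * mean(x)
  c(a = a, b = b)
}

# A small centered disk frame on zero background.
disk_frame <- function(shape = c(200L, 200L), center = c(100, 100),
                       radius = 20, level = 200, bit_depth = 8L, ...) {
  m <- matrix(0, shape[1], shape[2])
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2]))
    if (sqrt((r - 0.5 - center[1])^2 + (c - 0.5 - center[2])^2) < radius)
      m[r, c] <- level
  photometric_frame(m, bit_depth = bit_depth, thickness_mm = 1,
                    power_mW = 1, ...)
}

table1_model <- function(gain = 1) forward_model(gain = gain)

# The acceptance-style noiseless study grids.
recovery_grids <- function() {
  list(transmitted = seq(0.8, 10, by = 0.2),
       reflected = seq(0.1, 10, by = 0.1))
}
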