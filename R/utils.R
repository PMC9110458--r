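# Internal helpers shared across the package.

# Fixed palette for module labels; "grey" is reserved for unassigned genes.
.module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue"
)

# One root seed, deterministic sub-streams per operation so each stage is
# independently reproducible.  Offsets are arbitrary fixed constants; the
# result stays below 2^31 - 1.
.sub_seed <- function(seed, stream) {
  offsets <- c(
    tensor = 11L, counts = 101L, traits = 211L, restart = 307L,
    pipeline = 401L
  )
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    .stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

.check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && x <= hi
  if (!ok) .stopf("'%s' must be a fraction in %s%g, %g]", name,
                  if (lo_open) "(" else "[", lo, hi)
  as.numeric(x)
}

# Geometric mean of strictly positive values.
.geomean <- function(x) exp(mean(log(x)))

# Column-wise orthonormalisation via QR (sign-stabilised so that the
# diagonal of R is positive -> deterministic for a given input matrix).
.orthonormalise <- function(m) {
  qr_m <- qr(m)
  q <- qr.Q(qr_m)
  r_diag <- diag(qr.R(qr_m))
  sweep(q, 2L, sign(r_diag + (r_diag == 0)), `*`)
}
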