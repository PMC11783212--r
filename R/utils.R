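# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; stays below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483647) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unit vector.
unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

# Any vector orthogonal to v (deterministic).
ortho <- function(v) {
  v <- unit(v)
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit(pracma_cross(v, ref))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix about axis (unit vector) by angle (radians), row-vector convention:
# rotated <- x %*% rot_about(axis, theta)
rot_about <- function(axis, theta) {
  a <- unit(axis)
  c_ <- cos(theta); s <- sin(theta); C <- 1 - c_
  x <- a[1]; y <- a[2]; z <- a[3]
  m <- matrix(c(
    x * x * C + c_,     x * y * C - z * s, x * z * C + y * s,
    y * x * C + z * s,  y * y * C + c_,    y * z * C - x * s,
    z * x * C - y * s,  z * y * C + x * s, z * z * C + c_), 3, 3, byrow = TRUE)
  t(m)
}

# Write a TSV with '#'-prefixed metadata header lines.
write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}
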