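# Internal helpers shared across modules. All angles in degrees, all
# positions in millimetres, all frame indices 0-based half-open.

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Centered rolling mean with edge replication (series padded by repeating the
# first/last value), window must be odd.
roll_mean <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(x)
  h <- (window - 1) / 2
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[(h + 1):(h + length(x))]
}

# Centered rolling population standard deviation, same edge convention.
roll_sd <- function(x, window) {
  m1 <- roll_mean(x, window)
  m2 <- roll_mean(x^2, window)
  sqrt(pmax(m2 - m1^2, 0))
}

# Maximal runs of TRUE in a logical vector -> half-open 0-based intervals
# relative to the vector start.
runs_to_intervals <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

# Membership of 0-based frame indices in a set of half-open intervals.
frames_in_intervals <- function(frames, intervals) {
  inside <- rep(FALSE, length(frames))
  if (is.null(intervals) || nrow(intervals) == 0) return(inside)
  for (i in seq_len(nrow(intervals))) {
    inside <- inside | (frames >= intervals$start[i] & frames < intervals$end[i])
  }
  inside
}

# Evaluate an expression with a locally seeded RNG, restoring global state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

ct_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "climbtech_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
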