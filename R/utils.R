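# Shared geometry and random-stream helpers.
#
# Units ledger (fixed at ingestion, used everywhere):
#   lengths mm, CSA mm^2, muscle/tendon volume cm^3, anthropometry m and kg,
#   forces N, moments Nm, angles degrees unless a function says otherwise.

MM3_PER_CM3 <- 1000
MM2_PER_CM2 <- 100

#' Cross product of two 3-vectors
#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Euclidean norm
#' @noRd
vnorm <- function(v) sqrt(sum(v^2))

#' Normalize a vector to unit length
#' @noRd
unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps^0.5) {
    stop("cannot normalize a (near-)zero vector")
  }
  v / n
}

#' Rotation matrix about an arbitrary unit axis (Rodrigues)
#'
#' @param axis 3-vector, need not be unit length.
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 3x3 proper rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle_deg) {
  n <- unitize(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, n[3], -n[2],
                -n[3], 0, n[1],
                n[2], -n[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Axis-angle decomposition of a rotation matrix
#'
#' Returns the rotation angle in degrees and the unit axis (angle in
#' \[0, 180\]). For the identity the axis is arbitrary and reported as NA.
#' @noRd
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  cs <- max(-1, min(1, (tr - 1) / 2))
  th <- acos(cs)
  if (th < 1e-7) {
    return(list(angle_deg = th * 180 / pi,
                axis = c(NA_real_, NA_real_, NA_real_)))
  }
  if (pi - th < 1e-6) {
    # near 180 deg: axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs using the largest component
    i <- which.max(ax)
    sgn <- sign(B[i, ])
    sgn[sgn == 0] <- 1
    ax <- ax * sgn / sgn[i]
    return(list(angle_deg = th * 180 / pi, axis = unitize(ax)))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  list(angle_deg = th * 180 / pi, axis = unitize(ax))
}

#' Derive an independent child seed from a base seed
#'
#' Splitting rule: a fixed integer mix of the base seed with a stream label,
#' kept inside 32-bit signed range. Adding subjects or trials never perturbs
#' the streams of existing ones because each (seed, label) pair maps to its
#' own child seed.
#' @param seed base integer seed.
#' @param ... integer labels identifying the stream (e.g. subject index,
#'   trial index).
#' @keywords internal
child_seed <- function(seed, ...) {
  labs <- c(...)
  x <- as.double(seed) %% 2147483647
  for (l in labs) {
    x <- (x * 48271 + as.double(l) * 16807 + 12345) %% 2147483647
  }
  as.integer(x)
}

#' Evaluate an expression with a locally-set RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Truncated-normal sampling by rejection at +/- 4 SD
#'
#' Guards against non-physical anthropometry (negative heights/masses).
#' Errors if more than 1000 rejections occur, which indicates a
#' misconfigured distribution.
#' @noRd
rnorm_bounded <- function(n, mean, sd, lower = -Inf) {
  lo <- max(lower, mean - 4 * sd)
  hi <- mean + 4 * sd
  out <- numeric(n)
  rejections <- 0
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi && x > lower) {
        out[i] <- x
        break
      }
      rejections <- rejections + 1
      if (rejections > 1000) {
        stop("more than 1000 rejections sampling bounded normal; ",
             "check the configured mean/SD")
      }
    }
  }
  out
}

#' Linear resampling of a profile onto n points of normalized position
#' @noRd
resample_linear <- function(x, y, n = 101) {
  if (length(x) == 1) {
    return(list(x = seq(0, 100, length.out = n), y = rep(y, n)))
  }
  xi <- seq(min(x), max(x), length.out = n)
  list(x = seq(0, 100, length.out = n),
       y = stats::approx(x, y, xout = xi, ties = "ordered")$y)
}
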