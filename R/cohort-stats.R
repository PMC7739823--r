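#' Mann-Whitney rank-sum comparison of two samples
#'
#' U is computed from midranks of the pooled data
#' (`U_a = R_a - n_a(n_a+1)/2`). When the pooled size is at most
#' `exact_cutoff` and there are no ties, the two-sided p-value is exact:
#' the full permutation distribution of U is enumerated (count recursion
#' over rank assignments) and p = 2 x the smaller tail probability,
#' capped at 1. Otherwise a normal approximation with tie correction and
#' a 0.5 continuity correction is used, again doubling the smaller tail.
#'
#' @param a,b numeric samples, each with n >= 2.
#' @param exact_cutoff largest pooled sample size for which the exact
#'   enumeration is used (default 25, covering a 14 + 7 design).
#' @return object of class `group_comparison`: group means and SDs, `U`
#'   (for sample `a`), `p` (two-sided), `method` ("exact" or "normal").
#' @export
mann_whitney <- function(a, b, exact_cutoff = 25) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs n >= 2")
  }
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)               # midranks for ties
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && na + nb <= exact_cutoff) {
    dist <- u_count_distribution(na, nb)   # counts for U = 0..na*nb
    total <- sum(dist)
    u <- round(U)
    p_le <- sum(dist[seq_len(u + 1)]) / total
    p_ge <- sum(dist[(u + 1):length(dist)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    N <- na + nb
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sig2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sig2 <= 0) {
      p <- 1
    } else {
      sig <- sqrt(sig2)
      z_le <- (U - mu + 0.5) / sig
      z_ge <- (U - mu - 0.5) / sig
      p <- min(1, 2 * min(stats::pnorm(z_le), stats::pnorm(z_ge,
                                                           lower.tail = FALSE)))
    }
    method <- "normal"
  }
  structure(list(mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 U = U, p = p, method = method,
                 n_a = na, n_b = nb),
            class = "group_comparison")
}

# Number of rank assignments of sample a (size m) out of m + n giving each
# value of U = 0..m*n. Classic count recursion c(m, n, u) =
# c(m-1, n, u-n) + c(m, n-1, u), built bottom-up.
u_count_distribution <- function(m, n) {
  # prev[[j + 1]] holds counts over U for sample sizes (i, j); grow i.
  # i = 0: only U = 0 possible, one way, for any j.
  prev <- lapply(0:n, function(j) {
    v <- numeric(m * n + 1)
    v[1] <- 1
    v
  })
  for (i in seq_len(m)) {
    cur <- vector("list", n + 1)
    v0 <- numeric(m * n + 1)
    v0[1] <- 1
    cur[[1]] <- v0                       # j = 0: U must be 0
    for (j in seq_len(n)) {
      shifted <- c(numeric(j), prev[[j + 1]][seq_len(m * n + 1 - j)])
      cur[[j + 1]] <- shifted + cur[[j]]
    }
    prev <- cur
  }
  prev[[n + 1]]
}

#' Holm step-down familywise error correction
#'
#' Sorts the family's p-values ascending, multiplies the i-th smallest by
#' (m - i + 1), enforces monotone non-decreasing adjusted values, and
#' returns them in the input order. By default adjusted values are NOT
#' capped at 1 (so the full step-down products are visible); set
#' `cap = TRUE` for the conventional min(1, .) convention.
#'
#' @param p p-values in \[0, 1\].
#' @param cap logical; cap adjusted values at 1.
#' @return adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(p, cap = FALSE) {
  p <- as.numeric(p)
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  adj <- p[o] * (m - seq_len(m) + 1)
  adj <- cummax(adj)
  if (cap) adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Simple linear regression with slope inference
#'
#' Ordinary least squares from the closed-form normal equations:
#' slope = Sxy/Sxx, R^2 = 1 - SSE/SST, and a two-sided p-value for the
#' slope from t = slope / SE with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, n >= 3, x not constant.
#' @return object of class `regression_fit`: slope, intercept,
#'   r_squared, p (two-sided, for the slope), n.
#' @export
linear_regression <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need n >= 3 complete observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx < .Machine$double.eps * max(1, mean(x)^2) * n) {
    stop("x is constant; slope is not identifiable")
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  sse <- sum((y - intercept - slope * x)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  se <- sqrt(sse / (n - 2) / sxx)
  p <- if (se == 0) {
    .Machine$double.xmin
  } else {
    2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p = max(min(p, 1), .Machine$double.xmin), n = n),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit: y = %.4g x + %.4g, R^2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p, x$n))
  invisible(x)
}
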