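# Internal numerical helpers shared across modules.

DEG <- 180 / pi

#' Behaviour label set
#'
#' Canonical behaviour vocabulary of the classifier, in the fixed reporting
#' order used by confusion matrices (move last, as it is absent from
#' laboratory validation).
#'
#' @return Character vector of the seven behaviour labels.
#' @export
behaviour_levels <- function() {
  c("sedentary", "stand", "walk", "run", "stairs", "cycle", "move")
}

# labels annotators may use on top of the behaviours; epochs dominated by
# these are excluded from all metrics
.annotation_extras <- c("other", "invisible", "uncertain")
.excluded_label <- "excluded"

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half away from zero
#'
#' Display rounding used for metric tables: ties round away from zero
#' (0.945 -> 0.95, -0.945 -> -0.95), unlike base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# Evaluate `code` under a private RNG stream; global .Random.seed restored.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Causal IIR filter from rest (direct-form transposed realisation through
# stats::filter so the recursion runs in C). Exact equivalent of the
# textbook difference equation with zero initial conditions.
lfilter <- function(b, a, x) {
  nb <- length(b)
  if (a[1] != 1) {
    b <- b / a[1]
    a <- a / a[1]
  }
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[(nb - 1) + seq_along(x)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# Zero-phase forward-backward filtering with odd-reflection padding.
# The DC level is subtracted before each pass so a constant input is
# reproduced exactly (the filters used here all have unit DC gain).
filtfilt_zp <- function(b, a, x) {
  n <- length(x)
  if (n < 2) return(x)
  p <- min(n - 1, max(3 * (max(length(a), length(b)) - 1), 100))
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  xe <- c(pre, x, post)
  pass <- function(z) {
    z0 <- z[1]
    lfilter(b, a, z - z0) + z0
  }
  y <- rev(pass(rev(pass(xe))))
  y[p + seq_len(n)]
}

# Minimal rotation (Rodrigues) taking unit vector `from` onto unit vector
# `to`; antiparallel inputs rotate 180 degrees about a perpendicular axis.
rotation_between <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  t2 <- to / sqrt(sum(to^2))
  v <- c(
    f[2] * t2[3] - f[3] * t2[2],
    f[3] * t2[1] - f[1] * t2[3],
    f[1] * t2[2] - f[2] * t2[1]
  )
  cth <- sum(f * t2)
  sth <- sqrt(sum(v^2))
  if (sth < 1e-12) {
    if (cth > 0) return(diag(3))
    # 180 degrees: any axis perpendicular to f
    ax <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * f) * f
    ax <- ax / sqrt(sum(ax^2))
    K <- skew3(ax)
    return(diag(3) + 2 * K %*% K)
  }
  K <- skew3(v / sth)
  diag(3) + sth * K + (1 - cth) * (K %*% K)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

# Dominant periodic frequency of a short segment by zero-padded FFT with a
# Hann window; returns 0 when the band peak does not dominate the band's
# median spectral power by `peak_ratio`.
dominant_frequency <- function(x, fs, band = c(0.3, 4), peak_ratio = 3) {
  n <- length(x)
  if (n < 4) return(0)
  x <- x - mean(x)
  if (max(abs(x)) < 1e-10) return(0)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  nfft <- 2^ceiling(log2(8 * n))
  p <- Mod(stats::fft(c(x * w, rep(0, nfft - n))))^2
  f <- (seq_len(nfft) - 1) * fs / nfft
  sel <- f >= band[1] & f <= min(band[2], fs / 2)
  if (!any(sel)) return(0)
  ps <- p[sel]
  i <- which.max(ps)
  if (ps[i] < peak_ratio * stats::median(ps)) return(0)
  f[sel][i]
}
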