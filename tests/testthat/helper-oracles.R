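# Independent brute-force oracles, written as plain loops over the
# defining formulas; deliberately share no code with the package.

# interdaily stability on a complete hourly series (balanced design)
brute_is <- function(x, hour_of_day) {
  n <- length(x)
  xbar <- mean(x)
  hours <- sort(unique(hour_of_day))
  p <- length(hours)
  num <- 0
  for (h in hours) {
    xh <- mean(x[hour_of_day == h])
    num <- num + (xh - xbar)^2
  }
  (n * num) / (p * sum((x - xbar)^2))
}

# intradaily variability on a contiguous hourly series
brute_iv <- function(x) {
  n <- length(x)
  xbar <- mean(x)
  num <- 0
  for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
  (n * num) / ((n - 1) * sum((x - xbar)^2))
}

# Cliff's delta by full pair enumeration
brute_cliff <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) s <- s + 1
    if (xi < yj) s <- s - 1
  }
  s / (length(x) * length(y))
}

# disturbance bouts by a plain scan: maximal runs strictly above theta
# lasting at least min_bout epochs
brute_bouts <- function(v, theta, min_bout = 1) {
  lens <- integer(0)
  run <- 0
  for (i in seq_along(v)) {
    if (v[i] > theta) run <- run + 1
    else {
      if (run >= min_bout) lens <- c(lens, run)
      run <- 0
    }
  }
  if (run >= min_bout) lens <- c(lens, run)
  lens
}

# exhaustive smallest-n scan for the paired t test using only stats::
brute_required_n <- function(d, alpha = 0.05, power = 0.8) {
  for (n in 2:10000) {
    tc <- stats::qt(1 - alpha / 2, n - 1)
    pw <- stats::pt(tc, n - 1, ncp = sqrt(n) * d, lower.tail = FALSE) +
      stats::pt(-tc, n - 1, ncp = sqrt(n) * d)
    if (pw >= power) return(n)
  }
  NA_integer_
}
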