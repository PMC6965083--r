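# internal helpers shared across modules

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so that seeded stages never perturb each other through the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# derive a distinct child seed from a parent seed; stays below 2^31
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + as.double(k) * 9973) %% 2147483629
}

#' Median with a percentile-bootstrap confidence interval
#'
#' @param x Numeric vector (NAs dropped).
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed RNG seed for the resampling.
#' @return List with `median`, `ci` (length-2), `n`.
#' @export
median_ci <- function(x, n_boot = 10000, conf = 0.95, seed = 1) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) {
    return(list(median = NA_real_, ci = c(NA_real_, NA_real_), n = 0L))
  }
  med <- stats::median(x)
  if (n == 1L) {
    return(list(median = med, ci = c(med, med), n = 1L))
  }
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    apply(idx, 2, function(i) stats::median(x[i]))
  })
  alpha <- (1 - conf) / 2
  list(
    median = med,
    ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
    n = n
  )
}

#' Mean with a percentile-bootstrap confidence interval
#'
#' @inheritParams median_ci
#' @return List with `mean`, `ci`, `n`.
#' @export
mean_ci <- function(x, n_boot = 10000, conf = 0.95, seed = 1) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) {
    return(list(mean = NA_real_, ci = c(NA_real_, NA_real_), n = 0L))
  }
  m <- mean(x)
  if (n == 1L) {
    return(list(mean = m, ci = c(m, m), n = 1L))
  }
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    colMeans(matrix(x[idx], nrow = n))
  })
  alpha <- (1 - conf) / 2
  list(mean = m, ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))), n = n)
}
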