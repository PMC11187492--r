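# Internal helpers shared across modules.

.datatable.aware <- TRUE

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package functions do
#' not perturb the session stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derived from a base seed and a stream label.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

# Truncated normal draws via inverse-CDF (exact, vectorized).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# Moments of N(mu, sigma) truncated to [a, b] (closed form).
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Underlying (mu, sigma) such that the [a, b]-truncated normal has the target
# mean and sd.
truncnorm_match <- function(target_mean, target_sd, a, b) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), a, b)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  p <- stats::optim(c(target_mean, log(target_sd)), obj,
                    method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 2000))$par
  c(mu = p[1], sigma = exp(p[2]))
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Row-wise L2 normalisation of a matrix; zero rows stay zero.
l2_normalise <- function(m) {
  nrm <- sqrt(rowSums(m * m))
  nrm[nrm == 0] <- 1
  m / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
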