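# Diploid noise estimation: univariate Gaussian mixture fit by EM with
# BIC model selection. The component with mean nearest 0 is taken as the
# diploid (noise) component and defines the noise band.

#' Fit the diploid-noise Gaussian mixture model
#'
#' Fits univariate Gaussian mixtures with `K = 1..max_components` by EM
#' (k-means++-style initial means, multiple restarts, monotone
#' log-likelihood) to per-probe log2 ratios pooled within one sample, and
#' selects `K` by BIC. The diploid component is the one with mean nearest
#' zero; the noise band is `mean +/- z_(1-alpha/2) * sd` of that component.
#'
#' @param x A log2-ratio track tibble (single sample; pass `sample` to pick
#'   one from a cohort track) or a numeric vector of log2 ratios.
#' @param max_components Largest mixture size tried.
#' @param alpha Band tail probability (default 0.05, a 95% band).
#' @param seed Integer seed for EM restarts.
#' @param sample Sample id to select when `x` is a multi-sample track.
#' @param n_restarts EM restarts per `K`.
#' @return An object of class `mm_noise_model`: `components` tibble
#'   (`weight`, `mean`, `sd`), `diploid_index`, `band_low`, `band_high`,
#'   `alpha`, `bic` per K, and the winning restart's `loglik_trace`.
#' @export
fit_noise_model <- function(x, max_components = 3, alpha = 0.05, seed = 1L,
                            sample = NULL, n_restarts = 3L) {
  if (is.data.frame(x)) {
    assert_cols(x, c("sample_id", "log2_ratio"))
    if (!is.null(sample)) x <- x[x$sample_id == sample, ]
    if (length(unique(x$sample_id)) > 1) {
      abort("track contains several samples; pass `sample` to pick one")
    }
    x <- x$log2_ratio[!is.na(x$log2_ratio)]
  }
  x <- x[is.finite(x)]
  if (length(x) < 50) abort("need at least 50 observations to fit the noise model")
  assert_scalar_in(alpha, 0, 1, "alpha", open_lo = TRUE, open_hi = TRUE)

  with_seed(substream_seed(seed, "noise_model"), {
    fits <- purrr::map(seq_len(max_components), function(k) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        f <- em_gmm1d(x, k)
        if (is.null(best) || f$loglik > best$loglik) best <- f
      }
      best
    })
    n <- length(x)
    bic <- purrr::map2_dbl(fits, seq_along(fits), function(f, k) {
      -2 * f$loglik + (3 * k - 1) * log(n)
    })
    k_best <- which.min(bic)
    f <- fits[[k_best]]
    di <- which.min(abs(f$mean))
    z <- stats::qnorm(1 - alpha / 2)
    structure(
      list(
        components = tibble(weight = f$weight, mean = f$mean, sd = f$sd),
        diploid_index = di,
        band_low = f$mean[di] - z * f$sd[di],
        band_high = f$mean[di] + z * f$sd[di],
        alpha = alpha,
        n_obs = n,
        bic = bic,
        loglik_trace = f$trace
      ),
      class = "mm_noise_model"
    )
  })
}

# One EM run for a K-component univariate GMM. sd floored at 1e-4.
em_gmm1d <- function(x, k, max_iter = 300, tol = 1e-8) {
  n <- length(x)
  mu <- kmeanspp_means(x, k)
  sdv <- rep(max(sd(x) / k, 1e-4), k)
  if (!is.finite(sdv[1]) || sdv[1] <= 1e-4) {
    warn("degenerate (near-constant) data; sd floored at 1e-4")
    sdv <- rep(1e-4, k)
  }
  w <- rep(1 / k, k)
  trace <- numeric()
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      w[j] * stats::dnorm(x, mu[j], sdv[j])
    }, numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(rowsum_d))
    trace <- c(trace, ll)
    resp <- dens / rowsum_d
    nk <- pmax(colSums(resp), 1e-12)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sdv <- pmax(sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk), 1e-4)
    if (is.finite(ll_old) && ll - ll_old < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(weight = w, mean = mu, sd = sdv, loglik = ll, trace = trace)
}

# k-means++-style seeding: first mean uniform, later means drawn with
# probability proportional to squared distance from the nearest chosen mean.
kmeanspp_means <- function(x, k) {
  mu <- numeric(k)
  mu[1] <- x[sample.int(length(x), 1)]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- vapply(x, function(xi) min((xi - mu[seq_len(j - 1)])^2), numeric(1))
      if (sum(d2) <= 0) {
        mu[j] <- x[sample.int(length(x), 1)]
      } else {
        mu[j] <- x[sample.int(length(x), 1, prob = d2)]
      }
    }
  }
  mu
}

#' @export
print.mm_noise_model <- function(x, ...) {
  cat(sprintf(
    "Diploid noise model: %d component(s), diploid component %d, band [%.4f, %.4f] (alpha = %g)\n",
    nrow(x$components), x$diploid_index, x$band_low, x$band_high, x$alpha
  ))
  print(x$components)
  invisible(x)
}

#' @describeIn fit_noise_model Mixture components as a tibble.
#' @param ... Unused (method consistency).
#' @export
tidy.mm_noise_model <- function(x, ...) {
  mutate(x$components, component = row_number(),
         diploid = row_number() == x$diploid_index, .before = 1)
}

#' @describeIn fit_noise_model One-row model summary.
#' @export
glance.mm_noise_model <- function(x, ...) {
  tibble(
    k = nrow(x$components),
    diploid_mean = x$components$mean[x$diploid_index],
    diploid_sd = x$components$sd[x$diploid_index],
    band_low = x$band_low, band_high = x$band_high,
    alpha = x$alpha, n_obs = x$n_obs,
    loglik = tail(x$loglik_trace, 1), bic = min(x$bic)
  )
}
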