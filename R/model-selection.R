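#' Stepping-stone power schedule
#'
#' Powers are quantiles of a Beta(`beta_alpha`, 1) distribution, descending
#' from 1 to 0, which concentrates steps near the prior where the
#' integrand changes fastest.
#'
#' @param n_steps Number of stones.
#' @param beta_alpha Beta-distribution shape (0.4 by convention).
#' @return Descending numeric vector of length `n_steps + 1` from 1 to 0.
#' @export
ss_power_schedule <- function(n_steps, beta_alpha = 0.4) {
  stats::qbeta(seq(1, 0, length.out = n_steps + 1), beta_alpha, 1)
}

#' Stepping-stone run profiles
#'
#' `"desk"` is sized for interactive use and testing (10 stones, 10k
#' iterations each). `"paper"` records the full-scale production settings
#' used for published muroid-scale analyses: 30 stones plus 5 burn-in
#' stones across 250 million generations. The paper profile is documentary
#' at desk scale; running it requires cluster time.
#'
#' @param profile `"desk"` or `"paper"`.
#' @return List of stepping-stone settings.
#' @export
ss_config <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  switch(profile,
    desk = list(n_steps = 10, burnin_steps = 1, per_step = 10000,
                total_generations = 1e5, beta_alpha = 0.4,
                profile = "desk"),
    paper = list(n_steps = 30, burnin_steps = 5, per_step = NA_real_,
                 total_generations = 250e6, beta_alpha = 0.4,
                 profile = "paper")
  )
}

#' Stepping-stone marginal-likelihood estimate (generic MH engine)
#'
#' Estimates `ln m = sum_k ln (1/n) sum_i exp((b_{k+1} - b_k) lnL_i)` with
#' samples drawn by Metropolis-Hastings from the power posterior at the
#' lower power `b_k` of each ratio, accumulated in log space.
#'
#' @param log_lik Function(theta) -> data log-likelihood.
#' @param log_prior Function(theta) -> log prior density.
#' @param propose Function(theta) -> list(theta, log_hastings).
#' @param init Starting parameter value (any R object).
#' @param n_steps Number of stones (power-posterior ratios).
#' @param per_step MH iterations per stone.
#' @param burnin Fraction of each stone's iterations discarded.
#' @param beta_alpha Power-schedule shape.
#' @param seed Integer seed.
#' @return List: `mlnl`, `se` (naive Monte Carlo standard error), `steps`
#'   tibble.
#' @export
stepping_stone <- function(log_lik, log_prior, propose, init, n_steps = 10,
                           per_step = 10000, burnin = 0.2, beta_alpha = 0.4,
                           seed = 1) {
  set.seed(seed)
  betas <- ss_power_schedule(n_steps, beta_alpha)
  theta <- init
  ll <- log_lik(theta)
  lp <- log_prior(theta)
  if (!is.finite(lp)) stop("init has zero prior probability")
  total <- 0
  var_total <- 0
  steps <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    b_hi <- betas[k]; b_lo <- betas[k + 1]
    lls <- numeric(per_step)
    for (i in seq_len(per_step)) {
      pr <- propose(theta)
      ll2 <- log_lik(pr$theta)
      lp2 <- log_prior(pr$theta)
      a <- b_lo * (ll2 - ll) + (lp2 - lp) + pr$log_hastings
      if (is.finite(a) && log(stats::runif(1)) < a) {
        theta <- pr$theta; ll <- ll2; lp <- lp2
      }
      lls[i] <- ll
    }
    lls <- lls[-seq_len(floor(burnin * per_step))]
    if (all(!is.finite(lls))) stop("degenerate stone: all likelihoods zero")
    w <- (b_hi - b_lo) * lls
    m <- max(w)
    r <- mean(exp(w - m))
    lnr <- m + log(r)
    # delta-method SE with a crude autocorrelation correction
    nef <- max(4, ess(w))
    v <- stats::var(exp(w - m)) / (nef * r^2)
    total <- total + lnr
    var_total <- var_total + v
    steps[[k]] <- tibble::tibble(step = k, beta_lower = b_lo,
                                 beta_upper = b_hi, ln_ratio = lnr,
                                 n_eff = nef)
  }
  structure(list(mlnl = total, se = sqrt(var_total),
                 steps = dplyr::bind_rows(steps)),
            class = "ss_result")
}

#' Stepping-stone marginal likelihood of a tip-dating model
#'
#' Runs one tempered chain per stone with [run_mcmc] (warm burn-in per
#' step) and accumulates the power-posterior ratios of the Mk(v) data
#' likelihood.
#'
#' @inheritParams run_mcmc
#' @param n_steps,per_step,burnin,beta_alpha Stepping-stone settings.
#' @return List as in [stepping_stone].
#' @export
stepping_stone_mk <- function(cmat, tree, config = mcmc_config(),
                              n_steps = 10, per_step = 2000, burnin = 0.3,
                              beta_alpha = 0.4, seed = 1,
                              sample_every = 5) {
  betas <- ss_power_schedule(n_steps, beta_alpha)
  total <- 0
  var_total <- 0
  steps <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    b_hi <- betas[k]; b_lo <- betas[k + 1]
    run <- run_mcmc(cmat, tree, config, n_iter = per_step,
                    sample_every = sample_every, seed = seed + 7919L * k,
                    beta = b_lo)
    lls <- run$trace$lnL
    lls <- lls[-seq_len(floor(burnin * length(lls)))]
    w <- (b_hi - b_lo) * lls
    m <- max(w)
    r <- mean(exp(w - m))
    nef <- max(4, ess(w))
    total <- total + m + log(r)
    var_total <- var_total + stats::var(exp(w - m)) / (nef * r^2)
    steps[[k]] <- tibble::tibble(step = k, beta_lower = b_lo,
                                 beta_upper = b_hi, ln_ratio = m + log(r))
  }
  structure(list(mlnl = total, se = sqrt(var_total),
                 steps = dplyr::bind_rows(steps)),
            class = "ss_result")
}

#' Bayes factor on the 2 ln scale
#'
#' `BF = 2 * (mlnl_best - mlnl_model)`: 0 for the best model, positive for
#' every other.
#'
#' @param mlnl_model,mlnl_best Marginal natural log-likelihoods.
#' @return Numeric Bayes factor.
#' @export
bayes_factor <- function(mlnl_model, mlnl_best) {
  if (!is.finite(mlnl_model) || !is.finite(mlnl_best)) {
    stop("marginal likelihoods must be finite")
  }
  2 * (mlnl_best - mlnl_model)
}

#' Rank competing models by marginal likelihood
#'
#' @param comparisons Data frame with columns `model` and `mlnl`.
#' @param strong_threshold BF above which support is labelled strong
#'   (conventionally 5 on the 2 ln scale).
#' @return Tibble sorted by `mlnl` descending (stable for ties) with `bf`
#'   relative to the best model and a `support` label.
#' @export
rank_models <- function(comparisons, strong_threshold = 5) {
  df <- tibble::as_tibble(comparisons)
  if (nrow(df) < 1) stop("no models to rank")
  ord <- order(-df$mlnl)  # stable: ties keep input order
  df <- df[ord, ]
  best <- df$mlnl[1]
  df$bf <- vapply(df$mlnl, bayes_factor, numeric(1), mlnl_best = best)
  df$support <- dplyr::case_when(
    df$bf == 0 ~ "best",
    df$bf > strong_threshold ~ "strong",
    df$bf > 2 ~ "positive",
    TRUE ~ "weak"
  )
  df
}

#' @export
print.ss_result <- function(x, ...) {
  cat(sprintf("stepping-stone mLnL: %.4f (MC se %.4f, %d stones)\n",
              x$mlnl, x$se, nrow(x$steps)))
  invisible(x)
}

#' @export
glance.ss_result <- function(x, ...) {
  tibble::tibble(mlnl = x$mlnl, se = x$se, n_steps = nrow(x$steps))
}

#' Stone-by-stone contribution plot
#' @param object An `ss_result`.
#' @param ... Unused.
#' @export
autoplot.ss_result <- function(object, ...) {
  ggplot2::ggplot(object$steps,
                  ggplot2::aes(x = .data$beta_lower, y = .data$ln_ratio)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "power (lower bound of stone)",
                  y = "ln ratio contribution") +
    ggplot2::theme_minimal()
}
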