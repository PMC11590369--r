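#' Clock-rate prior from a non-clock pre-run
#'
#' The informative lognormal prior on the base clock rate is built by
#' dividing the median posterior tree height in substitutions (from a
#' non-clock analysis) by the median of the root-age prior, then taking the
#' natural log as the lognormal location. The scale is passed through
#' unchanged (a broad value like 1.5 keeps the prior weakly informative).
#'
#' @param tree_height_subst Median root-to-tip tree height in substitutions.
#' @param root_age Median of the root-age prior, Ma.
#' @param sd_log Lognormal scale parameter.
#' @return A tibble with `ratio`, `mean_log`, `sd_log`.
#' @export
derive_clock_rate_prior <- function(tree_height_subst, root_age,
                                    sd_log = 1.5) {
  if (tree_height_subst <= 0 || root_age <= 0) {
    stop("tree height and root age must be positive")
  }
  if (sd_log <= 0) stop("sd_log must be positive")
  ratio <- tree_height_subst / root_age
  tibble::tibble(ratio = ratio, mean_log = log(ratio), sd_log = sd_log)
}

#' Clock model configuration
#'
#' Supported branch-rate models: `strict` (all multipliers 1), `iln`
#' (independent lognormal, unit mean in real space), `igr` (independent
#' gamma, mean 1 and variance `nu`), `wn` (white noise: gamma with variance
#' `nu / duration`, so longer branches average out rate noise), and `tk02`
#' (autocorrelated lognormal node rates; the log-rate variance accumulates
#' as `nu * duration` along a lineage, and a branch multiplier is the
#' arithmetic mean of its endpoint node rates).
#'
#' @param model One of `"strict"`, `"tk02"`, `"iln"`, `"igr"`, `"wn"`.
#' @param base_rate Base clock rate c, substitutions per Ma.
#' @param nu Rate-variance parameter (> 0 unless strict).
#' @param base_rate_prior Named list `mean_log`, `sd_log` of the lognormal
#'   prior on `base_rate`.
#' @param nu_prior_mean Mean of the exponential hyperprior on `nu`.
#' @return A `clock_config` list.
#' @export
clock_config <- function(model = c("strict", "tk02", "iln", "igr", "wn"),
                         base_rate = 0.4426, nu = 0.1,
                         base_rate_prior = list(mean_log = log(0.4426),
                                                sd_log = 1.5),
                         nu_prior_mean = 1) {
  model <- match.arg(model)
  if (base_rate <= 0) stop("base_rate must be positive")
  if (model != "strict" && nu <= 0) stop("nu must be positive")
  structure(list(model = model, base_rate = base_rate, nu = nu,
                 base_rate_prior = base_rate_prior,
                 nu_prior_mean = nu_prior_mean),
            class = "clock_config")
}

#' Simulate branch-rate multipliers under a clock model
#'
#' Draws per-branch relative rates with prior mean 1 under each model. For
#' TK02 the root node rate is 1 and child node log-rates diffuse with
#' variance `nu * duration` (with the -nu*t/2 drift that keeps the expected
#' rate at 1); branch multipliers average the endpoint node rates. Branches
#' of zero duration (sampled-ancestor attachments) inherit rates without a
#' density contribution.
#'
#' @param clock A [clock_config].
#' @param tree A [time_tree].
#' @return A `branch_rates` list: `rates` per edge (order of
#'   `tree$phy$edge`) and, for TK02, `node_rates` per node.
#' @export
draw_branch_rates <- function(clock, tree) {
  e <- tree$phy$edge
  dur <- branch_durations(tree)
  nb <- nrow(e)
  nu <- clock$nu
  node_rates <- NULL
  rates <- switch(clock$model,
    strict = rep(1, nb),
    iln = {
      s2 <- log1p(nu)  # lognormal with real-space mean 1, variance nu
      stats::rlnorm(nb, meanlog = -s2 / 2, sdlog = sqrt(s2))
    },
    igr = stats::rgamma(nb, shape = 1 / nu, rate = 1 / nu),
    wn = ifelse(dur <= 0, 1,
                stats::rgamma(nb, shape = dur / nu, rate = dur / nu)),
    tk02 = {
      nn <- ape::Ntip(tree$phy) + tree$phy$Nnode
      nr <- rep(NA_real_, nn)
      nr[ape::Ntip(tree$phy) + 1L] <- 1
      po <- rev(ape::postorder(tree$phy))  # preorder over edges
      for (i in po) {
        p <- e[i, 1]; ch <- e[i, 2]; t <- dur[i]
        nr[ch] <- if (t <= 0) nr[p] else {
          stats::rlnorm(1, meanlog = log(nr[p]) - nu * t / 2,
                        sdlog = sqrt(nu * t))
        }
      }
      node_rates <- nr
      (nr[e[, 1]] + nr[e[, 2]]) / 2
    }
  )
  structure(list(rates = rates, node_rates = node_rates,
                 model = clock$model), class = "branch_rates")
}

#' Log prior density of branch rates under a clock model
#'
#' @param clock A [clock_config].
#' @param br A `branch_rates` object (needs `node_rates` for TK02).
#' @param tree A [time_tree].
#' @return Log density (0 for a strict clock with all-ones rates).
#' @export
branch_rate_log_prior <- function(clock, br, tree) {
  e <- tree$phy$edge
  dur <- branch_durations(tree)
  r <- br$rates
  nu <- clock$nu
  switch(clock$model,
    strict = if (all(r == 1)) 0 else -Inf,
    iln = {
      s2 <- log1p(nu)
      sum(stats::dlnorm(r, meanlog = -s2 / 2, sdlog = sqrt(s2), log = TRUE))
    },
    igr = sum(stats::dgamma(r, shape = 1 / nu, rate = 1 / nu, log = TRUE)),
    wn = {
      ok <- dur > 0
      sum(stats::dgamma(r[ok], shape = dur[ok] / nu, rate = dur[ok] / nu,
                        log = TRUE))
    },
    tk02 = {
      nr <- br$node_rates
      if (is.null(nr)) stop("TK02 prior needs node rates")
      ok <- dur > 0
      sum(stats::dlnorm(nr[e[ok, 2]],
                        meanlog = log(nr[e[ok, 1]]) - nu * dur[ok] / 2,
                        sdlog = sqrt(nu * dur[ok]), log = TRUE))
    }
  )
}

#' Effective branch lengths in expected substitutions
#'
#' `length_b = duration_b * base_rate * r_b`; sampled-ancestor attachment
#' branches have zero duration and hence zero effective length.
#'
#' @param tree A [time_tree].
#' @param base_rate Base clock rate (substitutions per Ma).
#' @param br Optional `branch_rates`; strict clock if omitted.
#' @return Numeric vector in the order of `tree$phy$edge`.
#' @export
effective_lengths <- function(tree, base_rate = 1, br = NULL) {
  r <- if (is.null(br)) 1 else br$rates
  branch_durations(tree) * base_rate * r
}
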