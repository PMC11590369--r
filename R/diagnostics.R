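#' Average standard deviation of split frequencies
#'
#' Across-run convergence diagnostic for tree samples: for every split that
#' reaches `min_freq` in at least one run, take the sample standard
#' deviation of its frequency across runs, and average over qualifying
#' splits.
#'
#' @param runs List of >= 2 `mcmc_trace` objects (or lists of `phylo`).
#' @param min_freq Minimum within-run frequency for a split to qualify.
#' @param burnin Fraction of each run discarded.
#' @return ASDSF (0 when no split qualifies, with a warning).
#' @export
asdsf <- function(runs, min_freq = 0.1, burnin = 0.25) {
  trees <- lapply(runs, trace_trees, burnin = burnin)
  if (length(trees) < 2) stop("need >= 2 runs")
  freqs <- lapply(trees, split_freqs)
  splits <- unique(unlist(lapply(freqs, names)))
  tab <- vapply(freqs, function(f) {
    ifelse(splits %in% names(f), f[splits], 0)
  }, numeric(length(splits)))
  tab <- matrix(tab, nrow = length(splits))
  qual <- apply(tab, 1, max) >= min_freq
  if (!any(qual)) {
    warning("no split reaches min_freq; ASDSF reported as 0")
    return(0)
  }
  mean(apply(tab[qual, , drop = FALSE], 1, stats::sd))
}

trace_trees <- function(x, burnin = 0) {
  tr <- if (inherits(x, "mcmc_trace")) x$trees else x
  n <- length(tr)
  tr[(floor(burnin * n) + 1L):n]
}

# Named frequency vector of non-trivial splits (by sorted tip-label key).
split_freqs <- function(trees) {
  n <- length(trees)
  counts <- new.env(hash = TRUE)
  labs <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    pp <- ape::prop.part(tr)
    lab <- attr(pp, "labels")
    for (cl in pp) {
      if (length(cl) <= 1L || length(cl) >= length(lab)) next
      key <- paste(sort(lab[cl]), collapse = "|")
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  out <- unlist(as.list(counts)) / n
  if (is.null(out)) stats::setNames(numeric(0), character(0)) else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' @param runs List of >= 2 `mcmc_trace` objects, or a list of numeric
#'   matrices/data frames of sampled parameters.
#' @param burnin Fraction discarded.
#' @return Tibble: parameter, psrf, flag for zero-variance series (PSRF
#'   reported as 1).
#' @export
psrf <- function(runs, burnin = 0.25) {
  mats <- lapply(runs, trace_params, burnin = burnin)
  if (length(mats) < 2) stop("need >= 2 runs")
  pars <- colnames(mats[[1]])
  purrr::map_dfr(pars, function(pn) {
    xs <- lapply(mats, function(m) m[, pn])
    if (all(vapply(xs, stats::var, numeric(1)) < 1e-30)) {
      return(tibble::tibble(parameter = pn, psrf = 1, zero_variance = TRUE))
    }
    ml <- coda::mcmc.list(lapply(xs, coda::mcmc))
    g <- try(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1],
             silent = TRUE)
    tibble::tibble(parameter = pn,
                   psrf = if (inherits(g, "try-error")) NA_real_ else g,
                   zero_variance = FALSE)
  })
}

trace_params <- function(x, burnin = 0) {
  m <- if (inherits(x, "mcmc_trace")) {
    as.matrix(x$trace[, setdiff(colnames(x$trace), "iteration")])
  } else as.matrix(x)
  n <- nrow(m)
  m[(floor(burnin * n) + 1L):n, , drop = FALSE]
}

#' Effective sample size
#'
#' Autocorrelation-time-based ESS (spectral estimator).
#'
#' @param series Numeric vector (one stationary chain segment).
#' @return ESS estimate.
#' @export
ess <- function(series) {
  if (stats::var(series) < 1e-30) return(length(series))
  as.numeric(coda::effectiveSize(coda::mcmc(series)))
}

#' Convergence gate mirroring standard run-acceptance thresholds
#'
#' @param runs List of >= 2 `mcmc_trace` objects.
#' @param asdsf_max,psrf_max,ess_min Thresholds (0.01, 1.05, 200).
#' @param burnin Fraction discarded.
#' @return A `glance`-style one-row tibble with the diagnostics and a
#'   `converged` verdict.
#' @export
convergence_gate <- function(runs, asdsf_max = 0.01, psrf_max = 1.05,
                             ess_min = 200, burnin = 0.25) {
  a <- asdsf(runs, burnin = burnin)
  p <- psrf(runs, burnin = burnin)
  mats <- lapply(runs, trace_params, burnin = burnin)
  pooled <- do.call(rbind, mats)
  keep <- apply(pooled, 2, stats::var) > 1e-30
  esss <- vapply(colnames(pooled)[keep], function(pn) {
    sum(vapply(mats, function(m) ess(m[, pn]), numeric(1)))
  }, numeric(1))
  tibble::tibble(
    asdsf = a,
    max_psrf = max(p$psrf, na.rm = TRUE),
    min_ess = if (length(esss)) min(esss) else Inf,
    converged = a <= asdsf_max & max(p$psrf, na.rm = TRUE) <= psrf_max &
      (!length(esss) || min(esss) >= ess_min)
  )
}

#' @export
glance.mcmc_trace <- function(x, ...) {
  m <- trace_params(x, burnin = 0.25)
  keep <- apply(m, 2, stats::var) > 1e-30
  tibble::tibble(
    n_samples = nrow(x$trace),
    target = x$target,
    seed = x$seed,
    min_ess = if (any(keep)) {
      min(vapply(colnames(m)[keep], function(pn) ess(m[, pn]), numeric(1)))
    } else Inf,
    mean_lnL = mean(x$trace$lnL)
  )
}

#' @export
tidy.mcmc_trace <- function(x, burnin = 0.25, ...) {
  m <- trace_params(x, burnin = burnin)
  purrr::map_dfr(colnames(m), function(pn) {
    v <- m[, pn]
    h <- hpd(v)
    tibble::tibble(parameter = pn, mean = mean(v),
                   median = stats::median(v),
                   hpd_lower = h[1], hpd_upper = h[2])
  })
}

#' Trace plot of sampled parameters
#'
#' @param object An `mcmc_trace`.
#' @param parameters Which columns to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcmc_trace <- function(object,
                                parameters = c("lnL", "base_rate",
                                               "root_age"), ...) {
  df <- object$trace |>
    dplyr::select(dplyr::all_of(c("iteration", parameters))) |>
    tidyr::pivot_longer(-"iteration", names_to = "parameter")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}
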