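#' Fossilized birth-death parameters
#'
#' Parameterized as net diversification `d = lambda - mu`, turnover
#' `r = mu / lambda` in `[0, 1)`, fossil-sampling probability
#' `s = psi / (mu + psi)` in `[0, 1]`, and extant-sampling fraction `rho`.
#'
#' @param d Net diversification, per Ma (> 0).
#' @param r Turnover in `[0, 1)`.
#' @param s Fossil-sampling probability in `[0, 1]`.
#' @param rho Extant-sampling fraction in `(0, 1]`.
#' @return An `fbd_params` list that also carries the implied `lambda`,
#'   `mu`, `psi`.
#' @export
fbd_params <- function(d, r = 0, s = 0, rho = 1) {
  if (d <= 0) stop("net diversification must be > 0")
  if (r < 0 || r >= 1) stop("turnover must be in [0, 1)")
  if (s < 0 || s > 1) stop("fossil-sampling probability must be in [0, 1]")
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  if (s >= 1) stop("s = 1 implies infinite psi")
  lambda <- d / (1 - r)
  mu <- lambda * r
  psi <- s * mu / (1 - s)
  structure(list(d = d, r = r, s = s, rho = rho,
                 lambda = lambda, mu = mu, psi = psi),
            class = "fbd_params")
}

#' @rdname fbd_params
#' @param lambda,mu,psi Direct birth, death and fossil-sampling rates.
#' @export
fbd_params_rates <- function(lambda, mu, psi, rho = 1) {
  if (lambda <= mu) stop("requires lambda > mu")
  if (min(lambda, psi) < 0 || mu < 0) stop("rates must be non-negative")
  structure(list(d = lambda - mu, r = mu / lambda,
                 s = if (mu + psi > 0) psi / (mu + psi) else 0, rho = rho,
                 lambda = lambda, mu = mu, psi = psi),
            class = "fbd_params")
}

# Auxiliary FBD quantities (age t >= 0 before present).
# p0(t): probability that a lineage alive at age t leaves no sampled
# descendants (neither psi-fossils nor rho-sampled extant tips).
# q(t): per-branch density factor of the reconstructed sampled tree.
fbd_c12 <- function(p) {
  c1 <- sqrt((p$lambda - p$mu - p$psi)^2 + 4 * p$lambda * p$psi)
  c2 <- -(p$lambda - p$mu - 2 * p$lambda * p$rho - p$psi) / c1
  list(c1 = c1, c2 = c2)
}

fbd_p0 <- function(t, p) {
  cc <- fbd_c12(p)
  ex <- exp(-cc$c1 * t)
  num <- ex * (1 - cc$c2) - (1 + cc$c2)
  den <- ex * (1 - cc$c2) + (1 + cc$c2)
  1 + (-(p$lambda - p$mu - p$psi) + cc$c1 * num / den) / (2 * p$lambda)
}

fbd_log_q <- function(t, p) {
  cc <- fbd_c12(p)
  # q(t) = 4 e^{-c1 t} / (e^{-c1 t}(1-c2) + (1+c2))^2, with q(0) = 1
  log(4) - cc$c1 * t -
    2 * log(exp(-cc$c1 * t) * (1 - cc$c2) + (1 + cc$c2))
}

#' Fossilized birth-death log density of a sampled tree
#'
#' Density over labeled, dated sampled trees, conditioned on the root age
#' and on both root lineages having sampled descendants. Built from event
#' factors: `lambda` per bifurcation, `psi * p0(y)` per fossil tip at age
#' `y`, `psi` per sampled ancestor, `rho` per extant tip, and the branch
#' factor `q(top)/q(bottom)` per reconstructed branch (which telescopes to
#' a product over node ages).
#'
#' @param tree A [time_tree] with sampled-ancestor flags set.
#' @param p An [fbd_params].
#' @return Log density.
#' @export
fbd_log_density <- function(tree, p) {
  ntip <- ape::Ntip(tree$phy)
  ages <- tree$ages
  sa <- tree$sampled_ancestor
  tip_is_sa <- sa[seq_len(ntip)]
  tipage <- ages[seq_len(ntip)]
  fossil_tip <- tipage > 1e-10 & !tip_is_sa
  extant_tip <- !fossil_tip & !tip_is_sa
  # bifurcation nodes: internal nodes that are not SA attachment points
  internal <- (ntip + 1L):(ntip + tree$phy$Nnode)
  sa_parent <- unique(tree$phy$edge[tree$phy$edge[, 2] <= ntip, 1][
    tip_is_sa[tree$phy$edge[tree$phy$edge[, 2] <= ntip, 2]]])
  bif <- setdiff(internal, sa_parent)
  root <- ntip + 1L
  x1 <- ages[root]
  if (p$psi == 0 && (sum(fossil_tip) + sum(tip_is_sa)) > 0) return(-Inf)
  ll <- 2 * fbd_log_q(x1, p) +
    sum(fbd_log_q(ages[setdiff(bif, root)], p)) +
    (length(bif) - 1L) * log(p$lambda) +
    sum(extant_tip) * log(p$rho)
  if (any(fossil_tip)) {
    y <- tipage[fossil_tip]
    ll <- ll + sum(log(p$psi) + log(fbd_p0(y, p)) - fbd_log_q(y, p))
  }
  if (any(tip_is_sa)) ll <- ll + sum(tip_is_sa) * log(p$psi)
  # condition on both root lineages being sampled
  ll - 2 * log1p(-fbd_p0(x1, p))
}

#' Root-age calibration with a hard minimum and soft maximum
#'
#' Offset-exponential prior: zero mass below `offset`, exponential decay
#' above it. By default the tail rate is set so that `soft_max` is the
#' `tail_prob`-upper quantile (5% of mass beyond the soft maximum);
#' alternatively `soft_max` can be interpreted as the distribution mean.
#'
#' @param offset Hard minimum age, Ma.
#' @param soft_max Soft maximum age, Ma (> offset).
#' @param tail_prob Mass allowed above `soft_max` (quantile semantics).
#' @param semantics `"quantile"` or `"mean"`.
#' @return A `root_calibration` list with the exponential `rate`.
#' @export
root_calibration <- function(offset = 34, soft_max = 41.2, tail_prob = 0.05,
                             semantics = c("quantile", "mean")) {
  semantics <- match.arg(semantics)
  if (soft_max <= offset) stop("soft_max must exceed offset")
  rate <- switch(semantics,
    quantile = -log(tail_prob) / (soft_max - offset),
    mean = 1 / (soft_max - offset)
  )
  structure(list(offset = offset, soft_max = soft_max, rate = rate,
                 semantics = semantics), class = "root_calibration")
}

#' @rdname root_calibration
#' @param age Root age, Ma.
#' @param cal A `root_calibration`.
#' @export
root_age_log_prior <- function(age, cal) {
  ifelse(age < cal$offset, -Inf,
         stats::dexp(age - cal$offset, rate = cal$rate, log = TRUE))
}

#' Uniform stratigraphic tip-age priors
#'
#' Each fossil tip age gets an independent uniform prior over its
#' stratigraphic range; extant tips are fixed at 0 and contribute nothing.
#'
#' @param tree A [time_tree] whose `calibrations` tibble has columns
#'   `taxon`, `min_age`, `max_age`.
#' @return Log prior density of the current tip ages.
#' @export
tip_age_log_prior <- function(tree) {
  cal <- tree$calibrations
  if (is.null(cal) || nrow(cal) == 0) return(0)
  if (any(cal$min_age >= cal$max_age)) {
    stop("calibration with min_age >= max_age")
  }
  ta <- tip_ages(tree)
  idx <- match(cal$taxon, names(ta))
  if (anyNA(idx)) stop(sprintf("calibrated taxon '%s' not in tree",
                               cal$taxon[which(is.na(idx))[1]]))
  a <- ta[idx]
  if (any(a < cal$min_age | a > cal$max_age)) return(-Inf)
  -sum(log(cal$max_age - cal$min_age))
}
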