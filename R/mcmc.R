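#' MCMC configuration for tip-dated analyses
#'
#' Bundles the model settings of a dating run: clock model, among-character
#' rate variation, FBD hyperpriors, and the root calibration.
#'
#' @param clock A [clock_config].
#' @param root_cal A [root_calibration].
#' @param n_categories Discrete-gamma categories for the Mk likelihood.
#' @param alpha_prior_mean Mean of the exponential prior on the gamma shape.
#' @param net_div_prior_mean Mean of the exponential prior on net
#'   diversification (turnover and fossil-sampling probability get flat
#'   U\[0,1\] priors).
#' @param rho Extant-sampling fraction (fixed, not sampled).
#' @param topology_moves Enable rooted NNI moves?
#' @param sa_toggle Enable sampled-ancestor toggling of fossil tips?
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(clock = clock_config("strict"),
                        root_cal = root_calibration(34, 41.2),
                        n_categories = 4, alpha_prior_mean = 1,
                        net_div_prior_mean = 1, rho = 1,
                        topology_moves = FALSE, sa_toggle = TRUE) {
  structure(list(clock = clock, root_cal = root_cal,
                 n_categories = n_categories,
                 alpha_prior_mean = alpha_prior_mean,
                 net_div_prior_mean = net_div_prior_mean, rho = rho,
                 topology_moves = topology_moves, sa_toggle = sa_toggle),
            class = "mcmc_config")
}

# Parameter-prior log density (hyperpriors + calibrations, no tree density).
param_log_prior <- function(st, cfg) {
  lp <- stats::dlnorm(st$c, cfg$clock$base_rate_prior$mean_log,
                      cfg$clock$base_rate_prior$sd_log, log = TRUE) +
    stats::dexp(st$alpha, 1 / cfg$alpha_prior_mean, log = TRUE) +
    stats::dexp(st$d, 1 / cfg$net_div_prior_mean, log = TRUE) +
    stats::dunif(st$r, 0, 1, log = TRUE) +
    stats::dunif(st$s, 0, 1, log = TRUE)
  if (cfg$clock$model != "strict") {
    lp <- lp + stats::dexp(st$nu, 1 / cfg$clock$nu_prior_mean, log = TRUE)
  }
  lp
}

# Tip-age calibration prior; sampled-ancestor tips contribute a window
# indicator (their age is tied to the parent) but no uniform density term.
tip_prior_state <- function(st, cfg) {
  cal <- st$tree$calibrations
  if (is.null(cal) || nrow(cal) == 0) return(0)
  ta <- tip_ages(st$tree)
  idx <- match(cal$taxon, names(ta))
  a <- ta[idx]
  sa <- st$tree$sampled_ancestor[idx]
  if (any(a < cal$min_age - 1e-12 | a > cal$max_age + 1e-12)) return(-Inf)
  -sum(log(cal$max_age - cal$min_age)[!sa])
}

state_log_prior <- function(st, cfg, target) {
  lp <- param_log_prior(st, cfg) + tip_prior_state(st, cfg) +
    root_age_log_prior(root_age(st$tree), cfg$root_cal)
  if (cfg$clock$model != "strict") {
    lp <- lp + branch_rate_log_prior(cfg_clock(cfg, st), st$br, st$tree)
  }
  if (target != "hyperprior") {
    lp <- lp + fbd_log_density(st$tree, fbd_params(st$d, st$r, st$s,
                                                   cfg$rho))
  }
  lp
}

cfg_clock <- function(cfg, st) {
  cl <- cfg$clock
  cl$nu <- st$nu
  cl
}

state_log_lik <- function(st, cfg, cmat, prior_only) {
  if (prior_only) return(0)
  eff <- branch_durations(st$tree) * st$c * st$br$rates
  mk_loglik(cmat, st$tree, eff, gamma_shape = st$alpha,
            n_categories = cfg$n_categories)
}

refresh_tree <- function(st) {
  st$tree$phy$edge.length <- branch_durations(st$tree)
  st$tree$sampled_ancestor <- detect_sampled_ancestors(st$tree)
  st
}

#' Metropolis-Hastings sampler for tip-dated morphological analyses
#'
#' Samples node and fossil-tip ages, clock and substitution parameters, and
#' FBD parameters from the joint posterior of a [char_matrix] on a
#' [time_tree]. Proposals: multiplier moves on the base rate, gamma shape,
#' rate variance and net diversification; reflected slides on turnover and
#' fossil-sampling probability; constrained uniform slides on internal-node
#' and fossil-tip ages; a multiplier on the root age; branch- or node-rate
#' multipliers for relaxed clocks; sampled-ancestor toggles; and optional
#' rooted NNI topology moves.
#'
#' @param cmat A [char_matrix] (ignored when `target != "posterior"`).
#' @param tree Starting [time_tree] (with calibrations for fossil tips).
#' @param config An [mcmc_config].
#' @param n_iter Number of iterations.
#' @param sample_every Thinning interval for the trace.
#' @param seed Integer seed (all randomness flows from it).
#' @param target `"posterior"`, `"prior"` (tree prior retained, data
#'   likelihood off) or `"hyperprior"` (parameter and calibration priors
#'   only; used to validate the proposal machinery against the stated
#'   priors).
#' @param audit_every Recompute the cached posterior from scratch this
#'   often and error if it drifted.
#' @return An `mcmc_trace`: tibble of sampled parameters, sampled trees,
#'   acceptance rates, seed and config.
#' @export
run_mcmc <- function(cmat, tree, config = mcmc_config(), n_iter = 10000,
                     sample_every = 10, seed = 1, target = "posterior",
                     audit_every = 2500, beta = 1, proposal_scale = 1) {
  set.seed(seed)
  prior_only <- target != "posterior"
  cfg <- config
  cl <- cfg$clock
  st <- list(
    tree = tree,
    c = cl$base_rate, alpha = 1, nu = if (cl$model == "strict") 0 else cl$nu,
    d = 0.5, r = 0.25, s = 0.25,
    br = draw_branch_rates(cl, tree)
  )
  if (cl$model != "strict") {
    # start from the prior mean rather than a random draw
    st$br$rates[] <- 1
    if (!is.null(st$br$node_rates)) st$br$node_rates[] <- 1
  }
  st <- refresh_tree(st)
  st$lp <- state_log_prior(st, cfg, target)
  st$ll <- state_log_lik(st, cfg, cmat, prior_only)
  if (!is.finite(st$lp)) stop("starting state has zero prior probability")

  ntip <- ape::Ntip(tree$phy)
  internal <- if (tree$phy$Nnode > 1L) {
    (ntip + 2L):(ntip + tree$phy$Nnode)
  } else integer(0)
  cal <- tree$calibrations
  fossil_tips <- if (is.null(cal)) integer(0) else {
    match(cal$taxon, tree$phy$tip.label)
  }
  moves <- c("c", "alpha", "d", "r", "s", "node_age", "root_age",
             "tree_scale", "rate_height")
  if (length(fossil_tips)) moves <- c(moves, "tip_age")
  if (length(fossil_tips) && cfg$sa_toggle) moves <- c(moves, "sa_toggle")
  if (cl$model != "strict") moves <- c(moves, "nu", "branch_rate")
  if (cfg$topology_moves && length(internal) >= 1) moves <- c(moves, "nni")
  move_w <- stats::setNames(rep(1, length(moves)), moves)
  move_w["node_age"] <- max(1, length(internal) / 2)
  move_w[c("tree_scale", "rate_height")] <- 2
  if ("tip_age" %in% moves) move_w["tip_age"] <- max(1, length(fossil_tips) / 3)
  if ("branch_rate" %in% moves) {
    move_w["branch_rate"] <- max(1, nrow(tree$phy$edge) / 3)
  }
  move_p <- move_w / sum(move_w)
  acc <- stats::setNames(numeric(length(moves)), moves)
  tries <- acc

  keep <- floor(n_iter / sample_every)
  pars <- matrix(NA_real_, keep, 10)
  colnames(pars) <- c("iteration", "lnL", "lnPrior", "base_rate", "alpha",
                      "nu", "net_div", "turnover", "fossil_sampling",
                      "root_age")
  trees <- vector("list", keep)
  ages_mat <- matrix(NA_real_, keep, ntip + tree$phy$Nnode)
  si <- 0L

  for (it in seq_len(n_iter)) {
    mv <- sample(moves, 1, prob = move_p)
    tries[mv] <- tries[mv] + 1
    prop <- propose_move(st, mv, cfg, ntip, internal, fossil_tips,
                         proposal_scale)
    if (!is.null(prop) &&
        min(prop$state$tree$ages[prop$state$tree$phy$edge[, 1]] -
              prop$state$tree$ages[prop$state$tree$phy$edge[, 2]]) > -1e-12) {
      ps <- prop$state
      ps <- refresh_tree(ps)
      ps$lp <- state_log_prior(ps, cfg, target)
      if (is.finite(ps$lp)) {
        ps$ll <- if (prop$needs_lik) {
          state_log_lik(ps, cfg, cmat, prior_only)
        } else st$ll
        lr <- beta * (ps$ll - st$ll) + (ps$lp - st$lp) + prop$log_hastings
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          st <- ps
          acc[mv] <- acc[mv] + 1
        }
      }
    }
    if (it %% audit_every == 0) {
      fresh <- state_log_lik(st, cfg, cmat, prior_only)
      if (abs(fresh - st$ll) > 1e-8) stop("cached likelihood drifted")
    }
    if (it %% sample_every == 0) {
      si <- si + 1L
      pars[si, ] <- c(it, st$ll, st$lp, st$c, st$alpha, st$nu, st$d, st$r,
                      st$s, root_age(st$tree))
      trees[[si]] <- st$tree$phy
      ages_mat[si, ] <- st$tree$ages
    }
  }
  structure(list(
    trace = tibble::as_tibble(as.data.frame(pars)),
    trees = trees[seq_len(si)],
    ages = ages_mat[seq_len(si), , drop = FALSE],
    tip_age_trace = NULL,
    acceptance = tibble::tibble(move = moves, tried = as.integer(tries),
                                accepted = as.integer(acc),
                                rate = ifelse(tries > 0, acc / tries, NA)),
    seed = seed, config = cfg, target = target,
    final = st
  ), class = "mcmc_trace")
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf("mcmc_trace: %d samples (target: %s, seed %d)\n",
              nrow(x$trace), x$target, x$seed))
  zero <- x$acceptance$move[x$acceptance$tried > 0 &
                              x$acceptance$accepted == 0]
  if (length(zero)) {
    cat("proposal classes with zero acceptance:",
        paste(zero, collapse = ", "), "\n")
  }
  invisible(x)
}

# One proposal. Returns NULL for an immediate reject (e.g. no valid target),
# else list(state, log_hastings, needs_lik).
propose_move <- function(st, mv, cfg, ntip, internal, fossil_tips,
                         scale = 1) {
  lh <- 0
  needs_lik <- TRUE
  switch(mv,
    c = {
      f <- exp(scale * 0.4 * (stats::runif(1) - 0.5))
      st$c <- st$c * f; lh <- log(f)
    },
    alpha = {
      f <- exp(scale * 0.6 * (stats::runif(1) - 0.5))
      st$alpha <- st$alpha * f; lh <- log(f)
    },
    nu = {
      f <- exp(scale * 0.6 * (stats::runif(1) - 0.5))
      st$nu <- st$nu * f; lh <- log(f)
      needs_lik <- FALSE
    },
    d = {
      f <- exp(scale * 0.8 * (stats::runif(1) - 0.5))
      st$d <- st$d * f; lh <- log(f)
      needs_lik <- FALSE
    },
    r = {
      st$r <- reflect01(st$r + min(1, scale * 0.2) * (stats::runif(1) - 0.5))
      needs_lik <- FALSE
    },
    s = {
      st$s <- reflect01(st$s + min(1, scale * 0.2) * (stats::runif(1) - 0.5))
      needs_lik <- FALSE
    },
    node_age = {
      if (!length(internal)) return(NULL)
      v <- if (length(internal) == 1) internal else sample(internal, 1)
      e <- st$tree$phy$edge
      par <- e[e[, 2] == v, 1]
      kids <- e[e[, 1] == v, 2]
      sa_kids <- kids[kids <= ntip & st$tree$sampled_ancestor[kids]]
      free_kids <- setdiff(kids, sa_kids)
      lo <- if (length(free_kids)) max(st$tree$ages[free_kids]) else 0
      hi <- st$tree$ages[par]
      if (hi <= lo) return(NULL)
      newage <- stats::runif(1, lo, hi)
      st$tree$ages[v] <- newage
      st$tree$ages[sa_kids] <- newage
    },
    root_age = {
      root <- ntip + 1L
      e <- st$tree$phy$edge
      kids <- e[e[, 1] == root, 2]
      sa_kids <- kids[kids <= ntip & st$tree$sampled_ancestor[kids]]
      free_kids <- setdiff(kids, sa_kids)
      lo <- if (length(free_kids)) max(st$tree$ages[free_kids]) else 0
      h <- st$tree$ages[root] - lo
      f <- exp(scale * 0.3 * (stats::runif(1) - 0.5))
      st$tree$ages[root] <- lo + h * f
      st$tree$ages[sa_kids] <- st$tree$ages[root]
      lh <- log(f)
    },
    tip_age = {
      tp <- if (length(fossil_tips) == 1) fossil_tips else {
        sample(fossil_tips, 1)
      }
      if (st$tree$sampled_ancestor[tp]) return(NULL)
      cal <- st$tree$calibrations
      ci <- match(st$tree$phy$tip.label[tp], cal$taxon)
      e <- st$tree$phy$edge
      par <- e[e[, 2] == tp, 1]
      lo <- cal$min_age[ci]
      hi <- min(cal$max_age[ci], st$tree$ages[par])
      if (hi <= lo) return(NULL)
      st$tree$ages[tp] <- stats::runif(1, lo, hi)
    },
    sa_toggle = {
      tp <- if (length(fossil_tips) == 1) fossil_tips else {
        sample(fossil_tips, 1)
      }
      cal <- st$tree$calibrations
      ci <- match(st$tree$phy$tip.label[tp], cal$taxon)
      e <- st$tree$phy$edge
      par <- e[e[, 2] == tp, 1]
      page <- st$tree$ages[par]
      lo <- cal$min_age[ci]
      hi <- min(cal$max_age[ci], page)
      if (st$tree$sampled_ancestor[tp]) {
        if (hi <= lo) return(NULL)
        st$tree$ages[tp] <- stats::runif(1, lo, hi)
        lh <- log(hi - lo)   # reverse move is deterministic
      } else {
        if (page < lo || page > cal$max_age[ci] || hi <= lo) return(NULL)
        st$tree$ages[tp] <- page
        lh <- -log(hi - lo)
      }
    },
    tree_scale = {
      f <- exp(scale * 0.2 * (stats::runif(1) - 0.5))
      idx <- (ntip + 1L):length(st$tree$ages)
      sa_tips <- which(st$tree$sampled_ancestor[seq_len(ntip)])
      st$tree$ages[idx] <- st$tree$ages[idx] * f
      if (length(sa_tips)) {
        e <- st$tree$phy$edge
        par <- e[match(sa_tips, e[, 2]), 1]
        st$tree$ages[sa_tips] <- st$tree$ages[par]
      }
      lh <- length(idx) * log(f)
    },
    rate_height = {
      f <- exp(scale * 0.2 * (stats::runif(1) - 0.5))
      idx <- (ntip + 1L):length(st$tree$ages)
      sa_tips <- which(st$tree$sampled_ancestor[seq_len(ntip)])
      st$tree$ages[idx] <- st$tree$ages[idx] * f
      if (length(sa_tips)) {
        e <- st$tree$phy$edge
        par <- e[match(sa_tips, e[, 2]), 1]
        st$tree$ages[sa_tips] <- st$tree$ages[par]
      }
      st$c <- st$c / f
      lh <- (length(idx) - 1) * log(f)
    },
    branch_rate = {
      nb <- length(st$br$rates)
      if (st$br$model == "tk02") {
        nr <- st$br$node_rates
        v <- sample(length(nr), 1)
        f <- exp(scale * 0.5 * (stats::runif(1) - 0.5))
        nr[v] <- nr[v] * f
        st$br$node_rates <- nr
        e <- st$tree$phy$edge
        st$br$rates <- (nr[e[, 1]] + nr[e[, 2]]) / 2
        lh <- log(f)
      } else {
        b <- sample(nb, 1)
        f <- exp(scale * 0.5 * (stats::runif(1) - 0.5))
        st$br$rates[b] <- st$br$rates[b] * f
        lh <- log(f)
      }
    },
    nni = {
      res <- nni_move(st, ntip)
      if (is.null(res)) return(NULL)
      st <- res
    }
  )
  list(state = st, log_hastings = lh, needs_lik = needs_lik)
}

reflect01 <- function(x) {
  x <- x %% 2
  if (x > 1) 2 - x else x
}

# Rooted NNI: swap a child of an internal node w with w's sibling, when the
# result respects age ordering. Sampled-ancestor tips are never moved.
nni_move <- function(st, ntip) {
  phy <- st$tree$phy
  e <- phy$edge
  cand <- which(e[, 2] > ntip)  # internal edges (v -> w)
  if (!length(cand)) return(NULL)
  ei <- if (length(cand) == 1) cand else sample(cand, 1)
  v <- e[ei, 1]; w <- e[ei, 2]
  wkids <- e[e[, 1] == w, 2]
  y <- setdiff(e[e[, 1] == v, 2], w)  # sibling of w
  x <- if (length(wkids) == 1) wkids else sample(wkids, 1)
  is_sa <- function(n) n <= ntip && st$tree$sampled_ancestor[n]
  if (is_sa(x) || is_sa(y)) return(NULL)
  if (st$tree$ages[w] <= st$tree$ages[y]) return(NULL)
  e[e[, 1] == w & e[, 2] == x, 1] <- v
  e[e[, 1] == v & e[, 2] == y, 1] <- w
  st$tree$phy$edge <- e
  st
}
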