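#' Extract one character as tip state masks
#'
#' @param cmat A [char_matrix].
#' @param char Character column index.
#' @return Named integer vector of state bitmasks (full set = missing).
#' @export
extract_char <- function(cmat, char) {
  stats::setNames(cmat$masks[, char], cmat$taxa)
}

ctmc_npar <- function(model, k) {
  switch(model, ER = 1L, SYM = as.integer(k * (k - 1) / 2),
         ARD = as.integer(k * (k - 1)))
}

ctmc_build_q <- function(model, k, rates) {
  Q <- matrix(0, k, k)
  off <- which(row(Q) != col(Q))
  if (model == "ER") {
    Q[off] <- rates[1]
  } else if (model == "SYM") {
    idx <- 0L
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      idx <- idx + 1L
      Q[i, j] <- Q[j, i] <- rates[idx]
    }
  } else {
    idx <- 0L
    for (i in 1:k) for (j in 1:k) {
      if (i != j) { idx <- idx + 1L; Q[i, j] <- rates[idx] }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

ctmc_stationary <- function(Q) {
  k <- nrow(Q)
  ev <- eigen(t(Q))
  v <- abs(Re(ev$vectors[, which.min(abs(Re(ev$values)))]))
  v / sum(v)
}

# Down pass for a general CTMC on a dated tree: per-node partials (with
# scaling) and per-edge propagators.
ctmc_down <- function(tree, masks, Q) {
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  k <- nrow(Q)
  D <- matrix(1, nn, k)
  for (t in seq_len(ntip)) {
    D[t, ] <- as.numeric(bitwAnd(masks[phy$tip.label[t]],
                                 bitwShiftL(1L, 0:(k - 1L))) != 0L)
  }
  logsc <- numeric(nn)
  dur <- branch_durations(tree)
  po <- ape::postorder(phy)
  e <- phy$edge
  props <- vector("list", nrow(e))
  up <- matrix(1, nn, k)
  for (ei in po) {
    p <- e[ei, 1]; ch <- e[ei, 2]
    P <- ape::matexpo(Q * dur[ei])
    props[[ei]] <- P
    vec <- as.vector(P %*% D[ch, ])
    mx <- max(vec)
    if (mx <= 0) mx <- 1
    up[ch, ] <- vec / mx
    logsc[p] <- logsc[p] + logsc[ch] + log(mx)
    D[p, ] <- D[p, ] * up[ch, ]
  }
  list(D = D, logsc = logsc, props = props, up = up)
}

ctmc_loglik <- function(tree, masks, Q, pi) {
  dn <- ctmc_down(tree, masks, Q)
  root <- ape::Ntip(tree$phy) + 1L
  L <- sum(pi * dn$D[root, ])
  if (L <= 0) -Inf else log(L) + dn$logsc[root]
}

#' Fit a CTMC to one discrete character on a dated tree
#'
#' Maximum-likelihood rate matrix under the equal-rates (ER), symmetric
#' (SYM) or all-rates-different (ARD) constraint classes;
#' `AIC = 2p - 2 lnL`.
#'
#' @param tree A [time_tree].
#' @param states Named bitmask vector (see [extract_char]) or named
#'   integer 0-based states with `NA` for missing.
#' @param model `"ER"`, `"SYM"` or `"ARD"`.
#' @param k State count; inferred from the data when `NULL`.
#' @param root_prior `"stationary"` of the fitted matrix or `"uniform"`.
#' @return A `ctmc_fit`: `Q`, `loglik`, `aic`, `npar`, `pi`, `model`,
#'   `boundary` flag (rate driven to ~0 for a constant character).
#' @export
fit_ctmc <- function(tree, states, model = c("ER", "SYM", "ARD"), k = NULL,
                     root_prior = c("stationary", "uniform")) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  masks <- normalize_states(states, k)
  k <- attr(masks, "k")
  if (attr(masks, "n_observed") < 2) {
    stop("character needs >= 2 observed states for a CTMC fit")
  }
  np <- ctmc_npar(model, k)
  obj <- function(logr) {
    Q <- ctmc_build_q(model, k, exp(logr))
    pi <- if (root_prior == "uniform") rep(1 / k, k) else ctmc_stationary(Q)
    ll <- ctmc_loglik(tree, masks, Q, pi)
    if (!is.finite(ll)) 1e10 else -ll
  }
  if (np == 1L) {
    op <- stats::optimize(obj, c(-14, 6))
    par <- op$minimum; val <- op$objective
  } else {
    op <- stats::optim(rep(log(0.1), np), obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
    par <- op$par; val <- op$value
  }
  Q <- ctmc_build_q(model, k, exp(par))
  pi <- if (root_prior == "uniform") rep(1 / k, k) else ctmc_stationary(Q)
  structure(list(Q = Q, loglik = -val, npar = np, aic = 2 * np + 2 * val,
                 pi = pi, model = model, k = k,
                 boundary = any(exp(par) < 1e-5), masks = masks),
            class = "ctmc_fit")
}

# Accepts either plain 0-based states (with NA for missing) or bitmasks as
# produced by extract_char(). Masks never contain 0 and plain state vectors
# always do once more than one state is observed, so 0/NA presence decides.
normalize_states <- function(states, k = NULL, encoding = "auto") {
  if (is.null(names(states))) stop("states must be named by taxon")
  x <- states
  if (encoding == "auto") {
    encoding <- if (any(is.na(x)) || any(x == 0, na.rm = TRUE)) {
      "state"
    } else "mask"
  }
  if (encoding == "state") {
    kk <- if (is.null(k)) as.integer(max(x, na.rm = TRUE)) + 1L else k
    kk <- max(kk, 2L)
    full <- bitwShiftL(1L, kk) - 1L
    m <- ifelse(is.na(x), full, bitwShiftL(1L, as.integer(x)))
  } else {
    kk <- if (is.null(k)) {
      as.integer(max(floor(log2(as.numeric(x))))) + 1L
    } else k
    kk <- max(kk, 2L)
    full <- bitwShiftL(1L, kk) - 1L
    m <- bitwAnd(as.integer(x), full)
  }
  m <- stats::setNames(as.integer(m), names(states))
  obs <- unique(unlist(lapply(m[m != full], mask_to_states, k = kk)))
  attr(m, "k") <- as.integer(kk)
  attr(m, "n_observed") <- length(obs)
  m
}

#' @export
print.ctmc_fit <- function(x, ...) {
  cat(sprintf("ctmc_fit: %s, k = %d, lnL = %.4f, AIC = %.4f%s\n", x$model,
              x$k, x$loglik, x$aic,
              if (x$boundary) " (rate at zero boundary)" else ""))
  invisible(x)
}

#' @export
tidy.ctmc_fit <- function(x, ...) {
  k <- x$k
  idx <- which(row(x$Q) != col(x$Q), arr.ind = TRUE)
  tibble::tibble(from = idx[, 1] - 1L, to = idx[, 2] - 1L,
                 rate = x$Q[idx])
}

#' @export
glance.ctmc_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik, npar = x$npar,
                 AIC = x$aic, boundary = x$boundary)
}

#' Compare ER/SYM/ARD fits by AIC
#'
#' The best (lowest-AIC) model is selected; equal AICs favour the simpler
#' model. A SYM fit that fails or lands on a non-finite likelihood falls
#' back to ER (logged via a message), mirroring common practice when the
#' symmetric model misbehaves on sparse characters.
#'
#' @inheritParams fit_ctmc
#' @param models Candidate model set.
#' @return List: `table` (tibble of model, lnL, npar, AIC), `best` (a
#'   `ctmc_fit`).
#' @export
select_ctmc <- function(tree, states, models = c("ER", "SYM", "ARD"),
                        k = NULL, root_prior = "stationary") {
  fits <- list()
  for (m in models) {
    f <- try(fit_ctmc(tree, states, m, k, root_prior), silent = TRUE)
    if (inherits(f, "try-error") || !is.finite(f$loglik)) {
      if (m == "SYM") message("SYM fit misbehaved; falling back to ER")
      next
    }
    fits[[m]] <- f
  }
  if (!length(fits)) stop("no model could be fitted")
  tab <- dplyr::bind_rows(lapply(fits, glance))
  complexity <- c(ER = 1, SYM = 2, ARD = 3)
  ord <- order(tab$AIC, complexity[tab$model])
  tab <- tab[ord, ]
  list(table = tab, best = fits[[tab$model[1]]])
}

#' Marginal ancestral-state posteriors and threshold calls
#'
#' Up-down pruning pass giving each internal node's marginal state
#' probabilities under the fitted CTMC; `call_states` reports the state
#' whose probability strictly exceeds the threshold, else `"uncertain"`.
#'
#' @param tree A [time_tree].
#' @param fit A `ctmc_fit`.
#' @return Matrix of node-state probabilities (rows = nodes, including
#'   tips).
#' @export
node_state_posteriors <- function(tree, fit) {
  masks <- fit$masks
  Q <- fit$Q
  dn <- ctmc_down(tree, masks, Q)
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  k <- nrow(Q)
  U <- matrix(0, nn, k)
  U[ntip + 1L, ] <- fit$pi
  e <- phy$edge
  for (ei in rev(ape::postorder(phy))) {
    v <- e[ei, 1]; ch <- e[ei, 2]
    kids <- e[e[, 1] == v, 2]
    sibs <- setdiff(kids, ch)
    out <- U[v, ]
    for (sb in sibs) out <- out * dn$up[sb, ]
    U[ch, ] <- as.vector(out %*% dn$props[[ei]])
    if (max(U[ch, ]) > 0) U[ch, ] <- U[ch, ] / max(U[ch, ])
  }
  post <- U * dn$D
  sw <- rowSums(post)
  sw[sw <= 0] <- 1
  post / sw
}

#' @rdname node_state_posteriors
#' @param posteriors Matrix from `node_state_posteriors`.
#' @param threshold Call threshold (strictly-above rule).
#' @return Tibble: node, call (state as character, or "uncertain"),
#'   probability of the argmax state.
#' @export
call_states <- function(posteriors, threshold = 0.5) {
  purrr::map_dfr(seq_len(nrow(posteriors)), function(v) {
    p <- posteriors[v, ]
    b <- which.max(p)
    tibble::tibble(
      node = v,
      call = if (p[b] > threshold) as.character(b - 1L) else "uncertain",
      probability = p[b]
    )
  })
}

#' Sample stochastic character histories (SIMMAP)
#'
#' Backward-samples node states from their conditional distributions, then
#' fills each branch with an endpoint-conditioned CTMC path by
#' uniformization. Dwell times on each branch sum to the branch duration.
#'
#' @param tree A [time_tree].
#' @param fit A `ctmc_fit`.
#' @param n Number of histories.
#' @param seed Integer seed.
#' @param max_jumps Cap on uniformization jumps per branch.
#' @return List with `node_states` (n x nodes matrix of sampled 0-based
#'   states) and `histories` (list of per-branch segment tibbles: edge,
#'   state, dwell).
#' @export
sample_history <- function(tree, fit, n = 100, seed = 1, max_jumps = 1000) {
  set.seed(seed)
  Q <- fit$Q
  k <- nrow(Q)
  dn <- ctmc_down(tree, fit$masks, Q)
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  e <- phy$edge
  dur <- branch_durations(tree)
  preord <- rev(ape::postorder(phy))
  root <- ntip + 1L
  node_states <- matrix(NA_integer_, n, nn)
  histories <- vector("list", n)
  mu <- max(-diag(Q))
  R <- if (mu > 0) diag(k) + Q / mu else diag(k)
  for (h in seq_len(n)) {
    st <- integer(nn)
    pr <- fit$pi * dn$D[root, ]
    st[root] <- sample.int(k, 1, prob = pr)
    segs <- vector("list", nrow(e))
    for (ei in preord) {
      v <- e[ei, 1]; ch <- e[ei, 2]
      w <- dn$props[[ei]][st[v], ] * dn$D[ch, ]
      st[ch] <- sample.int(k, 1, prob = w)
      segs[[ei]] <- uniformization_path(st[v], st[ch], dur[ei], Q, R, mu,
                                        dn$props[[ei]], ei, max_jumps)
    }
    node_states[h, ] <- st - 1L
    histories[[h]] <- dplyr::bind_rows(segs)
  }
  list(node_states = node_states, histories = histories)
}

# Endpoint-conditioned path on one branch via uniformization. Returns a
# tibble of (edge, state, dwell) segments ordered from parent to child.
uniformization_path <- function(a, b, t, Q, R, mu, P, edge_id, max_jumps) {
  k <- nrow(Q)
  if (t <= 0 || mu == 0) {
    if (a != b && t <= 0) stop(sprintf("branch %d: impossible endpoints",
                                       edge_id))
    return(tibble::tibble(edge = edge_id, state = a - 1L, dwell = t))
  }
  p_ab <- P[a, b]
  if (p_ab <= 0) stop(sprintf("branch %d: endpoint pair has zero probability",
                              edge_id))
  # sample number of uniformized jumps
  u <- stats::runif(1) * p_ab
  Rpow <- list(diag(k))
  cum <- stats::dpois(0, mu * t) * (a == b)
  nj <- 0L
  while (cum < u) {
    nj <- nj + 1L
    if (nj > max_jumps) stop(sprintf("branch %d: jump cap exceeded", edge_id))
    Rpow[[nj + 1L]] <- Rpow[[nj]] %*% R
    cum <- cum + stats::dpois(nj, mu * t) * Rpow[[nj + 1L]][a, b]
  }
  if (nj == 0L) {
    return(tibble::tibble(edge = edge_id, state = a - 1L, dwell = t))
  }
  # jump-chain states conditioned on endpoints
  sts <- integer(nj + 1L)
  sts[1] <- a; sts[nj + 1L] <- b
  if (nj > 1L) {
    for (i in 2:nj) {
      w <- R[sts[i - 1L], ] * Rpow[[nj + 1L - i + 1L]][, b]
      sts[i] <- sample.int(k, 1, prob = w)
    }
  }
  times <- sort(stats::runif(nj)) * t
  # collapse virtual jumps into dwell segments
  state_seq <- integer(0); dwell <- numeric(0)
  cur <- sts[1]; start <- 0
  for (i in seq_len(nj)) {
    if (sts[i + 1L] != cur) {
      state_seq <- c(state_seq, cur); dwell <- c(dwell, times[i] - start)
      cur <- sts[i + 1L]; start <- times[i]
    }
  }
  state_seq <- c(state_seq, cur); dwell <- c(dwell, t - start)
  tibble::tibble(edge = edge_id, state = state_seq - 1L, dwell = dwell)
}
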