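# Shared fixture builders. Everything is generated in code; nothing binary.

quartet_tree <- function() {
  time_tree(ape::read.tree(text = "((A:1,B:2):1,(C:1.5,D:0.5):1.5);"))
}

# Small fossil-bearing FBD tree with calibrations, deterministic by seed.
fossil_tree <- function(seed = 11, root_age = 12, min_tips = 10,
                        max_tips = 30) {
  p <- fbd_params(0.2, 0.5, 0.5, 1)
  simulate_fbd_tree(p, root_age, seed = seed, min_tips = min_tips,
                    max_tips = max_tips)$tree
}

# One-column character matrix from named 0-based tip states.
one_char_matrix <- function(states, k = max(states) + 1L) {
  masks <- matrix(bitwShiftL(1L, as.integer(states)), ncol = 1)
  char_matrix(masks, names(states), as.integer(k))
}

# Brute-force Mk likelihood by enumeration over internal-node states,
# independent of the pruning engine (uses mk_transition_matrix only).
enumerate_mk_loglik <- function(tree, tip_states, k,
                                eff_len = branch_durations(tree)) {
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  e <- phy$edge
  P <- lapply(seq_len(nrow(e)), function(i) {
    mk_transition_matrix(k, eff_len[i])
  })
  nint <- phy$Nnode
  grid <- as.matrix(expand.grid(rep(list(1:k), nint)))
  tot <- 0
  tipv <- tip_states[phy$tip.label] + 1L
  for (g in seq_len(nrow(grid))) {
    st <- c(tipv, grid[g, ])
    pr <- 1 / k
    for (i in seq_len(nrow(e))) pr <- pr * P[[i]][st[e[i, 1]], st[e[i, 2]]]
    tot <- tot + pr
  }
  log(tot)
}

# Random dated tree with n tips (durations scaled to a given depth).
random_time_tree <- function(n, depth = 5) {
  phy <- ape::rcoal(n)
  phy$edge.length <- phy$edge.length *
    (depth / max(ape::node.depth.edgelength(phy)))
  time_tree(phy)
}

# Marginal-likelihood toy: n normal observations, known sd 1, normal prior
# on the mean. Analytic log marginal.
normal_toy <- function(n = 20, mu = 0.5, prior_sd = 2, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n, mu, 1)
  t2 <- prior_sd^2
  analytic <- -n / 2 * log(2 * pi) - 0.5 * log(1 + n * t2) -
    0.5 * (sum(x^2) - sum(x)^2 / (n + 1 / t2))
  list(
    x = x,
    log_lik = function(th) sum(stats::dnorm(x, th, 1, log = TRUE)),
    log_prior = function(th) stats::dnorm(th, 0, prior_sd, log = TRUE),
    propose = function(th) list(theta = th + stats::rnorm(1, 0, 1.5),
                                log_hastings = 0),
    analytic = analytic
  )
}

table1_mlnl <- function() {
  tibble::tibble(
    model = c("IGR", "ILN", "WN", "TK02"),
    mlnl = c(-7329.76, -7330.05, -7396.93, -7234.59)
  )
}
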