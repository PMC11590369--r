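test_that("Mk transition matrix matches its closed form and limits", {
  expect_equal(mk_transition_matrix(2, 0), diag(2))
  expect_equal(mk_transition_matrix(4, 1e6),
               matrix(0.25, 4, 4), tolerance = 1e-12)
  # independent oracle: matrix exponential of the normalized 2-state
  # rate matrix
  Q <- matrix(c(-1, 1, 1, -1), 2) / 1  # unit expected rate
  expect_equal(mk_transition_matrix(2, 0.5), ape::matexpo(Q * 0.5),
               tolerance = 1e-12)
  expect_equal(mk_transition_matrix(2, 0.5)[1, 1], 0.68394, tolerance = 1e-5)
  for (k in 2:5) {
    P <- mk_transition_matrix(k, 0.37)
    expect_equal(rowSums(P), rep(1, k))
    Qk <- matrix(1 / (k - 1), k, k); diag(Qk) <- -1
    expect_equal(P, ape::matexpo(Qk * 0.37), tolerance = 1e-12)
  }
  expect_error(mk_transition_matrix(3, -0.1), ">= 0")
})

test_that("discrete gamma categories have unit mean and match quadrature", {
  expect_equal(discrete_gamma_rates(0.7, 1), 1)
  expect_equal(discrete_gamma_rates(1e5, 4), rep(1, 4), tolerance = 1e-2)
  for (alpha in c(0.5, 1, 2)) {
    r <- discrete_gamma_rates(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    # quadrature oracle: conditional means of the quartile bins
    q <- stats::qgamma(seq(0, 1, 0.25), alpha, alpha)
    oracle <- vapply(1:4, function(i) {
      4 * stats::integrate(function(x) x * stats::dgamma(x, alpha, alpha),
                           q[i], min(q[i + 1], 1e3))$value
    }, numeric(1))
    expect_equal(r, oracle / mean(oracle), tolerance = 1e-6)
  }
})

test_that("pruning equals brute-force enumeration and handles degenerate data", {
  tt <- quartet_tree()
  # all effective lengths zero, identical states -> root frequency only
  cm0 <- one_char_matrix(c(A = 0, B = 0, C = 0, D = 0), k = 3)
  expect_equal(mk_loglik(cm0, tt, effective_lengths = rep(0, 6)), log(1 / 3))
  # all-missing character marginalizes to 1
  cmq <- char_matrix(matrix(3L, 4, 1), c("A", "B", "C", "D"), 2L)
  expect_equal(mk_loglik(cmq, tt), 0)

  states <- c(A = 0, B = 1, C = 2, D = 0)
  cm <- one_char_matrix(states, k = 3)
  expect_equal(mk_loglik(cm, tt), enumerate_mk_loglik(tt, states, 3),
               tolerance = 1e-12)
  expect_error(mk_loglik(cm, time_tree(ape::read.tree(text = "((A:1,X:1):1,C:2);"))),
               "not in character matrix")
})

test_that("pruning matches enumeration on random trees and is order-invariant", {
  set.seed(7)
  for (case in 1:25) {
    n <- sample(4:6, 1)
    k <- sample(2:4, 1)
    tt <- random_time_tree(n, depth = stats::runif(1, 0.5, 4))
    states <- stats::setNames(sample(0:(k - 1), n, replace = TRUE),
                              tt$phy$tip.label)
    cm <- one_char_matrix(states, k = k)
    expect_equal(mk_loglik(cm, tt), enumerate_mk_loglik(tt, states, k),
                 tolerance = 1e-12)
  }
  # taxon order invariance
  tt <- fossil_tree(seed = 3, min_tips = 6, max_tips = 12)
  sc <- simulate_characters(tt, clock_config("strict", base_rate = 0.3),
                            n_chars = 15, seed = 9)
  perm <- sample(nrow(sc$matrix$masks))
  cm_perm <- char_matrix(sc$matrix$masks[perm, , drop = FALSE],
                         sc$matrix$taxa[perm], sc$matrix$state_count,
                         coding = sc$matrix$coding)
  expect_equal(mk_loglik(sc$matrix, tt), mk_loglik(cm_perm, tt),
               tolerance = 1e-10)
})

test_that("gamma mixture converges to the single-rate likelihood as shape grows", {
  tt <- quartet_tree()
  cm <- one_char_matrix(c(A = 0, B = 1, C = 1, D = 0), k = 2)
  ll_single <- mk_loglik(cm, tt, gamma_shape = Inf)
  ll_big_alpha <- mk_loglik(cm, tt, gamma_shape = 1e6, n_categories = 4)
  expect_equal(ll_big_alpha, ll_single, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(
    mk_loglik(cm, tt, gamma_shape = 0.3, n_categories = 4), ll_single)))
})

test_that("Mkv ascertainment correction matches 2-taxon closed-form algebra", {
  phy <- ape::read.tree(text = "(A:1,B:1);")
  tt <- time_tree(phy)
  masks <- matrix(c(1L, 2L), 2, 1)  # states 0, 1
  cmv <- char_matrix(masks, c("A", "B"), 2L, coding = "variable")
  ll_corr <- mk_loglik(cmv, tt)
  # closed form: L_raw / (1 - 2 L_same) with L_same the both-tips-equal
  # likelihood computed from the transition matrix directly
  P <- mk_transition_matrix(2, 1)
  l_raw <- 0.5 * (P[1, 1] * P[1, 2] + P[2, 1] * P[2, 2])
  l_same <- 0.5 * (P[1, 1]^2 + P[1, 2]^2)
  expect_equal(ll_corr, log(l_raw / (1 - 2 * l_same)), tolerance = 1e-12)

  # coding = all leaves the likelihood untouched
  cma <- char_matrix(masks, c("A", "B"), 2L, coding = "all")
  expect_equal(mk_loglik(cma, tt), log(l_raw), tolerance = 1e-12)

  # corrected log-likelihood is always below the raw one
  tt2 <- fossil_tree(seed = 21, min_tips = 8, max_tips = 15)
  sc <- simulate_characters(tt2, clock_config("strict", base_rate = 0.3),
                            n_chars = 50, seed = 4)
  # conditioning on variability divides each likelihood by a denominator
  # below 1, so the corrected log-likelihood always exceeds the raw one
  raw <- mk_loglik(sc$matrix, tt2, correct = FALSE, by_character = TRUE)
  corr <- mk_loglik(sc$matrix, tt2, correct = TRUE, by_character = TRUE)
  expect_true(all(corr > raw))
})
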