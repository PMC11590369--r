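test_that("CTMC fits have correct parameter counts and AIC arithmetic", {
  tt <- quartet_tree()
  st <- c(A = 0, B = 0, C = 1, D = 1)
  fits <- lapply(c("ER", "SYM", "ARD"), function(m) fit_ctmc(tt, st, m))
  expect_equal(vapply(fits, `[[`, integer(1), "npar"), c(1L, 1L, 2L))
  k3 <- c(A = 0, B = 1, C = 2, D = 1)
  fits3 <- lapply(c("ER", "SYM", "ARD"), function(m) fit_ctmc(tt, k3, m))
  expect_equal(vapply(fits3, `[[`, integer(1), "npar"), c(1L, 3L, 6L))
  for (f in c(fits, fits3)) {
    expect_equal(rowSums(f$Q), rep(0, f$k), tolerance = 1e-12)
    expect_true(all(f$Q[row(f$Q) != col(f$Q)] >= 0))
    expect_equal(f$aic, 2 * f$npar - 2 * f$loglik)
  }
  # likelihood non-decreasing along the nesting ER <= SYM <= ARD
  lls <- vapply(fits3, `[[`, numeric(1), "loglik")
  expect_true(all(diff(lls) > -1e-6))
})

test_that("ER rate estimate matches a grid-search oracle", {
  tt <- time_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  st <- c(A = 0, B = 0, C = 1)
  f <- fit_ctmc(tt, st, "ER", root_prior = "uniform")
  grid <- exp(seq(-8, 2, length.out = 4000))
  e <- tt$phy$edge
  dur <- branch_durations(tt)
  gl <- vapply(grid, function(r) {
    Q <- matrix(c(-r, r, r, -r), 2)
    P <- lapply(dur, function(t) ape::matexpo(Q * t))
    tot <- 0
    tip <- st + 1
    for (rt in 1:2) for (v in 1:2) {
      tot <- tot + 0.5 * P[[1]][rt, v] * P[[2]][v, tip["A"]] *
        P[[3]][v, tip["B"]] * P[[4]][rt, tip["C"]]
    }
    log(tot)
  }, numeric(1))
  expect_equal(f$loglik, max(gl), tolerance = 1e-6)
  expect_equal(f$Q[1, 2], grid[which.max(gl)], tolerance = 0.01)
})

test_that("AIC model choice prefers simpler models on ties and flags constant data", {
  tt <- quartet_tree()
  st <- c(A = 0, B = 0, C = 1, D = 1)
  sel <- select_ctmc(tt, st)
  # binary SYM equals ER; ER must win the tie and ARD pays its penalty
  expect_equal(sel$table$model[1], "ER")
  expect_gt(sel$table$AIC[sel$table$model == "ARD"],
            sel$table$AIC[sel$table$model == "ER"])
  expect_error(fit_ctmc(tt, c(A = 0, B = 0, C = 0, D = 0)), ">= 2 observed")
})

test_that("node posteriors equal brute-force enumeration on three taxa", {
  tt <- time_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  st <- c(A = 0, B = 1, C = 1)
  f <- fit_ctmc(tt, st, "ER", root_prior = "uniform")
  post <- node_state_posteriors(tt, f)
  # enumeration over (root, internal) states with the fitted Q
  P1 <- ape::matexpo(f$Q * 1)
  P2 <- ape::matexpo(f$Q * 2)
  tip <- st + 1
  joint <- matrix(0, 2, 2)  # root state x internal state
  for (r in 1:2) for (v in 1:2) {
    joint[r, v] <- 0.5 * P1[r, v] * P1[v, tip["A"]] * P1[v, tip["B"]] *
      P2[r, tip["C"]]
  }
  expect_equal(post[4, ], rowSums(joint) / sum(joint), tolerance = 1e-9)
  expect_equal(post[5, ], colSums(joint) / sum(joint), tolerance = 1e-9)

  # threshold call rule is strictly-above
  cp <- call_states(rbind(c(0.5, 0.5), c(0.51, 0.49)), threshold = 0.5)
  expect_equal(cp$call, c("uncertain", "0"))
})

test_that("near-zero rates drive the root posterior to the shared tip state", {
  tt <- quartet_tree()
  st <- c(A = 1, B = 1, C = 1, D = 1)
  # constant character: fit against a second observed state being absent is
  # rejected, so force a tiny-rate matrix directly
  f <- fit_ctmc(tt, c(A = 1, B = 1, C = 1, D = 0), "ER")
  masks <- morphoclock:::normalize_states(st, encoding = "state")
  f$masks <- masks
  f$Q <- matrix(c(-1e-9, 1e-9, 1e-9, -1e-9), 2)
  post <- node_state_posteriors(tt, f)
  root <- ape::Ntip(tt$phy) + 1
  expect_gt(post[root, 2], 0.999)
  expect_equal(call_states(post)$call[root], "1")
})

test_that("sampled histories agree with marginal posteriors and dwell-time accounting", {
  tt <- time_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  st <- c(A = 0, B = 1, C = 1)
  f <- fit_ctmc(tt, st, "ER", root_prior = "uniform")
  post <- node_state_posteriors(tt, f)
  h <- sample_history(tt, f, n = 4000, seed = 2)
  freq <- colMeans(h$node_states == 0)
  expect_lt(max(abs(freq[4:5] - post[4:5, 1])), 0.03)
  # dwell times on each branch sum to the branch duration
  segs <- h$histories[[1]]
  dur <- branch_durations(tt)
  for (ei in unique(segs$edge)) {
    expect_equal(sum(segs$dwell[segs$edge == ei]), dur[ei],
                 tolerance = 1e-10)
  }
  # zero rates, uniform tip state: no transitions anywhere
  f0 <- f
  f0$Q <- matrix(c(-1e-12, 1e-12, 1e-12, -1e-12), 2)
  f0$masks <- morphoclock:::normalize_states(c(A = 1, B = 1, C = 1),
                                             encoding = "state")
  h0 <- sample_history(tt, f0, n = 20, seed = 3)
  expect_true(all(vapply(h0$histories, nrow, integer(1)) == 4))
})

test_that("per-branch substitution counts match a discretized rejection oracle", {
  # one branch, endpoints 0 -> 1, duration 2, symmetric rate 0.4
  r <- 0.4; tspan <- 2
  Q <- matrix(c(-r, r, r, -r), 2)
  set.seed(9)
  # oracle: fine discrete-time chain conditioned on the endpoints
  nstep <- 2000
  Pstep <- ape::matexpo(Q * (tspan / nstep))
  count <- c(); tries <- 0
  while (length(count) < 400 && tries < 200000) {
    tries <- tries + 1
    s <- 1; n <- 0
    for (i in seq_len(nstep)) {
      s2 <- sample.int(2, 1, prob = Pstep[s, ])
      if (s2 != s) n <- n + 1
      s <- s2
    }
    if (s == 2) count <- c(count, n)
  }
  tt1 <- time_tree(ape::read.tree(text = "(A:2,B:0.001);"))
  f <- fit_ctmc(tt1, c(A = 1, B = 0), "ER")
  f$Q <- Q
  f$masks <- morphoclock:::normalize_states(c(A = 1, B = 0))
  h <- sample_history(tt1, f, n = 2000, seed = 4)
  edge_a <- which(tt1$phy$edge[, 2] == 1)
  jumps <- vapply(h$histories, function(seg) {
    sum(seg$edge == edge_a) - 1L
  }, integer(1))
  expect_equal(mean(jumps), mean(count), tolerance = 0.12)
})
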