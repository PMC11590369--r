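test_that("range state spaces enumerate subsets deterministically", {
  expect_equal(length(enumerate_ranges(2, 2)$masks), 4L)   # {}, A, B, AB
  expect_equal(length(enumerate_ranges(13, 1)$masks), 14L)
  expect_equal(length(enumerate_ranges(13, 3)$masks), 1L + 13L + 78L + 286L)
  sp <- enumerate_ranges(3, 2)
  expect_equal(sp$masks, c(0L, 1L, 2L, 4L, 3L, 5L, 6L))  # size then lex
  expect_error(enumerate_ranges(3, 4), "max_size")
})

test_that("the anagenetic generator encodes dispersal, extinction and connectivity", {
  sp <- enumerate_ranges(2, 2)
  Q <- dec_rate_matrix(sp, d = 0.3, e = 0.1)
  iA <- sp$index["1"]; iAB <- sp$index["3"]; iE <- sp$index["0"]
  expect_equal(Q[iA, iAB], 0.3)
  expect_equal(Q[iA, iE], 0.1)
  expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12)
  expect_equal(Q[iE, ], rep(0, 4))  # empty range is absorbing

  # all-zero connectivity: no expansion transitions anywhere
  Q0 <- dec_rate_matrix(sp, d = 0.3, e = 0.1, matrix(0, 2, 2))
  expect_equal(unname(Q0[-iAB, iAB]), rep(0, 3))  # no route into {A,B}

  # d = e = 0: zero generator, identity propagator
  Qz <- dec_rate_matrix(sp, 0, 0)
  expect_equal(Qz, matrix(0, 4, 4))
  expect_equal(ape::matexpo(Qz * 5), diag(4))

  # every propagator is row-stochastic
  sp3 <- enumerate_ranges(4, 3)
  Q3 <- dec_rate_matrix(sp3, 0.2, 0.07)
  P <- ape::matexpo(Q3 * 3.7)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-10)
})

test_that("DEC likelihood handles the no-event limit and matches a discretized oracle", {
  phy <- ape::read.tree(text = "(A:2,B:2);")
  tt <- time_tree(phy)
  m <- dec_model(areas = c("X", "Y"), d = 0, e = 0, max_range_size = 2)
  rt <- range_table(c("A", "B"), rbind(c(1, 0), c(1, 0)), c("X", "Y"))
  # no events possible: likelihood is the root prior mass on {X}
  expect_equal(dec_log_likelihood(tt, rt, m), log(1 / 3), tolerance = 1e-12)

  # 3-taxon toy against an independently built fine-discretization oracle
  phy3 <- ape::read.tree(text = "((A:1,B:1.5):1,C:2);")
  tt3 <- time_tree(phy3)
  m3 <- dec_model(areas = c("X", "Y"), d = 0.3, e = 0.1, max_range_size = 2)
  rt3 <- range_table(c("A", "B", "C"), rbind(c(1, 0), c(1, 1), c(0, 1)),
                     c("X", "Y"))
  ll <- dec_log_likelihood(tt3, rt3, m3)
  # oracle: states {}, X, Y, XY; generator written from the model rules,
  # propagated by squaring an Euler step; cladogenesis enumerated by hand
  states <- list(integer(0), 1L, 2L, c(1L, 2L))
  Qh <- matrix(0, 4, 4)
  for (i in 2:4) for (j in 1:4) {
    si <- states[[i]]; sj <- states[[j]]
    if (length(sj) == length(si) + 1 && all(si %in% sj)) {
      Qh[i, j] <- 0.3 * length(si)
    }
    if (length(sj) == length(si) - 1 && all(sj %in% si)) Qh[i, j] <- 0.1
  }
  diag(Qh) <- -rowSums(Qh)
  prop <- function(t, n = 2^18) {
    M <- diag(4) + Qh * (t / n)
    R <- diag(4)
    while (n > 0) {
      if (n %% 2 == 1) R <- R %*% M
      M <- M %*% M
      n <- n %/% 2
    }
    R
  }
  P1 <- prop(1); P15 <- prop(1.5); P2 <- prop(2)
  clado <- list(NULL, cbind(2, 2, 1), cbind(3, 3, 1),
                cbind(c(2, 4, 3, 4, 2, 3), c(4, 2, 4, 3, 3, 2),
                      rep(1 / 6, 6)))
  tipidx <- c(A = 2, B = 4, C = 3)
  pi <- c(0, 1, 1, 1) / 3
  tot <- 0
  for (r5 in 1:4) {
    ev5 <- clado[[r5]]
    if (is.null(ev5)) next
    for (q in seq_len(nrow(ev5))) {
      inner <- 0
      for (r6 in 1:4) {
        ev6 <- clado[[r6]]
        if (is.null(ev6)) next
        sub <- 0
        for (q2 in seq_len(nrow(ev6))) {
          sub <- sub + ev6[q2, 3] * P1[ev6[q2, 1], tipidx["A"]] *
            P15[ev6[q2, 2], tipidx["B"]]
        }
        inner <- inner + P1[ev5[q, 1], r6] * sub
      }
      tot <- tot + pi[r5] * ev5[q, 3] * inner * P2[ev5[q, 2], tipidx["C"]]
    }
  }
  expect_equal(ll, log(tot), tolerance = 1e-6)
  expect_error(dec_log_likelihood(tt3, rt3,
                                  dec_model(c("X", "Y"), max_range_size = 1)),
               "max_range_size")
})

test_that("epoch-split propagators obey the semigroup property", {
  areas <- c("X", "Y", "Z")
  m_same <- matrix(1, 3, 3)
  # two epochs with identical connectivity: splitting a branch at the epoch
  # boundary must not change the likelihood
  cm2 <- connectivity_model(list(m_same, m_same), c(50, 1.2), c(1.2, 0),
                            areas)
  phy <- ape::read.tree(text = "((A:1,B:1.5):1,C:2);")
  tt <- time_tree(phy)
  rt <- range_table(c("A", "B", "C"), rbind(c(1, 0, 0), c(1, 1, 0),
                                            c(0, 1, 1)), areas)
  m_one <- dec_model(areas, d = 0.2, e = 0.05, max_range_size = 2)
  m_two <- dec_model(areas, d = 0.2, e = 0.05, max_range_size = 2,
                     connectivity = cm2)
  expect_equal(dec_log_likelihood(tt, rt, m_two),
               dec_log_likelihood(tt, rt, m_one), tolerance = 1e-9)

  # differing epochs change it, and the change matches composing the two
  # propagators by hand on a single 2-area branch
  mA <- matrix(1, 2, 2); mB <- matrix(0, 2, 2)
  cmd <- connectivity_model(list(mB, mA), c(50, 1), c(1, 0), c("X", "Y"))
  md <- dec_model(c("X", "Y"), d = 0.4, e = 0, max_range_size = 2,
                  connectivity = cmd)
  sp <- md$space
  Qfree <- dec_rate_matrix(sp, 0.4, 0, mA)
  Qblock <- dec_rate_matrix(sp, 0.4, 0, mB)
  P_hand <- ape::matexpo(Qblock * 1) %*% ape::matexpo(Qfree * 1)
  P_pkg <- morphoclock:::dec_branch_propagator(md, 2, 0,
                                               morphoclock:::dec_q_cache(md))
  expect_equal(P_pkg, P_hand, tolerance = 1e-10)
})

test_that("likelihood is invariant to consistent area permutation", {
  areas <- c("X", "Y", "Z")
  phy <- ape::read.tree(text = "((A:1,B:1.5):1,C:2);")
  tt <- time_tree(phy)
  pres <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 1))
  rt <- range_table(c("A", "B", "C"), pres, areas)
  m <- dec_model(areas, d = 0.25, e = 0.08, max_range_size = 2)
  perm <- c(3, 1, 2)
  rt_p <- range_table(c("A", "B", "C"), pres[, perm], areas[perm])
  m_p <- dec_model(areas[perm], d = 0.25, e = 0.08, max_range_size = 2)
  expect_equal(dec_log_likelihood(tt, rt, m),
               dec_log_likelihood(tt, rt_p, m_p), tolerance = 1e-10)
})

test_that("trivial fits recover the shared range and flag rate bounds", {
  set.seed(3)
  tt <- random_time_tree(12, depth = 8)
  pres <- matrix(0, 12, 3); pres[, 1] <- 1
  rt <- range_table(tt$phy$tip.label, pres, c("X", "Y", "Z"))
  m <- dec_model(c("X", "Y", "Z"), max_range_size = 2)
  f <- fit_dec(tt, rt, m)
  expect_true(f$at_bound)
  expect_lt(f$e, 1e-4)
  anc <- ancestral_ranges(tt, rt, f)
  best <- anc[anc$best, ]
  expect_true(all(best$range == "X"))
  expect_equal(nrow(best), tt$phy$Nnode)
})

test_that("a muroid-style fixture with fossils and epochs runs end to end", {
  areas <- muroid_areas()
  set.seed(14)
  tt <- fossil_tree(seed = 14, min_tips = 10, max_tips = 18)
  m1 <- matrix(1, 13, 13); m1[4, 3] <- m1[3, 4] <- 0
  m2 <- matrix(1, 13, 13)
  cm <- connectivity_model(list(m1, m2), c(45, 6), c(6, 0), areas)
  dm <- dec_model(areas, d = 0.08, e = 0.02, max_range_size = 2,
                  connectivity = cm)
  sr <- suppressWarnings(simulate_ranges(tt, dm, seed = 15,
                                         min_survivors = 6))
  fit <- fit_dec(sr$tree, sr$ranges, dm)
  expect_true(is.finite(fit$loglik))
  anc <- ancestral_ranges(sr$tree, sr$ranges, fit)
  expect_equal(length(unique(anc$node)), sr$tree$phy$Nnode)
  expect_true(all(anc$probability > 0 & anc$probability <= 1))
})
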