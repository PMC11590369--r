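test_that("pure-birth simulations match the Yule tip-count expectation", {
  p <- fbd_params_rates(lambda = 1, mu = 0, psi = 0, rho = 1)
  set.seed(21)
  tips <- replicate(500, {
    sub <- morphoclock:::sim_lineage(3, p)
    n_extant <- function(l) {
      switch(l$type,
        extant = 1L, dead = 0L,
        split = n_extant(l$kids[[1]]) + n_extant(l$kids[[2]])
      )
    }
    n_extant(sub)
  })
  # a single lineage run for T: E[N] = e^{lambda T}
  se <- stats::sd(tips) / sqrt(length(tips))
  expect_lt(abs(mean(tips) - exp(3)), 3 * se)
})

test_that("FBD tree simulation respects sampling switches and seeds", {
  p0 <- fbd_params(0.3, 0.4, 0, 1)   # psi = 0: no fossils at all
  sim <- simulate_fbd_tree(p0, 6, seed = 4, min_tips = 3, max_tips = 100)
  expect_equal(sum(tip_ages(sim$tree) > 0), 0)
  expect_null(sim$tree$calibrations)

  p <- fbd_params(0.3, 0.5, 0.5, 1)
  s1 <- simulate_fbd_tree(p, 8, seed = 7, min_tips = 5, max_tips = 50)
  s2 <- simulate_fbd_tree(p, 8, seed = 7, min_tips = 5, max_tips = 50)
  expect_identical(s1$tree$ages, s2$tree$ages)
  expect_identical(ape::write.tree(s1$tree$phy), ape::write.tree(s2$tree$phy))
  # truth manifest carries what a re-simulation needs
  expect_equal(s1$truth$root_age, 8)
  expect_equal(s1$truth$params$d, 0.3)
  # calibration windows bracket the true fossil ages
  cal <- s1$tree$calibrations
  if (!is.null(cal)) {
    ages <- tip_ages(s1$tree)[cal$taxon]
    expect_true(all(cal$min_age <= ages & ages <= cal$max_age))
  }
})

test_that("character simulation honours coding, degenerate input and stationarity", {
  tt <- fossil_tree(seed = 5)
  expect_error(
    simulate_characters(tt, clock_config("strict", base_rate = 0),
                        n_chars = 5),
    "positive"
  )
  zero_tree <- tt
  zero_tree$ages[] <- 0
  # all effective lengths zero: every character constant, rejection flagged
  expect_error(
    suppressWarnings(
      simulate_characters(time_tree(tt$phy, ages = rep(0, length(tt$ages))),
                          clock_config("strict", base_rate = 0.3),
                          n_chars = 3)
    ),
    "constant|zero"
  )

  # long branches: tip states approach the uniform stationary distribution
  long_phy <- ape::stree(8, "balanced")
  long_phy$edge.length <- rep(50, nrow(long_phy$edge))
  long <- time_tree(long_phy)
  sc <- simulate_characters(long, clock_config("strict", base_rate = 1),
                            n_chars = 400, state_counts = 2L,
                            state_count_probs = 1, gamma_shape = 1e6,
                            variable_only = FALSE, seed = 8)
  counts <- table(factor(as.vector(sc$matrix$masks), levels = c(1, 2)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # study-scale fixture: 166 taxa x 108 characters over 13 areas
  big <- random_time_tree(166, depth = 45)
  scb <- simulate_characters(big, clock_config("strict", base_rate = 0.4426),
                             n_chars = 108, seed = 9)
  expect_equal(dim(scb$matrix), c(166L, 108L))
  expect_true(all(scb$matrix$state_count %in% 2:5))
  expect_equal(scb$matrix$coding, "variable")
  dmb <- dec_model(muroid_areas(), d = 0.05, e = 0.01, max_range_size = 2)
  srb <- suppressWarnings(simulate_ranges(big, dmb, seed = 10,
                                          min_survivors = 120))
  expect_equal(length(attr(srb$ranges, "areas")), 13L)
  expect_true(all(rowSums(as.matrix(srb$ranges[, muroid_areas()])) >= 1))
})

test_that("range simulation follows the anagenetic process and connectivity", {
  tt <- random_time_tree(10, depth = 4)
  m0 <- dec_model(LETTERS[1:3], d = 0, e = 0, max_range_size = 3)
  sr <- simulate_ranges(tt, m0, seed = 11)
  pres <- as.matrix(sr$ranges[, LETTERS[1:3]])
  expect_equal(nrow(unique(pres)), 1L)  # all tips inherit the root range

  # two disconnected blocks: no tip range spans both
  areas <- c("A1", "A2", "B1", "B2")
  conn <- matrix(0, 4, 4)
  conn[1:2, 1:2] <- 1; conn[3:4, 3:4] <- 1
  cm <- connectivity_model(list(conn), 100, 0, areas)
  mb <- dec_model(areas, d = 0.5, e = 0.01, max_range_size = 3,
                  connectivity = cm)
  for (seed in 12:14) {
    srb <- suppressWarnings(simulate_ranges(tt, mb, seed = seed))
    pb <- as.matrix(srb$ranges[, areas])
    spans <- rowSums(pb[, 1:2, drop = FALSE]) > 0 &
      rowSums(pb[, 3:4, drop = FALSE]) > 0
    expect_false(any(spans))
  }

  # Gillespie occupancy on a single branch matches the matrix exponential
  m <- dec_model(LETTERS[1:3], d = 0.2, e = 0.15, max_range_size = 3)
  sp <- m$space
  Q <- dec_rate_matrix(sp, 0.2, 0.15)
  start <- sp$index["3"]  # {A, B}
  P <- ape::matexpo(Q * 2.5)
  set.seed(42)
  ends <- replicate(10000, morphoclock:::gillespie_branch(start, 2.5, 0, m,
                                                          sp))
  emp <- tabulate(ends, nbins = length(sp$masks)) / 10000
  expect_lt(max(abs(emp - P[start, ])), 0.02)
})

test_that("stepping stone prefers the generating relaxed clock over a strict one", {
  wins <- 0L
  n_rep <- 5L
  for (i in seq_len(n_rep)) {
    tt <- fossil_tree(seed = 30 + i, min_tips = 12, max_tips = 18)
    sc <- simulate_characters(tt, clock_config("iln", base_rate = 0.4,
                                               nu = 3),
                              n_chars = 120, seed = 40 + i)
    cfgs <- lapply(c("strict", "iln"), function(mod) {
      mcmc_config(clock = clock_config(mod, base_rate = 0.4, nu = 0.5,
                                       base_rate_prior = list(
                                         mean_log = log(0.4), sd_log = 1.5)),
                  root_cal = root_calibration(10, 16))
    })
    ml <- vapply(cfgs, function(cf) {
      stepping_stone_mk(sc$matrix, tt, cf, n_steps = 6, per_step = 1200,
                        seed = 50 + i)$mlnl
    }, numeric(1))
    if (ml[2] > ml[1]) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.8 * n_rep))
})
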