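test_that("a fixed seed reproduces the trace bit for bit", {
  tt <- fossil_tree(seed = 11)
  sc <- simulate_characters(tt, clock_config("strict", base_rate = 0.3),
                            n_chars = 20, seed = 2)
  cfg <- mcmc_config(root_cal = root_calibration(10, 16))
  r1 <- run_mcmc(sc$matrix, tt, cfg, n_iter = 600, sample_every = 10,
                 seed = 99)
  r2 <- run_mcmc(sc$matrix, tt, cfg, n_iter = 600, sample_every = 10,
                 seed = 99)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$ages, r2$ages)
  r3 <- run_mcmc(sc$matrix, tt, cfg, n_iter = 600, sample_every = 10,
                 seed = 100)
  expect_false(identical(r1$trace$lnL, r3$trace$lnL))
})

test_that("sampling the parameter priors reproduces their stated distributions", {
  # likelihood off, tree prior off: the chain must recover the hyperpriors
  tt <- fossil_tree(seed = 11)
  cfg <- mcmc_config(
    clock = clock_config("strict", base_rate = 0.4,
                         base_rate_prior = list(mean_log = log(0.4),
                                                sd_log = 1.5)),
    root_cal = root_calibration(8, 16)
  )
  r <- run_mcmc(NULL, tt, cfg, n_iter = 240000, sample_every = 120,
                seed = 4, target = "hyperprior", proposal_scale = 6)
  tr <- r$trace[-(1:200), ]
  expect_gt(suppressWarnings(stats::ks.test(tr$net_div, "pexp", 1))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(tr$turnover, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(tr$fossil_sampling, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(tr$alpha, "pexp", 1))$p.value, 0.01)
})

test_that("root and tip ages sample their calibration priors", {
  # two extant tips: the root age marginal is exactly the offset exponential
  tt2 <- time_tree(ape::read.tree(text = "(A:10,B:10);"))
  rc <- root_calibration(8, 16)
  r <- run_mcmc(NULL, tt2, mcmc_config(root_cal = rc), n_iter = 60000,
                sample_every = 30, seed = 5, target = "hyperprior",
                proposal_scale = 6)
  x <- r$trace$root_age[-(1:200)]
  expect_gt(suppressWarnings(stats::ks.test(x - 8, "pexp", rc$rate))$p.value, 0.01)

  # one fossil tip whose window cannot collide with its parent: uniform
  phy <- ape::read.tree(text = "(F:6,(A:8,B:8):2);")
  tt3 <- time_tree(phy, calibrations = tibble::tibble(
    taxon = "F", min_age = 2, max_age = 6))
  r3 <- run_mcmc(NULL, tt3, mcmc_config(root_cal = rc, sa_toggle = FALSE),
                 n_iter = 60000, sample_every = 30, seed = 6,
                 target = "hyperprior", proposal_scale = 6)
  ta <- r3$ages[-(1:200), 1]
  expect_gt(suppressWarnings(stats::ks.test(ta, "punif", 2, 6))$p.value, 0.01)
})

test_that("proposal classes fire and the cached posterior passes its audit", {
  tt <- fossil_tree(seed = 11)
  sc <- simulate_characters(tt, clock_config("iln", base_rate = 0.3,
                                             nu = 0.1),
                            n_chars = 15, seed = 2)
  cfg <- mcmc_config(clock = clock_config("iln", base_rate = 0.3, nu = 0.1),
                     root_cal = root_calibration(10, 16))
  # audit_every divides n_iter: a drifted cache would error here
  r <- run_mcmc(sc$matrix, tt, cfg, n_iter = 2000, sample_every = 20,
                seed = 3, audit_every = 500)
  expect_s3_class(r, "mcmc_trace")
  acc <- r$acceptance
  expect_true(all(c("c", "alpha", "nu", "branch_rate", "node_age",
                    "tip_age", "tree_scale") %in% acc$move))
  expect_true(all(acc$tried > 0))
  expect_gt(sum(acc$accepted), 0)
})

test_that("NNI topology moves preserve age validity", {
  tt <- fossil_tree(seed = 11)
  sc <- simulate_characters(tt, clock_config("strict", base_rate = 0.3),
                            n_chars = 10, seed = 2)
  cfg <- mcmc_config(root_cal = root_calibration(10, 16),
                     topology_moves = TRUE)
  r <- run_mcmc(sc$matrix, tt, cfg, n_iter = 1500, sample_every = 30,
                seed = 7)
  for (ph in r$trees[seq(1, length(r$trees), by = 10)]) {
    expect_true(all(ph$edge.length > -1e-9))
    expect_silent(validate_time_tree(time_tree(ph)))
  }
})

test_that("ASDSF follows its definition on constructed tree samples", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  # identical runs: zero deviation
  expect_equal(asdsf(list(list(t1, t1), list(t1, t1)), burnin = 0), 0)
  # one qualifying split at frequencies 0.6 and 0.4: sample SD 0.1414
  run1 <- c(rep(list(t1), 6), rep(list(t2), 4))
  run2 <- c(rep(list(t1), 4), rep(list(t2), 6))
  a <- asdsf(list(run1, run2), min_freq = 0.1, burnin = 0)
  expect_equal(a, stats::sd(c(0.6, 0.4)), tolerance = 1e-12)
  expect_warning(asdsf(list(list(t1), list(t1)), min_freq = 1.1, burnin = 0),
                 "ASDSF")
})

test_that("PSRF and ESS behave on analytic reference series", {
  set.seed(1)
  x <- matrix(stats::rnorm(2000), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  y <- matrix(stats::rnorm(2000), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  p <- psrf(list(x, y), burnin = 0)
  expect_true(all(abs(p$psrf - 1) < 0.05))
  # zero-variance series reported as 1 with a flag
  z <- cbind(a = rep(2, 500))
  pz <- psrf(list(z, z), burnin = 0)
  expect_equal(pz$psrf, 1)
  expect_true(pz$zero_variance)

  # iid white noise: ESS near n
  set.seed(2)
  w <- stats::rnorm(1000)
  expect_equal(ess(w), 1000, tolerance = 0.25)
  # AR(1) with phi = 0.5: ESS ~ n (1 - phi) / (1 + phi)
  phi <- 0.5
  ar <- as.numeric(stats::arima.sim(list(ar = phi), 20000))
  expect_equal(ess(ar), 20000 * (1 - phi) / (1 + phi), tolerance = 0.2)
})

test_that("convergence gate summarizes paired runs", {
  tt <- fossil_tree(seed = 11)
  sc <- simulate_characters(tt, clock_config("strict", base_rate = 0.3),
                            n_chars = 15, seed = 2)
  cfg <- mcmc_config(root_cal = root_calibration(10, 16))
  runs <- lapply(1:2, function(i) {
    run_mcmc(sc$matrix, tt, cfg, n_iter = 1200, sample_every = 10,
             seed = 10 + i)
  })
  g <- convergence_gate(runs)
  expect_true(is.finite(g$asdsf))
  expect_true(is.finite(g$max_psrf))
  expect_true(is.logical(g$converged))
  gl <- glance(runs[[1]])
  expect_equal(gl$n_samples, 120)
  td <- tidy(runs[[1]])
  expect_true(all(td$hpd_lower <= td$median & td$median <= td$hpd_upper))
})
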