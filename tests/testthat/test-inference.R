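test_that("empirical-Bayes centres track coarse data summaries", {
  # flat synthetic data at a constant value
  sm <- data.frame(fish_id = rep("f1", 12), session = 0:11,
                   success_count = 3, median_angular_error_deg = 7,
                   median_d_m = 3)
  hs <- empirical_bayes_prior_centers(sm, "angular")
  expect_equal(hs$entries$mu_inf$center, 7)
  expect_equal(hs$entries$A_mu$center, 0)
  # synthetic exponential medians: centres within 50% of truth
  set.seed(51)
  ses <- rep(0:14, each = 4)
  vals <- 12 * exp(-ses / 3) + 1 + rnorm(length(ses), 0, 0.5)
  sm2 <- data.frame(fish_id = rep(sprintf("f%d", 1:4), times = 15),
                    session = ses, success_count = 1,
                    median_angular_error_deg = vals, median_d_m = 1)
  hs2 <- empirical_bayes_prior_centers(sm2, "angular")
  expect_equal(hs2$entries$A_mu$center, 12, tolerance = 0.5 * 12)
  expect_lt(abs(hs2$entries$mu_inf$center - 1), 1.5)
  expect_equal(hs2$entries$tau_mu$center, 5)   # one third of the stage length
  # degenerate input falls back to defaults with a warning
  one <- sm[1, ]
  expect_warning(hs3 <- empirical_bayes_prior_centers(one, "success"),
                 "default")
  expect_equal(hs3$entries$tau_mu$center, 5)
})

test_that("build_model validates its inputs", {
  dat <- data.frame(fish_id = "f1", session = 0:9, value = rpois(10, 3))
  expect_error(build_model(dat[0, ], "success"), "no data|no rows")
  neg <- dat; neg$value[2] <- -1
  expect_error(build_model(neg, "success"), "non-negative")
  bad_d <- data.frame(fish_id = "f1", session = 0:9, value = c(-1, runif(9, 2, 4)))
  expect_error(build_model(bad_d, "distance"), "positive")
  expect_error(build_model(data.frame(foo = 1), "angular"), "cannot extract")
})

test_that("single-fish joint log density equals the hand-summed oracle", {
  dat5 <- data.frame(fish_id = "f1", session = 0:4, value = c(1, 2, 3, 2, 4))
  hs <- hierarchy_spec("success", A_mu = 1, tau_mu = 5, mu_inf = 3)
  m5 <- build_model(dat5, "success", hierarchy = hs, hierarchical = FALSE)
  p <- learning_curve_params(-1.2, 4, 3.1)
  hand <- dgamma(1.2, 1.2, 1.2 / 1, log = TRUE) +
    dgamma(4, 1.2, 1.2 / 5, log = TRUE) +
    dgamma(3.1, 1.5, 1.5 / 3, log = TRUE) +
    sum(dpois(c(1, 2, 3, 2, 4), -1.2 * exp(-(0:4) / 4) + 3.1, log = TRUE))
  expect_equal(model_log_density(m5, p), hand, tolerance = 1e-12)
})

test_that("the sampler reproduces a conjugate Poisson posterior", {
  ts <- tiny_success_fit(seed = 7)
  y <- ts$model$data$y
  # flat curve, Gamma(1.5, 0.5) prior on the rate: conjugate closed form
  shape_post <- 1.5 + sum(y)
  rate_post <- 1.5 / 3 + length(y)
  post <- ts$fit$fish$mu_inf[, 1]
  expect_equal(mean(post), shape_post / rate_post,
               tolerance = 4 * sqrt(shape_post) / rate_post / sqrt(200))
  expect_equal(sd(post), sqrt(shape_post) / rate_post, tolerance = 0.05)
})

test_that("sampling is deterministic under a fixed seed", {
  ts1 <- tiny_success_fit(seed = 9, draws = 300, tune = 200)
  ts2 <- tiny_success_fit(seed = 9, draws = 300, tune = 200)
  expect_identical(ts1$fit$draws, ts2$fit$draws)
  expect_equal(nrow(ts1$fit$draws), 2 * 300)  # chains x draws retained
  ts3 <- tiny_success_fit(seed = 10, draws = 300, tune = 200)
  expect_false(identical(ts1$fit$draws, ts3$fit$draws))
})

test_that("hierarchical and single-fish fits agree for a cohort of one", {
  set.seed(52)
  fp <- cohort_params(1, seed = 3)
  md <- draw_measures(fp[fp$measure == "success", ], 15, 6, seed = 4)
  m <- build_model(md[c("fish_id", "session", "value")], "success")
  expect_false(m$hierarchical)  # hierarchy of size 1 collapses
  fit <- sample_posterior(m, chains = 2, tune = 1000, draws = 800, seed = 5)
  expect_equal(fit$derived$pop$initial_value, fit$derived$fish$initial_value[, 1])
})

test_that("prior predictive draws respect the measures' supports", {
  set.seed(53)
  fp <- cohort_params(3, seed = 6)
  mds <- draw_measures(fp[fp$measure == "success", ], 10, 6, seed = 7)
  ms <- build_model(mds[c("fish_id", "session", "value")], "success")
  pps <- prior_predictive(ms, n_draws = 100, seed = 8)
  vs <- unlist(lapply(pps$datasets, `[[`, "value"))
  expect_true(all(vs >= 0 & vs == round(vs)))
  mdd <- draw_measures(fp[fp$measure == "distance", ], 10, 6, seed = 9)
  mdl <- build_model(mdd[c("fish_id", "session", "value")], "distance")
  ppd <- prior_predictive(mdl, n_draws = 50, seed = 10)
  expect_true(all(unlist(lapply(ppd$datasets, `[[`, "value")) > 0))
})

test_that("prior-predictive initial values centre on the prior means", {
  # angular measure: normal hierarchies preserve means exactly, so the
  # prior mean of the curve at ses = 0 is the A centre plus the mu_inf centre
  set.seed(54)
  dat <- data.frame(fish_id = rep(c("a", "b"), each = 10),
                    session = rep(0:9, 2), value = rnorm(20, 5, 2))
  hs <- hierarchy_spec("angular", A_mu = 9, tau_mu = 4, mu_inf = 1,
                       A_sigma = 5, sigma_inf = 5, width_scale = 3)
  m <- build_model(dat, "angular", hierarchy = hs)
  mu0 <- replicate(3000, {
    p <- fovadapt:::draw_params_from_prior(m)
    mean(p$A + p$minf)
  })
  expect_equal(mean(mu0), 10, tolerance = 4 * sd(mu0) / sqrt(3000))
})

test_that("posterior predictive checks flag misspecified data", {
  set.seed(55)
  fp <- cohort_params(3, seed = 11)
  fp <- fp[fp$measure == "distance", ]
  md <- draw_measures(fp, 12, 6, seed = 12)
  m <- build_model(md[c("fish_id", "session", "value")], "distance")
  fit <- sample_posterior(m, chains = 2, tune = 600, draws = 400, seed = 13)
  pp <- posterior_predictive(fit, m, seed = 14, n_rep = 150)
  expect_gt(pp$coverage, 0.8)   # well-specified data: near-nominal coverage
  # a strong linear trend cannot be captured by a saturating exponential
  lin <- md
  lin$value <- pmax(10 - 0.6 * lin$session + rnorm(nrow(lin), 0, 0.2), 0.3)
  ml <- build_model(lin[c("fish_id", "session", "value")], "distance")
  fitl <- sample_posterior(ml, chains = 2, tune = 600, draws = 400, seed = 15)
  ppl <- posterior_predictive(fitl, ml, seed = 16, n_rep = 150)
  expect_lt(ppl$coverage, pp$coverage)
})

test_that("fish-level estimates shrink toward the population", {
  # two typical fish and one extreme fish: the extreme fish's hierarchical
  # estimate lies between its single-fish estimate and the population mean
  set.seed(56)
  mk <- function(id, minf) {
    p <- learning_curve_params(-1.5, 2.5, minf)
    data.frame(fish_id = id, session = 0:14,
               value = pmin(rpois(15, pmax(curve_mean(p, 0:14), 0.01)), 6))
  }
  md <- rbind(mk("f1", 3.3), mk("f2", 3.5), mk("f3", 5.9))
  mh <- build_model(md, "success")
  fh <- sample_posterior(mh, chains = 2, tune = 2000, draws = 2000, seed = 17)
  ms <- build_model(md[md$fish_id == "f3", ], "success",
                    hierarchy = mh$hierarchy, hierarchical = FALSE)
  fs <- sample_posterior(ms, chains = 2, tune = 2000, draws = 2000, seed = 17)
  single <- median(fs$fish$mu_inf[, 1])
  pooled <- median(fh$draws[, "minf_pop"])
  hier <- median(fh$fish$mu_inf[, 3])
  expect_gt(hier, pooled)   # pulled up from the population toward its data
  expect_lt(hier, single + 0.2)   # but shrunk relative to fitting alone
})

test_that("doubling the draws leaves posterior medians stable", {
  ts_small <- tiny_success_fit(seed = 18, flat = FALSE, tune = 1500, draws = 1000)
  ts_big <- tiny_success_fit(seed = 18, flat = FALSE, tune = 1500, draws = 2000)
  for (p in c("initial_value", "asymptotic_performance", "initial_learning_rate")) {
    m1 <- median(ts_small$fit$derived$pop[[p]])
    m2 <- median(ts_big$fit$derived$pop[[p]])
    expect_lt(abs(m1 - m2), 0.1 * sd(ts_big$fit$derived$pop[[p]]))
  }
})

test_that("diagnostics report split-R-hat near 1 for well-mixed chains", {
  ts <- tiny_success_fit(seed = 19, draws = 1000, tune = 600)
  expect_true(all(ts$fit$diagnostics$rhat < 1.02))
  expect_true(ts$fit$diagnostics$ok)
  expect_true(is.na(ts$fit$diagnostics$divergences))
  expect_named(ts$fit$diagnostics$ess)
})
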