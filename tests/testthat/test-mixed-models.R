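test_that("REML matches the closed-form balanced one-way oracle", {
  k <- 12; n <- 8
  d <- one_way_data(k, n, sigma_b = 2, sigma_e = 1, seed = 101)
  fit <- reml_fit(y ~ 1 + (1 | g), d)
  # ANOVA estimator: sigma_b^2 = (MSB - MSW) / n, exact REML optimum in the
  # balanced case
  gm <- tapply(d$y, d$g, mean)
  msb <- n * sum((gm - mean(d$y))^2) / (k - 1)
  msw <- sum((d$y - gm[d$g])^2) / (k * (n - 1))
  expect_equal(unname(fit$varcomp["g"]), (msb - msw) / n, tolerance = 1e-6)
  expect_equal(unname(fit$varcomp["Residual"]), msw, tolerance = 1e-6)

  # same fit through the variance-component engine: one-way random design
  # as a block-of-ones covariance; REML log-likelihoods must agree
  G <- matrix(0, k * n, k * n)
  for (g in seq_len(k)) {
    idx <- which(d$g == g)
    G[idx, idx] <- 1
  }
  vfit <- fit_vc_model(d$y, matrix(1, k * n, 1), G)
  expect_equal(vfit$loglik, fit$logLik, tolerance = 1e-5)
  expect_equal(vfit$s2a, (msb - msw) / n, tolerance = 1e-4)
})

test_that("null variance components are estimated at the zero boundary", {
  d <- one_way_data(10, 10, sigma_b = 0, sigma_e = 1, seed = 55)
  fit <- reml_fit(y ~ 1 + (1 | g), d)
  expect_lt(unname(fit$varcomp["g"]), 0.02)
  G <- matrix(0, 100, 100)
  for (g in 1:10) G[d$g == g, d$g == g] <- 1
  vfit <- fit_vc_model(d$y, matrix(1, 100, 1), G)
  expect_lt(vfit$s2a, 0.02)
})

test_that("profile-grid search agrees with the optimizer", {
  d <- one_way_data(8, 6, sigma_b = 1.5, sigma_e = 1, seed = 7)
  G <- matrix(0, 48, 48)
  for (g in 1:8) G[d$g == g, d$g == g] <- 1
  X <- matrix(1, 48, 1)
  vfit <- fit_vc_model(d$y, X, G)
  blocks <- matrix_blocks(G)
  cb <- kypemorph:::build_vc_blocks(d$y, X, G, NULL, blocks)
  grid <- seq(-6, 4, by = 0.01)
  nll <- vapply(grid, function(g)
    as.numeric(kypemorph:::.vc_reml_eval(g, cb, FALSE)$nll), numeric(1))
  expect_lt(abs(min(nll) - (-vfit$loglik)), 1e-4)
})

test_that("type-III tests reduce to classical ANOVA without random terms", {
  set.seed(19)
  d <- expand.grid(a = factor(1:3), b = factor(1:4), rep = 1:5)
  d$y <- rnorm(nrow(d)) + as.numeric(d$a) * 0.5
  fit <- reml_fit(y ~ a * b, d)
  expect_false(fit$is_mixed)
  tab <- type3_anova(fit)
  n <- nrow(d); p <- 12
  expect_equal(tab$den_df, rep(n - p, 3))
  # balanced design: classical sequential ANOVA F equals type III
  cl <- anova(lm(y ~ a * b, d))
  expect_equal(tab$f_value, cl$`F value`[1:3], tolerance = 1e-10)
})

test_that("Satterthwaite df equals the closed form on a balanced split plot", {
  a <- 4; r <- 3; b <- 5
  set.seed(23)
  d <- expand.grid(A = factor(seq_len(a)), rep = seq_len(r),
                   B = factor(seq_len(b)))
  d$plot <- factor(paste(d$A, d$rep))
  d$y <- rnorm(a * r * b) + rep(rnorm(a * r, sd = 1.5),
                                times = b) + as.numeric(d$A)
  fit <- reml_fit(y ~ A * B + (1 | plot), d)
  tab <- type3_anova(fit)
  expect_equal(tab$den_df[tab$term == "A"], a * (r - 1), tolerance = 1e-3)
  expect_equal(tab$den_df[tab$term == "B"], a * (r - 1) * (b - 1),
               tolerance = 1e-3)
  expect_equal(tab$den_df[tab$term == "A:B"], a * (r - 1) * (b - 1),
               tolerance = 1e-3)
  # invariance to the factor coding
  d2 <- d
  d2$A <- stats::relevel(d2$A, ref = "3")
  tab2 <- type3_anova(reml_fit(y ~ A * B + (1 | plot), d2))
  expect_equal(tab2$den_df, tab$den_df, tolerance = 1e-6)
  expect_equal(tab2$f_value, tab$f_value, tolerance = 1e-6)
})

test_that("backward elimination drops noise terms and respects thresholds", {
  cfg <- sim_config(seed = 42, design = small_design(25, 3))
  cc <- simulate_cohort(cfg)
  d <- lmm_data(cc$records)
  full <- AKH ~ strain + GSR + strain:GSR + (1 | family) + (1 | sire)
  sel <- backward_eliminate(full, d)
  fx <- kypemorph:::fixed_terms(sel$formula)
  # the generator ties AKH to strain but never to GSR
  expect_true("strain" %in% fx)
  expect_false("strain:GSR" %in% fx)
  # trace bookkeeping: every drop exceeded its threshold, kept terms do not
  tr <- sel$trace
  expect_true(all(tr$p_value[tr$action == "dropped" &
                               tr$phase == "fixed"] > 0.05))
  expect_true(all(tr$p_value[tr$action == "kept" &
                               tr$phase == "fixed"] <= 0.05 |
                    !tr$term[tr$action == "kept" & tr$phase == "fixed"] %in%
                    kypemorph:::droppable_fixed(fx)))
  # the selected model's REML likelihood dominates its fixed submodels
  sub <- reml_fit(build_formula("AKH", setdiff(fx, "strain"),
                                kypemorph:::random_terms(sel$formula)), d)
  expect_gte(sel$fit$logLik, sub$logLik - 1e-6)
})

test_that("estimated marginal means and Tukey adjustment behave canonically", {
  set.seed(31)
  d <- data.frame(g = factor(rep(1:6, each = 12)), y = rnorm(72))
  fit <- reml_fit(y ~ g, d)
  em <- emmeans_tukey(fit, "g")
  expect_equal(nrow(em$pairs), choose(6, 2))
  expect_equal(em$emmeans$emmean, as.numeric(tapply(d$y, d$g, mean)),
               tolerance = 1e-10)
  expect_true(all(em$pairs$p_tukey >= em$pairs$p_raw - 1e-12))
  expect_true(all(em$pairs$p_tukey >= 0 & em$pairs$p_tukey <= 1))
  expect_error(emmeans_tukey(fit, "strain"), "not in the model")

  d2 <- data.frame(g = factor(rep(1:2, each = 10)), y = rnorm(20))
  em2 <- emmeans_tukey(reml_fit(y ~ g, d2), "g")
  expect_equal(em2$pairs$p_tukey, em2$pairs$p_raw, tolerance = 1e-10)

  # familywise error of the all-null 6-level comparison is ~ alpha
  reps <- 600
  fwer <- 0
  set.seed(99)
  for (i in seq_len(reps)) {
    dd <- data.frame(g = factor(rep(1:6, each = 8)), y = rnorm(48))
    m <- stats::aov(y ~ g, dd)
    tk <- stats::TukeyHSD(m)$g[, "p adj"]
    fwer <- fwer + any(tk < 0.05)
  }
  expect_lt(abs(fwer / reps - 0.05), 0.025)
  # and our wrapper reproduces the studentized-range p-values exactly
  dd <- data.frame(g = factor(rep(1:6, each = 8)), y = rnorm(48))
  ours <- emmeans_tukey(reml_fit(y ~ g, dd), "g")
  ref <- stats::TukeyHSD(stats::aov(y ~ g, dd))$g
  expect_equal(sort(ours$pairs$p_tukey), sort(unname(ref[, "p adj"])),
               tolerance = 1e-6)
})
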