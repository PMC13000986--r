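test_that("single observation degenerates to the observed effect", {
  f <- fit_multilevel(0.4, 0.09, data.frame(study_id = "s1",
                                            treatment_id = "t1"))
  expect_equal(unname(f$beta), 0.4)
  expect_equal(unname(f$se), 0.3)
  expect_true(f$converged)
})

test_that("balanced equal-variance closed form is met", {
  # one random level per observation, equal v: tau2 = max(0, s2_y - v),
  # se(beta) = sqrt((tau2 + v)/k)
  y <- c(0.5, 0, -0.5); v <- rep(0.1, 3)
  d <- data.frame(unit = c("a", "b", "c"))
  f <- fit_multilevel(y, v, d, random = c(unit = "unit"))
  expect_equal(unname(f$beta), 0, tolerance = 1e-10)
  expect_equal(unname(f$vc["sigma2_unit"]), var(y) - 0.1, tolerance = 1e-6)
  expect_equal(unname(f$se), sqrt(0.25 / 3), tolerance = 1e-7)

  # boundary case: sample variance below v -> component exactly 0
  y2 <- c(0.05, 0, -0.05)
  f2 <- fit_multilevel(y2, v, d, random = c(unit = "unit"))
  expect_identical(unname(f2$vc["sigma2_unit"]), 0)
  w <- 1 / v
  expect_equal(unname(f2$beta), sum(w * y2) / sum(w), tolerance = 1e-12)
})

test_that("with no random terms the fit is the closed-form GLS solution", {
  set.seed(5)
  k <- 20
  y <- rnorm(k); v <- runif(k, 0.05, 0.4)
  x <- rnorm(k)
  d <- data.frame(x = x)
  f <- fit_multilevel(y, v, d, moderator = ~x, random = NULL)
  X <- cbind(1, x); W <- diag(1 / v)
  beta_gls <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  expect_equal(unname(f$beta), as.numeric(beta_gls), tolerance = 1e-12)
  expect_equal(unname(f$se), unname(sqrt(diag(solve(t(X) %*% W %*% X)))),
               tolerance = 1e-12)
})

test_that("REML optimum matches an independent grid-search oracle", {
  for (seed in 1:8) {
    inst <- random_instance(seed)
    f <- fit_multilevel(inst$y, inst$v, inst$data)
    oracle <- reml_grid_oracle(inst$y, inst$v, inst$data$study_id,
                               inst$data$treatment_id)
    expect_equal(unname(f$vc["sigma2_study"]), oracle$s2[1],
                 tolerance = 1e-4, label = paste("seed", seed, "study"))
    expect_equal(unname(f$vc["sigma2_treatment"]), oracle$s2[2],
                 tolerance = 1e-4, label = paste("seed", seed, "treatment"))
    expect_gte(f$reml_loglik, oracle$ll - 1e-6)
  }
})

test_that("fits agree with the established multilevel implementation", {
  skip_if_not_installed("metafor")
  for (seed in c(31, 32, 33)) {
    inst <- random_instance(seed, k_max = 30L)
    f <- fit_multilevel(inst$y, inst$v, inst$data)
    mf <- metafor::rma.mv(inst$y, inst$v,
                          random = ~ 1 | study_id / treatment_id,
                          data = inst$data, method = "REML")
    expect_equal(unname(f$beta), as.numeric(metafor::coef.rma(mf)),
                 tolerance = 1e-5)
    expect_equal(unname(f$se), mf$se, tolerance = 1e-4)
    expect_equal(unname(f$vc), mf$sigma2, tolerance = 1e-4)
    expect_equal(f$reml_loglik, as.numeric(stats::logLik(mf)),
                 tolerance = 1e-5)
  }
})

test_that("estimates are invariant to record order and identifier labels", {
  inst <- random_instance(17)
  f <- fit_multilevel(inst$y, inst$v, inst$data)
  set.seed(1); perm <- sample(inst$k)
  f_perm <- fit_multilevel(inst$y[perm], inst$v[perm],
                           inst$data[perm, , drop = FALSE])
  relab <- inst$data
  relab$study_id <- paste0("XX_", relab$study_id)
  relab$treatment_id <- toupper(relab$treatment_id)
  f_lab <- fit_multilevel(inst$y, inst$v, relab)
  for (g in list(f_perm, f_lab)) {
    expect_equal(unname(g$beta), unname(f$beta), tolerance = 1e-6)
    expect_equal(unname(g$vc), unname(f$vc), tolerance = 1e-5)
  }
})

test_that("adding a constant shifts the intercept and nothing else", {
  inst <- random_instance(23)
  f <- fit_multilevel(inst$y, inst$v, inst$data)
  f_shift <- fit_multilevel(inst$y + 1.7, inst$v, inst$data)
  expect_equal(unname(f_shift$beta), unname(f$beta) + 1.7, tolerance = 1e-6)
  expect_equal(unname(f_shift$vc), unname(f$vc), tolerance = 1e-5)
})

test_that("omnibus QM behaves as a Wald chi-square", {
  set.seed(41)
  d <- data.frame(study_id = rep(sprintf("s%d", 1:10), each = 3),
                  treatment_id = rep(sprintf("s%d.t1", 1:10), each = 3),
                  grp = rep(c("a", "b", "c"), 10))
  y <- rnorm(30, ifelse(d$grp == "b", 0.5, 0)); v <- runif(30, .05, .15)
  f <- fit_multilevel(y, v, d, moderator = ~grp)
  # single-coefficient case: qm = (b/se)^2 on df = 1
  single <- omnibus_moderator_test(f, which = "grpb")
  expect_equal(single$qm, (f$beta[["grpb"]] / f$se[["grpb"]])^2)
  expect_equal(single$qm_df, 1L)
  # default: all non-intercept coefficients
  both <- omnibus_moderator_test(f)
  expect_equal(both$qm_df, 2L)
  expect_equal(both$qm, f$qm)

  # duplicated groups carrying identical data: no group difference
  d2 <- data.frame(study_id = rep(sprintf("s%d", 1:6), 2),
                   treatment_id = rep(sprintf("s%d.t1", 1:6), 2),
                   grp = rep(c("a", "b"), each = 6))
  y2 <- rep(rnorm(6, 0, 0.3), 2); v2 <- rep(runif(6, .05, .1), 2)
  f2 <- fit_multilevel(y2, v2, d2, moderator = ~grp,
                       random = c(unit = ".row"))
  expect_lt(f2$qm, 1e-6)
  expect_gt(f2$qm_p, 0.999)
})

test_that("rank-deficient designs error naming the aliased level", {
  d <- data.frame(study_id = c("s1", "s1", "s2", "s2"),
                  treatment_id = c("t1", "t1", "t2", "t2"),
                  a = c("x", "x", "y", "y"), b = c("p", "p", "q", "q"))
  expect_error(
    fit_multilevel(c(0, .1, .2, .3), rep(.1, 4), d, moderator = ~ a + b),
    "aliased")
})

test_that("I-squared follows the multilevel formula", {
  # direct evaluation: sigma2 = 0.1 + 0.1, vtilde = 0.05 -> 80%
  expect_equal(100 * 0.2 / (0.2 + 0.05), 80)
  inst <- random_instance(55)
  f <- fit_multilevel(inst$y, inst$v, inst$data)
  w <- 1 / inst$v
  vt <- (inst$k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  S <- sum(f$vc)
  expect_equal(heterogeneity_i2(f), 100 * S / (S + vt), tolerance = 1e-10)
  expect_equal(f$i2, heterogeneity_i2(f))
  expect_true(f$i2 >= 0 && f$i2 <= 100)
  # all components zero -> 0%
  y0 <- c(0.01, -0.01, 0.02, 0); d0 <- data.frame(u = letters[1:4])
  f0 <- fit_multilevel(y0, rep(0.2, 4), d0, random = c(unit = "u"))
  expect_equal(heterogeneity_i2(f0), 0)
})

test_that("prediction interval widens the CI by the summed heterogeneity", {
  inst <- random_instance(61)
  f <- fit_multilevel(inst$y, inst$v, inst$data)
  pr <- predict_mean_and_pi(f)
  S <- sum(f$vc)
  expect_equal(pr$pi,
               unname(f$beta[1]) + c(-1, 1) *
                 qnorm(0.975) * sqrt(f$se[1]^2 + S),
               tolerance = 1e-10)
  expect_lte(pr$pi[1], pr$ci[1])
  expect_gte(pr$pi[2], pr$ci[2])
  expect_equal(c(f$ci_low[[1]], f$ci_high[[1]]), pr$ci)
  # direct evaluation: se = 0.1, sum sigma2 = 0.03 -> +/- 1.96*sqrt(0.04)
  expect_equal(qnorm(0.975) * sqrt(0.1^2 + 0.03), 1.959964 * 0.2,
               tolerance = 1e-6)
  # no heterogeneity -> pi equals ci
  y0 <- c(0.01, -0.01, 0.02, 0); d0 <- data.frame(u = letters[1:4])
  f0 <- fit_multilevel(y0, rep(0.2, 4), d0, random = c(unit = "u"))
  p0 <- predict_mean_and_pi(f0)
  expect_equal(p0$pi, p0$ci, tolerance = 1e-10)
})

test_that("phylogenetic random term matches the established implementation", {
  skip_if_not_installed("metafor")
  set.seed(71)
  tree <- simulate_tree(paste0("sp", 1:6), seed = 9)
  R <- correlation_from_tree(tree)
  k <- 24
  d <- data.frame(study_id = rep(sprintf("s%d", 1:8), each = 3),
                  treatment_id = rep(sprintf("s%d.t1", 1:8), each = 3),
                  sp = sample(paste0("sp", 1:6), k, replace = TRUE))
  y <- rnorm(k, -0.2, 0.5); v <- runif(k, .05, .2)
  f <- fit_multilevel(y, v, d, phylo = list(taxon = "sp", corr = R))
  d$phylo_sp <- d$sp
  mf <- suppressWarnings(metafor::rma.mv(
    y, v, random = list(~ 1 | study_id / treatment_id, ~ 1 | phylo_sp),
    R = list(phylo_sp = R), data = d, method = "REML"))
  expect_equal(unname(f$beta), as.numeric(metafor::coef.rma(mf)),
               tolerance = 1e-4)
  expect_equal(unname(f$vc), mf$sigma2, tolerance = 1e-3)

  # a taxon absent from the correlation matrix is a contract violation
  d_bad <- d; d_bad$sp[1] <- "unknown_taxon"
  expect_error(fit_multilevel(y, v, d_bad,
                              phylo = list(taxon = "sp", corr = R)),
               "lacks taxa")
})

test_that("precondition violations are rejected", {
  d <- data.frame(study_id = c("s1", "s2"), treatment_id = c("t1", "t1"))
  expect_error(fit_multilevel(c(1, 2), c(0.1, 0), d), "positive")
  expect_error(fit_multilevel(c(1, 2), 0.1, d), "same length")
  expect_error(fit_multilevel(c(1, 2), c(.1, .1), d,
                              random = c(treatment = "treatment_id")),
               "requires a study term")
})
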