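test_that("pooled SD matches hand evaluation and handles degenerate input", {
  expect_equal(pooled_sd(2, 2, 8, 8), 2)              # equal-SD case
  expect_equal(pooled_sd(3, 1, 5, 5), sqrt(5))        # sqrt((4*9+4*1)/8)
  expect_equal(pooled_sd(0, 0, 5, 5), 0)
  expect_error(pooled_sd(1, 1, 1, 1), "degenerate")
  expect_error(hedges_g(1, 2, 0, 0, 5, 5), "zero pooled")
})

test_that("hedges_g matches the hand-evaluated formula", {
  g <- hedges_g(8, 10, 2, 2, 10, 10)
  expect_equal(g$J, 1 - 3 / 71)
  expect_equal(g$value, -(1 - 3 / 71), tolerance = 1e-12)
  expect_equal(g$variance, 20 / 100 + g$value^2 / 40, tolerance = 1e-12)

  g0 <- hedges_g(5, 5, 1, 2, 7, 9)
  expect_equal(g0$value, 0)
  expect_equal(g0$variance, 16 / 63)                   # (n_t+n_c)/(n_t*n_c)

  # swapping arms negates the value, variance unchanged
  a <- hedges_g(8, 10, 2, 3, 6, 9)
  b <- hedges_g(10, 8, 3, 2, 9, 6)
  expect_equal(b$value, -a$value)
  expect_equal(b$variance, a$variance)
})

test_that("sign convention reverses development time and damage exactly once", {
  g <- hedges_g(c(12, 9, 4), c(10, 10, 5), c(2, 2, 1), c(2, 2, 1),
                c(10, 8, 9), c(10, 8, 9))
  out <- apply_sign_convention(g, c("development_time", "growth", "damage"))
  expect_equal(out$value[1], -g$value[1])
  expect_equal(out$value[2], g$value[2])               # untouched
  expect_equal(out$value[3], -g$value[3])
  expect_equal(out$sign_reversed, c(TRUE, FALSE, TRUE))
  expect_error(apply_sign_convention(out, "damage"), "already applied")
})

test_that("log odds ratio matches hand evaluation, with continuity handling", {
  l <- log_odds_ratio(8, 4, 10, 10)
  expect_equal(l$value, log(6), tolerance = 1e-12)
  expect_equal(l$variance, 1 / 8 + 1 / 2 + 1 / 4 + 1 / 6, tolerance = 1e-12)

  expect_equal(log_odds_ratio(6, 3, 10, 5)$value, 0)   # equal proportions
  sw <- log_odds_ratio(4, 8, 10, 10)
  expect_equal(sw$value, -l$value)

  z <- log_odds_ratio(0, 4, 10, 10)                    # zero cell: +0.5 all
  expect_equal(z$value, log((0.5 / 10.5) / (4.5 / 6.5)), tolerance = 1e-12)
  expect_error(log_odds_ratio(0, 0, 10, 10), "undefined odds")
  expect_error(log_odds_ratio(10, 10, 10, 10), "undefined odds")
  expect_error(log_odds_ratio(11, 2, 10, 10), "\\[0, n\\]")
})

test_that("J is in (0,1), increases monotonically in total n, g is
           scale-invariant, and variance decreases in n", {
  ns <- c(4, 6, 10, 20, 50, 200, 1000)
  Js <- vapply(ns, function(n)
    hedges_g(1, 0, 1, 1, n, n)$J, numeric(1))
  expect_true(all(Js > 0 & Js < 1))
  expect_true(all(diff(Js) > 0))
  expect_lt(1 - Js[length(Js)], 1e-3)

  set.seed(11)
  for (i in 1:20) {
    mt <- rnorm(1); mc <- rnorm(1)
    st <- runif(1, .2, 3); sc <- runif(1, .2, 3)
    nt <- sample(4:40, 1); nc <- sample(4:40, 1)
    base <- hedges_g(mt, mc, st, sc, nt, nc)
    cc <- runif(1, .1, 10)
    scaled <- hedges_g(cc * mt, cc * mc, cc * st, cc * sc, nt, nc)
    expect_equal(scaled$value, base$value, tolerance = 1e-12)
    expect_equal(scaled$variance, base$variance, tolerance = 1e-12)
    bigger <- hedges_g(mt, mc, st, sc, 2 * nt, 2 * nc)
    expect_lt(bigger$variance, base$variance)
  }
})

test_that("compute_effect_sizes routes records and excludes the unusable", {
  tab <- make_records(6L)
  tab$outcome[1] <- "development_time"
  tab$sd_treatment[4] <- NA                    # mean-based, no SD -> excluded
  tab$events_treatment <- NA_integer_; tab$events_control <- NA_integer_
  tab$mean_treatment[5] <- NA; tab$mean_control[5] <- NA
  tab$sd_treatment[5] <- NA; tab$sd_control[5] <- NA
  tab$events_treatment[5] <- 7L; tab$events_control[5] <- 3L
  ds <- dataset_from_table(tab)
  expect_warning(es <- compute_effect_sizes(ds), "excluded")
  expect_equal(nrow(es), 5L)
  expect_setequal(attr(es, "exclusions"), "r04")
  expect_equal(es$metric[es$record_id == "r05"], "log_odds_ratio")
  expect_true(es$sign_reversed[es$record_id == "r01"])
  direct <- hedges_g(tab$mean_treatment[1], tab$mean_control[1],
                     tab$sd_treatment[1], tab$sd_control[1],
                     tab$n_treatment[1], tab$n_control[1])
  expect_equal(es$value[es$record_id == "r01"], -direct$value)
})

test_that("effect sizes agree with an established implementation", {
  skip_if_not_installed("metafor")
  set.seed(21)
  for (i in 1:10) {
    mt <- rnorm(1); mc <- rnorm(1)
    st <- runif(1, .3, 2); sc <- runif(1, .3, 2)
    nt <- sample(5:30, 1); nc <- sample(5:30, 1)
    mine <- hedges_g(mt, mc, st, sc, nt, nc)
    ref <- metafor::escalc("SMD", m1i = mt, m2i = mc, sd1i = st, sd2i = sc,
                           n1i = nt, n2i = nc, vtype = "LS")
    # metafor applies the exact gamma-function bias correction; ours is the
    # standard 1 - 3/(4m - 1) approximation, so agreement is near, not exact
    expect_equal(mine$value, as.numeric(ref$yi), tolerance = 2e-3)
    expect_equal(mine$variance, as.numeric(ref$vi), tolerance = 2e-3)
    a <- sample(1:11, 1); cc <- sample(0:12, 1)
    lm_ <- log_odds_ratio(a, cc, 12, 12)
    refl <- metafor::escalc("OR", ai = a, bi = 12 - a, ci = cc, di = 12 - cc,
                            add = 1 / 2, to = "only0")
    expect_equal(lm_$value, as.numeric(refl$yi), tolerance = 1e-10)
    expect_equal(lm_$variance, as.numeric(refl$vi), tolerance = 1e-10)
  }
})
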