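# Fixtures built in code: a minimal well-formed record table and small
# random meta-analytic instances for oracle comparisons.

make_records <- function(n = 3L) {
  data.frame(
    record_id = sprintf("r%02d", seq_len(n)),
    study_id = sprintf("s%02d", rep(seq_len(max(1L, n %/% 2L)),
                                    length.out = n)),
    treatment_id = sprintf("t%02d", seq_len(n)),
    response_category = rep(c("herbivore_performance",
                              "herbivore_preference",
                              "plant_performance"), length.out = n),
    outcome = rep(c("growth", "feeding_choice", "biomass"), length.out = n),
    mean_treatment = seq(1, 2, length.out = n),
    mean_control = rep(1.5, n),
    sd_treatment = rep(0.5, n),
    sd_control = rep(0.6, n),
    n_treatment = rep(10L, n),
    n_control = rep(12L, n),
    publication_year = rep(2010L, n),
    setting = rep("glasshouse", n),
    plant_species = rep("Brassica oleracea", n),
    inducer_species = rep("Pieris rapae", n),
    subsequent_species = rep("Myzus persicae", n),
    inducer_guild = rep("chewer", n),
    subsequent_guild = rep("sap_feeder", n),
    stringsAsFactors = FALSE)
}

# Small random instance with a nested study/treatment structure; the
# structure guarantees both variance components are identifiable (several
# studies, multi-treatment studies, multi-record treatments). Used for the
# REML grid-search oracle comparisons.
random_instance <- function(seed, k_max = 12L) {
  set.seed(seed)
  k <- sample(8:k_max, 1L)
  n_study <- sample(2:3, 1L)
  # one large study with several two-record treatments plus two-record
  # single-treatment studies: keeps the study and treatment grouping
  # patterns distinct, so both components are identifiable
  sizes <- c(k - 2L * (n_study - 1L), rep(2L, n_study - 1L))
  study <- rep(seq_len(n_study), times = sizes)
  trt <- unlist(lapply(sizes, function(m)
    rep(seq_len(max(1L, ceiling(m / 2))), each = 2L, length.out = m)))
  d <- data.frame(study_id = paste0("s", study),
                  treatment_id = paste0("s", study, ".t", trt))
  v <- runif(k, 0.03, 0.3)
  s2s <- runif(1, 0, 0.5); s2t <- runif(1, 0, 0.4)
  us <- rnorm(n_study, 0, sqrt(s2s))[study]
  ut_lab <- as.integer(factor(d$treatment_id))
  ut <- rnorm(max(ut_lab), 0, sqrt(s2t))[ut_lab]
  y <- -0.3 + us + ut + rnorm(k, 0, sqrt(v))
  list(y = y, v = v, data = d, k = k)
}

# Independent REML oracle: dense base-R likelihood evaluated on a coarse
# grid, then refined by local search. Shares no code with the package
# fitter (no Matrix, no optimizer).
reml_ll_dense <- function(y, v, study, trt, s2s, s2t) {
  k <- length(y)
  Zs <- outer(study, unique(study), `==`) * 1
  Zt <- outer(trt, unique(trt), `==`) * 1
  V <- diag(v) + s2s * Zs %*% t(Zs) + s2t * Zt %*% t(Zt)
  Vi <- solve(V)
  X <- matrix(1, k, 1)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((k - 1) * log(2 * pi) - log(k) +
                       determinant(V)$modulus + log(XtViX) +
                       t(r) %*% Vi %*% r))
}

reml_grid_oracle <- function(y, v, study, trt, upper = 2) {
  f <- function(a, b) reml_ll_dense(y, v, study, trt, a, b)
  grid <- seq(0, upper, length.out = 41L)
  best <- c(0, 0); best_ll <- -Inf
  for (a in grid) for (b in grid) {
    ll <- f(a, b)
    if (ll > best_ll) { best_ll <- ll; best <- c(a, b) }
  }
  step <- grid[2] - grid[1]
  while (step > 1e-8) {
    repeat {
      cand <- expand.grid(a = best[1] + step * (-1:1),
                          b = best[2] + step * (-1:1))
      cand <- cand[cand$a >= 0 & cand$b >= 0, ]
      lls <- mapply(f, cand$a, cand$b)
      i <- which.max(lls)
      if (lls[i] <= best_ll) break
      best_ll <- lls[i]; best <- c(cand$a[i], cand$b[i])
    }
    step <- step / 2
  }
  list(s2 = best, ll = best_ll)
}
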