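## Multilevel random-effects meta-analytic model, fitted by REML with known
## sampling variances:
##   y = X beta + Z_s u_s + Z_t u_t (+ Z_p u_p) + e,
##   u_s ~ N(0, s2_study I), u_t ~ N(0, s2_treatment I),
##   u_p ~ N(0, s2_taxon R), e_i ~ N(0, v_i) with v known.
## Variance components are optimized on the log scale (quasi-Newton,
## multi-start) over the restricted likelihood; beta by GLS at the optimum.
## The marginal covariance is handled as a sparse matrix with a reusable
## symbolic Cholesky factorization, so nested-only models (block-diagonal in
## study) cost O(sum of block sizes cubed) per likelihood evaluation.

.CI_Z <- function(level) qnorm(1 - (1 - level) / 2)

.typical_sampling_variance <- function(v) {
  w <- 1 / v
  (length(v) - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

.random_design <- function(data, random, phylo, k) {
  G <- list(); labels <- character(0)
  if (is.null(random) || !length(random)) return(list(G = G, labels = labels))
  if (is.null(names(random)) || any(names(random) == ""))
    stop("'random' must be a named vector, e.g. c(study = \"study_id\")")
  if ("treatment" %in% names(random) && !"study" %in% names(random))
    stop("a treatment-within-study term requires a study term")
  grouping <- function(col) {
    if (identical(col, ".row")) return(factor(seq_len(k)))
    if (is.null(data) || is.null(data[[col]]))
      stop("random-effect column not found in data: ", col)
    if (anyNA(data[[col]])) stop("missing values in random-effect column: ", col)
    factor(data[[col]])
  }
  for (nm in names(random)) {
    f <- if (nm == "treatment") {
      interaction(grouping(random[["study"]]), grouping(random[["treatment"]]),
                  drop = TRUE)
    } else grouping(random[[nm]])
    Z <- Matrix::t(Matrix::fac2sparse(f))
    G[[length(G) + 1L]] <- Matrix::tcrossprod(Z)
    labels <- c(labels, paste0("sigma2_", nm))
  }
  if (!is.null(phylo)) {
    if (!is.list(phylo) || is.null(phylo$taxon) || is.null(phylo$corr))
      stop("'phylo' must be list(taxon = <column>, corr = <correlation matrix>)")
    taxa <- data[[phylo$taxon]]
    if (is.null(taxa)) stop("taxon column not found in data: ", phylo$taxon)
    R <- phylo$corr
    missing <- setdiff(unique(taxa), rownames(R))
    if (length(missing))
      stop("correlation matrix lacks taxa present in the data: ",
           paste(head(missing, 5L), collapse = ", "))
    f <- factor(taxa)
    Rsub <- R[levels(f), levels(f), drop = FALSE]
    Z <- Matrix::t(Matrix::fac2sparse(f))
    Gp <- Z %*% Matrix::Matrix(Rsub, sparse = TRUE) %*% Matrix::t(Z)
    G[[length(G) + 1L]] <- methods::as(Matrix::forceSymmetric(Gp), "CsparseMatrix")
    labels <- c(labels, "sigma2_taxon")
  }
  list(G = G, labels = labels)
}

## Restricted log-likelihood machinery shared by the optimizer and the final
## evaluation; includes metafor's +0.5*log|X'X| constant so reported
## log-likelihoods are directly comparable.
.reml_env <- function(y, v, X, G) {
  k <- length(y); p <- ncol(X)
  Dv <- Matrix::Diagonal(x = v)
  Vpat <- Matrix::forceSymmetric(Reduce(`+`, G, Dv))
  Ch <- Matrix::Cholesky(Vpat, LDL = FALSE)
  ld_xtx <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  const <- -0.5 * (k - p) * log(2 * pi) + 0.5 * ld_xtx
  eval_at <- function(s2) {
    V <- Dv
    for (j in seq_along(G)) V <- V + s2[j] * G[[j]]
    V <- Matrix::forceSymmetric(V)
    ch <- tryCatch(Matrix::update(Ch, V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    ldV <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    ViX <- as.matrix(Matrix::solve(ch, X, system = "A"))
    Viy <- as.numeric(Matrix::solve(ch, y, system = "A"))
    XtViX <- crossprod(X, ViX)
    cx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cx)) return(NULL)
    beta <- backsolve(cx, forwardsolve(t(cx), crossprod(X, Viy)))
    r <- y - as.numeric(X %*% beta)
    Vir <- as.numeric(Matrix::solve(ch, r, system = "A"))
    quad <- sum(r * Vir)
    ld_xtvix <- 2 * sum(log(diag(cx)))
    vb <- chol2inv(cx)
    list(ll = const - 0.5 * (ldV + ld_xtvix + quad),
         beta = as.numeric(beta), vb = vb)
  }
  list(eval_at = eval_at, k = k, p = p)
}

## Optimize the restricted likelihood over the components in `active`
## (others fixed at zero). Returns full-length s2, the log-likelihood and a
## convergence flag.
.reml_optimize <- function(env, m, active, starts) {
  if (!length(active)) {
    at <- env$eval_at(numeric(m))
    return(list(s2 = numeric(m), ll = at$ll, converged = TRUE))
  }
  obj <- function(par) {
    s2 <- numeric(m); s2[active] <- exp(par)
    at <- env$eval_at(s2)
    if (is.null(at) || !is.finite(at$ll)) return(1e10)
    -at$ll
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      nlminb(log(pmax(st[active], 1e-10)), obj,
             lower = log(1e-12), upper = log(1e6),
             control = list(rel.tol = 1e-10, iter.max = 1000,
                            eval.max = 2000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) return(list(s2 = numeric(m), ll = -Inf, converged = FALSE))
  s2 <- numeric(m); s2[active] <- exp(best$par)
  list(s2 = s2, ll = -best$objective,
       converged = best$convergence == 0 ||
         grepl("relative convergence|X-convergence|singular convergence",
               best$message %||% ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a multilevel random-effects meta-analytic model by REML
#'
#' Fits \eqn{y = X\beta + Z_s u_s + Z_t u_t (+ Z_p u_p) + \epsilon} with known
#' sampling variances \eqn{\epsilon_i \sim N(0, v_i)}, random intercepts for
#' study and for treatment nested within study, and optionally a taxon-level
#' random intercept whose correlation matrix comes from a phylogeny
#' ([correlation_from_tree()]). Variance components are estimated by
#' restricted maximum likelihood on the log scale with a multi-start
#' quasi-Newton optimizer; components driven to the boundary are compared
#' against the exactly-constrained fit and reported as exact zeros when that
#' fit is not worse. Fixed effects are the generalized least squares solution
#' at the optimum, with Wald-z confidence intervals and a chi-square omnibus
#' test of all non-intercept coefficients.
#'
#' @param y Effect-size values.
#' @param v Their sampling variances (all positive).
#' @param data Data frame carrying moderator and grouping columns.
#' @param moderator Fixed-effect formula (right-hand side), e.g. `~ guild_pair`
#'   or `~ duration_first`; `NULL` for an intercept-only model.
#' @param random Named character vector mapping random terms to columns;
#'   default `c(study = "study_id", treatment = "treatment_id")` gives the
#'   three-level model. The special column `".row"` denotes one level per
#'   observation. `NULL` drops all random terms (fixed-effects model).
#' @param phylo Optional `list(taxon = <column>, corr = <matrix>)` adding a
#'   correlated taxon intercept with unit-diagonal correlation `corr`.
#' @param level Confidence level for Wald intervals (default 0.95).
#' @return An object of class `seqherb_fit`: coefficients (`beta`, `se`,
#'   `ci_low`, `ci_high`, covariance `vb`), variance components (`vc`),
#'   heterogeneity (`i2`), omnibus test (`qm`, `qm_df`, `qm_p`), prediction
#'   interval for intercept-only fits (`pi_low`, `pi_high`), `reml_loglik`,
#'   `k`, `converged`.
#' @examples
#' d <- data.frame(study_id = c("s1","s1","s2","s3"),
#'                 treatment_id = c("t1","t2","t1","t1"))
#' fit <- fit_multilevel(c(-0.5, -0.2, 0.1, -0.4), rep(0.05, 4), d)
#' fit$beta
#' @export
fit_multilevel <- function(y, v, data = NULL, moderator = NULL,
                           random = c(study = "study_id",
                                      treatment = "treatment_id"),
                           phylo = NULL, level = 0.95) {
  y <- as.numeric(y); v <- as.numeric(v)
  k <- length(y)
  if (length(v) != k) stop("y and v must have the same length")
  if (any(!is.finite(y)) || any(!is.finite(v)) || any(v <= 0))
    stop("all effect values must be finite and all sampling variances positive")
  if (!is.null(data) && nrow(as.data.frame(data)) != k)
    stop("data must have one row per effect size")
  data <- if (is.null(data)) data.frame(row.names = seq_len(k)) else
    as.data.frame(data)

  X <- if (is.null(moderator)) matrix(1, k, 1, dimnames = list(NULL, "(Intercept)"))
       else model.matrix(as.formula(moderator), data)
  if (nrow(X) != k)
    stop("moderator columns contain missing values; subset complete cases first")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("rank-deficient fixed-effect design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  p <- ncol(X)
  zcrit <- .CI_Z(level)

  if (k == 1L) {
    ## single observation: no random structure estimable
    beta <- setNames(y, colnames(X)[1]); se <- sqrt(v)
    return(structure(list(
      beta = beta, se = se, ci_low = beta - zcrit * se,
      ci_high = beta + zcrit * se, vb = matrix(v, 1, 1),
      vc = setNames(numeric(0), character(0)), k = 1L, p = 1L,
      qm = NA_real_, qm_df = NA_integer_, qm_p = NA_real_, i2 = NA_real_,
      pi_low = beta - zcrit * se, pi_high = beta + zcrit * se,
      reml_loglik = NA_real_, converged = TRUE, level = level,
      y = y, v = v, X = X, moderator = moderator,
      random_labels = character(0)),
      class = "seqherb_fit"))
  }

  des <- .random_design(data, random, phylo, k)
  m <- length(des$G)
  env <- .reml_env(y, v, X, des$G)

  if (m == 0L) {
    s2 <- numeric(0); ll_at <- env$eval_at(numeric(0))
    fit <- list(s2 = numeric(0), ll = ll_at$ll, converged = TRUE)
  } else {
    ## profile-based, small, and moderate starts
    w <- 1 / v
    beta_fe <- sum(w * y) / sum(w)
    q0 <- max(mean((y - beta_fe)^2) - mean(v), 1e-3)
    starts <- list(rep(q0 / m, m), rep(1e-3, m), rep(0.5, m))
    fit <- .reml_optimize(env, m, seq_len(m), starts)
    ## boundary handling: components near zero are tested against the
    ## exactly-constrained fit
    near0 <- which(fit$s2 < 1e-7)
    if (length(near0)) {
      keep <- setdiff(seq_len(m), near0)
      cstarts <- lapply(starts, function(s) s)
      cfit <- .reml_optimize(env, m, keep, cstarts)
      if (cfit$ll >= fit$ll - 1e-6) fit <- cfit
    }
  }

  at <- env$eval_at(if (m) fit$s2 else numeric(0))
  beta <- setNames(at$beta, colnames(X))
  se <- setNames(sqrt(pmax(diag(at$vb), 0)), colnames(X))
  vc <- setNames(if (m) fit$s2 else numeric(0), des$labels)
  S <- sum(vc)

  i2 <- if (k >= 2L) 100 * S / (S + .typical_sampling_variance(v)) else NA_real_

  qm <- qm_df <- qm_p <- NA_real_
  nonint <- which(colnames(X) != "(Intercept)")
  if (length(nonint)) {
    wt <- .wald_test(beta, at$vb, nonint)
    qm <- wt$qm; qm_df <- wt$df; qm_p <- wt$p
  }

  intercept_only <- identical(colnames(X), "(Intercept)")
  pi_low <- pi_high <- NA_real_
  if (intercept_only) {
    half <- zcrit * sqrt(se[1]^2 + S)
    pi_low <- unname(beta[1] - half); pi_high <- unname(beta[1] + half)
  }

  structure(list(
    beta = beta, se = se,
    ci_low = beta - zcrit * se, ci_high = beta + zcrit * se,
    vb = at$vb, vc = vc, k = k, p = p,
    qm = qm, qm_df = qm_df, qm_p = qm_p, i2 = i2,
    pi_low = pi_low, pi_high = pi_high,
    reml_loglik = fit$ll, converged = isTRUE(fit$converged), level = level,
    y = y, v = v, X = X, moderator = moderator,
    random_labels = des$labels),
    class = "seqherb_fit")
}

.wald_test <- function(beta, vb, idx) {
  b <- beta[idx]
  Vsub <- vb[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(Vsub), error = function(e)
    stop("singular coefficient covariance in omnibus test"))
  qm <- as.numeric(crossprod(backsolve(ch, b, transpose = TRUE)))
  df <- length(idx)
  list(qm = qm, df = df, p = pchisq(qm, df, lower.tail = FALSE))
}

#' Omnibus moderator test (QM)
#'
#' Wald chi-square test that a subset of coefficients is simultaneously zero,
#' \eqn{Q_M = b' V_b^{-1} b} on `df = |subset|` degrees of freedom. By
#' default all non-intercept coefficients are tested, so for a categorical
#' moderator with L levels fitted with treatment coding, `df = L - 1`.
#'
#' @param fit A `seqherb_fit`.
#' @param which Coefficient names or indices; default all non-intercept terms.
#' @return List with `qm`, `qm_df`, `qm_p`.
#' @export
omnibus_moderator_test <- function(fit, which = NULL) {
  if (!fit$converged) stop("model did not converge; omnibus test unavailable")
  nms <- names(fit$beta)
  idx <- if (is.null(which)) which(nms != "(Intercept)")
         else if (is.character(which)) match(which, nms)
         else as.integer(which)
  if (!length(idx) || anyNA(idx)) stop("empty or unknown coefficient subset")
  wt <- .wald_test(fit$beta, fit$vb, idx)
  list(qm = wt$qm, qm_df = wt$df, qm_p = wt$p)
}

#' Multilevel I-squared
#'
#' Share of total variance attributable to heterogeneity rather than sampling
#' error: \eqn{I^2 = 100\,\Sigma\sigma^2 / (\Sigma\sigma^2 + \tilde{v})} with
#' the typical sampling variance
#' \eqn{\tilde{v} = (k-1)\Sigma w_i / \{(\Sigma w_i)^2 - \Sigma w_i^2\}},
#' \eqn{w_i = 1/v_i}.
#'
#' @param fit A converged `seqherb_fit`.
#' @param v Sampling variances; defaults to those stored in the fit.
#' @return I-squared as a percentage in `[0, 100]`.
#' @export
heterogeneity_i2 <- function(fit, v = NULL) {
  if (!fit$converged) stop("model did not converge")
  v <- if (is.null(v)) fit$v else v
  if (length(v) < 2L) stop("I-squared undefined for fewer than 2 effects")
  S <- sum(fit$vc)
  100 * S / (S + .typical_sampling_variance(v))
}

#' Confidence and prediction interval for the pooled mean
#'
#' For an intercept-only fit, the confidence interval is
#' \eqn{\hat\beta \pm z\,se} and the prediction interval — the range expected
#' to contain the true effect of a new study —
#' \eqn{\hat\beta \pm z\sqrt{se^2 + \Sigma\sigma^2}}.
#'
#' @param fit An intercept-only `seqherb_fit`.
#' @param level Interval level (defaults to the fit's).
#' @return List with elements `estimate`, `ci` (length-2), `pi` (length-2).
#' @export
predict_mean_and_pi <- function(fit, level = fit$level) {
  if (!identical(colnames(fit$X), "(Intercept)"))
    stop("prediction interval is defined for intercept-only fits")
  z <- .CI_Z(level)
  b <- unname(fit$beta[1]); se <- unname(fit$se[1]); S <- sum(fit$vc)
  list(estimate = b,
       ci = c(b - z * se, b + z * se),
       pi = c(b - z * sqrt(se^2 + S), b + z * sqrt(se^2 + S)))
}

#' @export
print.seqherb_fit <- function(x, digits = 4, ...) {
  cat("Multilevel random-effects meta-analytic model (REML)\n")
  cat("k =", x$k, "effect sizes;",
      if (length(x$vc)) paste(length(x$vc), "variance component(s)")
      else "no random terms", "\n")
  if (length(x$vc)) {
    cat("\nVariance components:\n")
    print(round(x$vc, digits))
  }
  cat("\nFixed effects (Wald", paste0(100 * x$level, "%"), "CI):\n")
  tab <- data.frame(estimate = x$beta, se = x$se,
                    ci_low = x$ci_low, ci_high = x$ci_high)
  print(round(tab, digits))
  if (!is.na(x$qm))
    cat("\nQM =", round(x$qm, 3), " df =", x$qm_df,
        " p =", signif(x$qm_p, 3), "\n")
  if (!is.na(x$i2)) cat("I^2 =", round(x$i2, 1), "%\n")
  if (!is.na(x$pi_low))
    cat("95% PI: [", round(x$pi_low, digits), ",",
        round(x$pi_high, digits), "]\n")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}
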