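#' Linear mixed-model ANOVA with Satterthwaite denominator df
#'
#' Fits, by REML, a linear mixed model with the listed fixed factors (all
#' interactions included by default) and a random intercept per level of
#' `random_group`, then reports an F test per fixed term. Factors are
#' sum-to-zero coded and each term is tested through the joint contrast on
#' its coefficients (equivalent to a Type-III test; identical to Type I in
#' the balanced designs produced by this pipeline). Denominator degrees of
#' freedom use the Satterthwaite approximation: per-eigenvector df of the
#' contrast covariance, computed from the gradient of the fixed-effect
#' covariance with respect to the variance parameters and the inverse
#' REML-deviance Hessian — the approximation that yields the fractional
#' denominator dfs customary in this literature. The method is recorded in
#' the result's `ddf_method` attribute.
#'
#' @param data Trial-level data frame (e.g. a filtered trial log).
#' @param response Name of the numeric response column. For accuracy,
#'   either the trial-level 0/1 `correct` indicator or a pre-aggregated
#'   percentage may be used (see `aggregate`).
#' @param fixed Character vector of fixed-factor column names.
#' @param random_group Name of the grouping column for the random
#'   intercept (default `"subject"`); needs >= 2 levels.
#' @param interactions Include all interactions among fixed factors
#'   (default TRUE).
#' @param aggregate If TRUE, average the response within
#'   `random_group` x fixed cells before fitting (the
#'   percentage-per-cell analysis mode); default FALSE (trial level).
#' @return Data frame with one row per fixed term: `term`, `F`, `df1`,
#'   `df2`, `p`. Attributes: `ddf_method`, `formula`, `varcor`. A model
#'   with an (numerically) constant response is flagged `degenerate` with
#'   F = 0.
#' @examples
#' \dontrun{
#' log <- simulate_cohort(5, seed = 1)$results
#' keep <- filter_trials(log)$trials
#' lmm_anova(keep, "correct", c("axis", "dimension"))
#' }
#' @export
lmm_anova <- function(data, response, fixed, random_group = "subject",
                      interactions = TRUE, aggregate = FALSE) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(fixed %in% names(data)), random_group %in% names(data))
  data <- data[stats::complete.cases(data[, c(response, fixed, random_group)]), ]
  data[[response]] <- as.numeric(data[[response]])
  for (f in fixed) data[[f]] <- factor(data[[f]])
  data[[random_group]] <- factor(data[[random_group]])
  if (nlevels(data[[random_group]]) < 2L) {
    stop("degenerate design: need >= 2 levels of '", random_group, "'",
         call. = FALSE)
  }
  for (f in fixed) {
    if (nlevels(data[[f]]) < 2L) {
      stop("degenerate design: factor '", f, "' has < 2 levels", call. = FALSE)
    }
  }
  if (aggregate) {
    data <- stats::aggregate(data[response],
                             data[c(random_group, fixed)], mean)
  }
  op <- if (interactions) " * " else " + "
  fml <- stats::as.formula(paste(
    response, "~", paste(fixed, collapse = op),
    "+ (1 |", random_group, ")"))
  if (stats::sd(data[[response]]) < 1e-12) {
    out <- data.frame(term = fixed, F = 0, df1 = NA_real_, df2 = NA_real_,
                      p = NA_real_)
    attr(out, "degenerate") <- TRUE
    attr(out, "ddf_method") <- "satterthwaite"
    return(out)
  }
  contr <- stats::setNames(rep(list("contr.sum"), length(fixed)), fixed)
  fit <- lme4::lmer(fml, data = data, REML = TRUE,
                    contrasts = contr,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  sw <- satterthwaite_anova(fit)
  attr(sw, "formula") <- deparse(fml)
  attr(sw, "varcor") <- lme4::VarCorr(fit)
  sw
}

# Satterthwaite F table for an lmerMod with any number of scalar variance
# parameters. Variance parameters are handled on the standard-deviation
# scale varpar = c(theta * sigma, sigma); their asymptotic covariance is
# 2 * inverse Hessian of the full (non-profiled) REML deviance.
satterthwaite_anova <- function(fit) {
  fr <- fit@frame
  X <- lme4::getME(fit, "X") # keeps the fit's contrast coding
  reTrms <- lme4::mkReTrms(lme4::findbars(stats::formula(fit)), fr)
  devfun <- lme4::mkLmerDevfun(fr, X, reTrms, REML = TRUE)
  n <- nrow(fr)
  p <- ncol(X)
  theta_hat <- lme4::getME(fit, "theta")
  sigma_hat <- stats::sigma(fit)
  vp_hat <- c(theta_hat * sigma_hat, sigma_hat)
  k <- length(theta_hat)
  rho <- environment(devfun)

  full_dev <- function(vp) { # -2 REML loglik at (sd params, sigma)
    th <- vp[seq_len(k)] / vp[k + 1L]
    s2 <- vp[k + 1L]^2
    dp <- devfun(th)
    pwrss <- rho$pp$sqrL(1) + rho$resp$wrss()
    s2hat <- pwrss / (n - p)
    dp + (n - p) * (log(s2 / s2hat) + s2hat / s2 - 1)
  }
  vcov_beta <- function(vp) {
    th <- vp[seq_len(k)] / vp[k + 1L]
    devfun(th)
    vp[k + 1L]^2 * as.matrix(rho$pp$unsc())
  }

  H <- numDeriv::hessian(full_dev, vp_hat)
  A <- tryCatch(2 * solve(H), error = function(e) NULL)
  Vb <- vcov_beta(vp_hat)
  beta <- lme4::fixef(fit)
  asgn <- attr(X, "assign")
  labs <- attr(stats::terms(fit), "term.labels")
  resid_df <- n - p # fallback when the variance-parameter Hessian is singular

  rows <- lapply(seq_along(labs), function(j) {
    idx <- which(asgn == j)
    q <- length(idx)
    L <- matrix(0, q, length(beta))
    L[cbind(seq_len(q), idx)] <- 1
    C <- L %*% Vb %*% t(L)
    Fstat <- drop(t(beta[idx]) %*% solve(C, beta[idx])) / q
    df2 <- satterthwaite_df(L, C, vp_hat, vcov_beta, A)
    if (is.na(df2)) df2 <- resid_df
    data.frame(term = labs[j], F = Fstat, df1 = q, df2 = df2,
               p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ddf_method") <- "satterthwaite"
  out
}

# Per-eigenvector Satterthwaite df for the q-dimensional contrast L,
# combined into a single denominator df (harmonization used by standard
# mixed-model software). A is the covariance of the variance parameters;
# when unavailable (singular Hessian) fall back to the residual df.
satterthwaite_df <- function(L, C, vp_hat, vcov_beta, A) {
  q <- nrow(L)
  if (is.null(A)) return(NA_real_)
  ed <- eigen(C, symmetric = TRUE)
  nu <- vapply(seq_len(q), function(i) {
    if (ed$values[i] <= 0) return(NA_real_)
    li <- drop(t(ed$vectors[, i]) %*% L)
    g <- numDeriv::grad(function(vp) {
      drop(li %*% vcov_beta(vp) %*% li)
    }, vp_hat)
    denom <- drop(t(g) %*% A %*% g)
    if (denom <= 0) return(NA_real_)
    2 * ed$values[i]^2 / denom
  }, numeric(1))
  nu <- nu[!is.na(nu)]
  if (!length(nu)) return(NA_real_)
  E <- sum(nu[nu > 2] / (nu[nu > 2] - 2))
  if (E <= q) return(Inf)
  2 * E / (E - q)
}
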