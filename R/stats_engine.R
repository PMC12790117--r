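# Self-contained statistical machinery: 2x2 odds ratios with Wald intervals,
# Pearson chi-square, Wilcoxon rank-sum (exact below a cutoff, tie-corrected
# normal approximation above), and logistic regression via iteratively
# reweighted least squares. These are authored here rather than delegated so
# that every numerical step of the analysis is auditable; the base-R
# equivalents serve as independent cross-checks in the test suite.

as_two_by_two <- function(t) {
  if (is.matrix(t)) t <- as.vector(t(t))
  if (length(t) != 4L || any(t < 0) || any(t != round(t))) {
    stop("a 2x2 table needs four nonnegative integer counts (a, b, c, d)")
  }
  if (sum(t) == 0) stop("empty 2x2 table")
  as.numeric(t)
}

#' Odds ratio with Wald confidence interval
#'
#' For counts (a, b, c, d) = (exposed-event, exposed-nonevent,
#' unexposed-event, unexposed-nonevent): OR = ad/bc with
#' CI = exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). Zero cells are an
#' error by default; opt in to the Haldane-Anscombe +0.5 continuity
#' correction explicitly rather than silently.
#'
#' @param t counts as a length-4 vector (a, b, c, d) or a 2x2 matrix read
#'   row-wise.
#' @param config run configuration (confidence level).
#' @param correction apply +0.5 to every cell (default \code{FALSE}).
#' @return list with \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{log_or}, \code{se}.
#' @export
#' @examples
#' odds_ratio(c(26, 404, 26, 307))$or  # ~0.76
odds_ratio <- function(t, config = default_config(), correction = FALSE) {
  t <- as_two_by_two(t)
  if (any(t == 0)) {
    if (!correction) {
      stop("zero cell in 2x2 table; rerun with correction = TRUE for the ",
           "Haldane-Anscombe +0.5 adjustment")
    }
    t <- t + 0.5
  }
  a <- t[1]; b <- t[2]; cc <- t[3]; d <- t[4]
  log_or <- log(a * d) - log(b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  list(or = exp(log_or),
       ci_low = exp(log_or - z * se),
       ci_high = exp(log_or + z * se),
       log_or = log_or, se = se)
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic (no continuity correction), df = (r-1)(c-1),
#' upper-tail p-value.
#'
#' @param tab r x c matrix of counts with positive margins.
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{expected}.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in contingency table")
  expected <- outer(rs, cs) / sum(tab)
  statistic <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
       expected = expected)
}

# exact two-sided Mann-Whitney p by enumeration of all rank subsets;
# valid only without ties
wilcoxon_exact_p <- function(u_obs, nx, ny) {
  n <- nx + ny
  splits <- utils::combn(n, nx)
  us <- colSums(matrix(seq_len(n)[splits], nrow = nx)) - nx * (nx + 1) / 2
  pl <- mean(us <= u_obs)
  pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties. Below the exact cutoff (combined n <= 14) and without
#' ties, the two-sided p-value is computed by full enumeration of rank
#' assignments; otherwise a normal approximation with tie-corrected variance
#' and 0.5 continuity correction is used. If every value is tied across both
#' samples the test is degenerate and p = 1.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_cutoff largest combined sample size for exact enumeration
#'   (default 14).
#' @return list with \code{statistic} (Mann-Whitney U for \code{x}),
#'   \code{p_value}, \code{method}, \code{degenerate}.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_cutoff = 14) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))  # midranks
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && n <= exact_cutoff) {
    return(list(statistic = u, p_value = wilcoxon_exact_p(u, nx, ny),
                method = "exact", degenerate = FALSE))
  }
  mu <- nx * ny / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- nx * ny / 12 * (n + 1 - tie_term)
  if (v <= 0) {
    return(list(statistic = u, p_value = 1, method = "normal",
                degenerate = TRUE))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
  list(statistic = u, p_value = 2 * stats::pnorm(-abs(z)),
       method = "normal", degenerate = FALSE)
}

log_likelihood <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Newton/IRLS from a zero start with step-halving on likelihood decrease,
#' iterated to a gradient norm of at most \code{tol} (default 1e-8) or 50
#' iterations. The Wald covariance is the inverse Fisher information at the
#' optimum. Rank-deficient designs are an error naming the dependent
#' columns; quasi-separation (diverging coefficients) is flagged, never
#' silently reported as converged.
#'
#' @param design n x p numeric model matrix including the intercept column.
#' @param outcome binary 0/1 vector of length n.
#' @param config run configuration (confidence level).
#' @param tol convergence tolerance on the max absolute score (default 1e-8).
#' @param max_iter iteration cap (default 50).
#' @return object of class \code{"respaudit_fit"}: coefficients on the
#'   log-odds scale, Wald covariance, per-coefficient OR with CI,
#'   convergence and separation diagnostics.
#' @export
#' @examples
#' trigger <- c(rep(1, 430), rep(0, 333))
#' died <- c(rep(1, 26), rep(0, 404), rep(1, 26), rep(0, 307))
#' fit <- logistic_fit(cbind(1, trigger), died)
#' fit$or_ci["trigger", ]  # matches odds_ratio(c(26, 404, 26, 307))
logistic_fit <- function(design, outcome, config = default_config(),
                         tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(design)
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than parameters")
  if (is.null(colnames(X))) colnames(X) <- rep("", p)
  unnamed <- colnames(X) == ""
  colnames(X)[unnamed] <- paste0("x", seq_len(p))[unnamed]
  qrx <- qr(X)
  if (qrx$rank < p) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("rank-deficient design; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  beta <- rep(0, p)
  ll <- log_likelihood(X, y, beta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- stats::plogis(drop(X %*% beta))
    grad <- drop(crossprod(X, y - mu))
    if (max(abs(grad)) <= tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    w <- pmax(mu * (1 - mu), .Machine$double.eps)
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving on likelihood decrease
    shrink <- 1
    repeat {
      cand <- beta + shrink * step
      ll_new <- log_likelihood(X, y, cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      shrink <- shrink / 2
      if (shrink < 1e-10) { cand <- beta; ll_new <- ll; break }
    }
    beta <- cand
    ll <- ll_new
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  info <- crossprod(X * w, X)
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(cov))
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  or_ci <- cbind(or = exp(beta), ci_low = exp(beta - z * se),
                 ci_high = exp(beta + z * se))
  rownames(or_ci) <- colnames(X)
  names(beta) <- colnames(X)
  dimnames(cov) <- list(colnames(X), colnames(X))
  separation <- any(abs(beta) > 15) || !converged
  structure(list(
    coefficients = beta,
    cov = cov,
    se = se,
    or_ci = or_ci,
    converged = converged,
    n_iter = iter,
    loglik = ll,
    n = n,
    ci_level = config$ci_level,
    diagnostics = list(quasi_separation = separation && any(abs(beta) > 15),
                       non_convergence = !converged)
  ), class = "respaudit_fit")
}

#' @export
coef.respaudit_fit <- function(object, ...) object$coefficients

#' @export
vcov.respaudit_fit <- function(object, ...) object$cov

#' @export
logLik.respaudit_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
confint.respaudit_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- object$coefficients
  ci <- cbind(b - z * object$se, b + z * object$se)
  colnames(ci) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.respaudit_fit <- function(object, newdata,
                                  type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- drop(as.matrix(newdata) %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
print.respaudit_fit <- function(x, digits = 3, ...) {
  cat("Logistic regression (IRLS),", x$n, "observations\n")
  print(round(x$or_ci, digits))
  if (!x$converged) cat("WARNING: did not converge in", x$n_iter, "iterations\n")
  if (x$diagnostics$quasi_separation) cat("WARNING: quasi-separation detected\n")
  invisible(x)
}

#' @export
summary.respaudit_fit <- function(object, ...) {
  b <- object$coefficients
  z <- b / object$se
  tab <- cbind(estimate = b, se = object$se, z = z,
               p_value = 2 * stats::pnorm(-abs(z)),
               or = object$or_ci[, "or"],
               ci_low = object$or_ci[, "ci_low"],
               ci_high = object$or_ci[, "ci_high"])
  structure(list(table = tab, converged = object$converged,
                 n_iter = object$n_iter, loglik = object$loglik,
                 n = object$n, diagnostics = object$diagnostics),
            class = "summary.respaudit_fit")
}

#' @export
print.summary.respaudit_fit <- function(x, digits = 3, ...) {
  cat("Logistic regression (IRLS)\n")
  cat("n =", x$n, " log-likelihood =", format(x$loglik, digits = 6),
      " iterations =", x$n_iter, "\n")
  print(round(x$table, digits))
  invisible(x)
}

drop_constant_columns <- function(X, keep = "(Intercept)") {
  const <- apply(X, 2, function(v) length(unique(v)) < 2L)
  const[colnames(X) %in% keep] <- FALSE
  if (any(const)) {
    warning("covariate(s) without contrast dropped: ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  X
}

#' Resource-bundle mortality model
#'
#' In-hospital death regressed on treatment at an intermediate-or-less
#' resource site, unadjusted and adjusted for site confounders: average
#' daily census above 50 patients, PICU availability, and academic center
#' designation.
#'
#' @param cohort hypoxemic cohort rows (needs \code{site_id}, \code{died}).
#' @param classifications site bundle classifications ([classify_sites()]).
#' @param sites validated site table.
#' @param config run configuration.
#' @return list of class \code{"respaudit_orfit"}: \code{unadjusted} and
#'   \code{adjusted} \code{respaudit_fit}s plus \code{exposure_or}, a
#'   two-row OR/CI summary for the exposure.
#' @export
fit_bundle_mortality_model <- function(cohort, classifications, sites,
                                       config = default_config()) {
  mC <- match(cohort$site_id, classifications$site_id)
  mS <- match(cohort$site_id, sites$site_id)
  if (anyNA(mC) || anyNA(mS)) {
    stop("join error: cohort site_id(s) missing from classifications or sites")
  }
  exposure <- as.numeric(classifications$group[mC] == "INTERMEDIATE_OR_LESS")
  if (length(unique(exposure)) < 2L) {
    stop("no contrast: every patient has the same bundle-group exposure")
  }
  y <- as.numeric(cohort$died %in% TRUE)
  X_un <- cbind("(Intercept)" = 1, low_resource = exposure)
  X_adj <- cbind(X_un,
                 census_gt50 = as.numeric(sites$census_gt50[mS] %in% TRUE),
                 picu = as.numeric(sites$picu[mS] %in% TRUE),
                 academic = as.numeric(sites$academic[mS] %in% TRUE))
  X_adj <- drop_constant_columns(X_adj)
  un <- logistic_fit(X_un, y, config)
  adj <- logistic_fit(X_adj, y, config)
  new_orfit(un, adj, "low_resource")
}

#' PARDS-trigger mortality model
#'
#' In-hospital death regressed on the presence of a PARDS trigger,
#' unadjusted and adjusted for age at or under 5 years, malnutrition,
#' LODS above 0, and site resource availability (bundle dichotomy).
#'
#' @param cohort hypoxemic cohort with score columns: \code{died},
#'   \code{has_trigger}, \code{age_years}, \code{malnourished},
#'   \code{lods}, and \code{bundle_group} (the site dichotomy).
#' @param config run configuration.
#' @return list of class \code{"respaudit_orfit"} as in
#'   [fit_bundle_mortality_model()].
#' @export
fit_trigger_mortality_model <- function(cohort, config = default_config()) {
  exposure <- as.numeric(cohort$has_trigger %in% TRUE)
  if (length(unique(exposure)) < 2L) {
    stop("no contrast: every patient has the same trigger exposure")
  }
  y <- as.numeric(cohort$died %in% TRUE)
  X_un <- cbind("(Intercept)" = 1, trigger = exposure)
  X_adj <- cbind(X_un,
                 age_le5 = as.numeric(!is.na(cohort$age_years) &
                                        cohort$age_years <= 5),
                 malnutrition = as.numeric(cohort$malnourished %in% TRUE),
                 lods_gt0 = as.numeric(!is.na(cohort$lods) & cohort$lods > 0),
                 low_resource = as.numeric(cohort$bundle_group ==
                                             "INTERMEDIATE_OR_LESS"))
  X_adj <- drop_constant_columns(X_adj)
  un <- logistic_fit(X_un, y, config)
  adj <- logistic_fit(X_adj, y, config)
  new_orfit(un, adj, "trigger")
}

new_orfit <- function(unadjusted, adjusted, exposure) {
  tab <- rbind(unadjusted = unadjusted$or_ci[exposure, ],
               adjusted = adjusted$or_ci[exposure, ])
  structure(list(unadjusted = unadjusted, adjusted = adjusted,
                 exposure = exposure, exposure_or = tab),
            class = "respaudit_orfit")
}

#' @export
print.respaudit_orfit <- function(x, digits = 3, ...) {
  cat("Mortality model; exposure:", x$exposure, "\n")
  print(round(x$exposure_or, digits))
  invisible(x)
}
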