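# Independent oracles, deliberately written without reference to the package
# internals they cross-check.

# one-sided P(U <= u_obs) and two-sided p by brute-force enumeration of all
# choose(nx+ny, nx) rank assignments (no ties)
oracle_wilcoxon <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  us <- apply(combn(n, nx), 2, function(ix) sum(ix) - nx * (nx + 1) / 2)
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  list(u = u_obs, p_lower = lower, p_upper = upper,
       p_two_sided = min(1, 2 * min(lower, upper)))
}

# direct likelihood maximization, independent of IRLS
oracle_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  opt$par
}

# trigger grouping re-derived from first principles for the enumeration test
oracle_trigger_group <- function(dx_set) {
  lrti <- c("pneumonia", "bronchiolitis", "covid19")
  other <- c("aspiration", "drowning", "other_shock")
  if (any(dx_set %in% lrti)) "LRTI"
  else if ("sepsis" %in% dx_set) "SEPSIS"
  else if ("trauma" %in% dx_set) "TRAUMA"
  else if (any(dx_set %in% other)) "OTHER"
  else "NONE"
}
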