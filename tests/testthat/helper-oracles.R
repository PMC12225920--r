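# Independent oracles used to check the analysis implementations.

# Mann-Whitney U of x by exhaustive pairwise enumeration (half-credit ties)
u_enumerate <- function(x, y) {
  s <- 0
  for (xi in x) for (yi in y) s <- s + (xi > yi) + 0.5 * (xi == yi)
  s
}

# Bernoulli log-likelihood of a logit model at coefficients beta
logit_ll <- function(beta, X, yy) {
  eta <- as.numeric(X %*% beta)
  sum(yy * eta - log1p(exp(eta)))
}

# brute-force ML logit fit by Nelder-Mead (for problems with <= 2 coefficients)
brute_logit <- function(X, yy) {
  stopifnot(ncol(X) <= 2L)
  opt <- stats::optim(rep(0, ncol(X)), function(b) -logit_ll(b, X, yy),
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(coef = opt$par, loglik = -opt$value)
}

# classical balanced two-way ANOVA sums of squares, computed from cell means
balanced_anova_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- table(a, b)
  stopifnot(length(unique(as.vector(n))) == 1L)  # balanced only
  m <- mean(y)
  ma <- tapply(y, a, mean)
  mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  r <- n[1L, 1L]
  ss_a <- r * nlevels(b) * sum((ma - m)^2)
  ss_b <- r * nlevels(a) * sum((mb - m)^2)
  ss_ab <- r * sum((mab - outer(ma, mb, "+") + m)^2)
  ss_res <- sum((y - mab[cbind(a, b)])^2)
  list(a = ss_a, b = ss_b, ab = ss_ab, res = ss_res,
       total = sum((y - m)^2))
}

# closed-form properties of the peak-normalised biexponential EPSP kernel
biexp_truth <- function(amp, tau_rise, tau_decay) {
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  pk <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  list(peak_time_ms = tp,
       integral_mvs = amp / pk * (tau_decay - tau_rise) / 1000)
}
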