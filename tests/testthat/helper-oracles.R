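# independent closed-form OLS via the normal equations (oracle for fit_curve)
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = 1 - ss_res / ss_tot)
}

# vector with exact sample mean and sd (n-1), arbitrary stochastic shape
with_moments <- function(n, mean, sd) {
  x <- stats::rnorm(n)
  z <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * z
}

# normal-theory expectation factor of the sample SD, E[s] = c4(n) * sigma
c4 <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)

# relative variance of the OLS slope under multiplicative noise of CV `cv`
# with `m` replicate injections averaged per level (delta method)
slope_relvar <- function(levels, cv, m) {
  (cv^2 / m) * sum((levels - mean(levels))^2 * levels^2) /
    sum((levels - mean(levels))^2)^2
}

random_formula <- function() {
  tab <- atomic_mass_table()$masses
  syms <- sample(names(tab), sample(1:5, 1))
  elemental_formula(stats::setNames(sample(1:30, length(syms), replace = TRUE),
                                    syms))
}
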