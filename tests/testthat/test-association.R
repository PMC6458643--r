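# Brute-force oracles for the regression machinery, kept deliberately
# independent of stats::cor.test / lm / glm.
bf_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2))
}
bf_ols <- function(X, y) {
  Xd <- cbind(1, X)
  solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
}

test_that("pearson matches the brute-force formula to 1e-12", {
  set.seed(51)
  for (i in 1:25) {
    x <- rnorm(30); y <- rnorm(30) + 0.4 * x
    a <- pearson_assoc(x, y); b <- bf_pearson(x, y)
    expect_equal(a$r, b$r, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
  # exact line: r = 1, p ~ 0
  x <- 1:10
  a <- pearson_assoc(x, 2 * x + 1)
  expect_equal(a$r, 1, tolerance = 1e-12)
  expect_lt(a$p, 1e-12)
  # the 4-point configuration {(1,2),(2,1),(3,4),(4,3)} by hand:
  # covariance 3, both SS 5, hence r = 3/5
  a4 <- pearson_assoc(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(a4$r, 0.6, tolerance = 1e-12)
  expect_equal(a4$r, bf_pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))$r,
               tolerance = 1e-12)
  # independence at large n keeps |r| small
  set.seed(52)
  expect_lt(abs(pearson_assoc(rnorm(1e4), rnorm(1e4))$r), 0.05)
  expect_error(pearson_assoc(rep(1, 10), rnorm(10)), "variance")
})

test_that("multivariable OLS is exact on noiseless data and orthogonalises
           residuals", {
  set.seed(53)
  X <- cbind(x1 = rnorm(40), x2 = rnorm(40))
  y <- 1 + 2 * X[, 1] - 3 * X[, 2]
  fit <- suppressWarnings(ols_multi(X, y))  # lm flags the perfect fit
  expect_equal(unname(fit$coefficients), c(1, 2, -3), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # brute-force normal equations agree on noisy data
  y2 <- y + rnorm(40)
  fit2 <- ols_multi(X, y2)
  expect_equal(unname(fit2$coefficients), unname(bf_ols(X, y2)),
               tolerance = 1e-8)
  # residual orthogonality to the design
  e <- y2 - cbind(1, X) %*% fit2$coefficients
  expect_lt(max(abs(t(cbind(1, X)) %*% e)), 1e-8 * max(abs(y2)) * 40)
  # single covariate: r^2 equals squared pearson r
  one <- ols_multi(X[, 1, drop = FALSE], y2)
  expect_equal(one$r_squared, pearson_assoc(X[, 1], y2)$r^2,
               tolerance = 1e-12)
  # null design: r^2 stays near zero at large n
  set.seed(54)
  Xn <- matrix(rnorm(3e4), ncol = 3)
  expect_lt(ols_multi(Xn, rnorm(1e4))$r_squared, 0.01)
  # collinearity is an error naming the offender
  Xc <- cbind(a = X[, 1], b = 2 * X[, 1])
  expect_error(ols_multi(Xc, y), "collinear")
})

test_that("logistic regression recovers a known slope and handles edge
           designs", {
  set.seed(55)
  x <- rnorm(5000)
  y <- rbinom(5000, 1, plogis(-0.5 + 1.5 * x))
  fit <- logistic_assoc(y, cbind(x = x))
  expect_equal(unname(fit$coefficients["x"]), 1.5, tolerance = 0.1)
  expect_true(fit$converged)
  # constant covariate: slope 0, intercept = logit of prevalence
  y2 <- rbinom(200, 1, 0.3)
  fit2 <- logistic_assoc(y2, cbind(x = rep(2, 200)))
  expect_equal(unname(fit2$coefficients["x"]), 0)
  expect_equal(unname(fit2$coefficients["(Intercept)"]),
               qlogis(mean(y2)), tolerance = 1e-6)
  # perfect separation is flagged
  xs <- c(rnorm(30, -4), rnorm(30, 4))
  ys <- rep(c(0, 1), each = 30)
  expect_warning(fit3 <- logistic_assoc(ys, cbind(x = xs)),
                 "converge|separation|fitted")
  expect_false(fit3$converged)
  expect_error(logistic_assoc(rep(1, 10), cbind(x = rnorm(10))), "classes")
})

test_that("the normality screen log-transforms only positive non-normal
           columns", {
  set.seed(56)
  norm60 <- rnorm(60)
  out <- log_transform_if_nonnormal(norm60)
  expect_false(out$transformed)
  expect_identical(out$values, norm60)
  ln60 <- exp(rnorm(60, sd = 1.2))
  out2 <- log_transform_if_nonnormal(ln60)
  expect_true(out2$transformed)
  expect_gt(shapiro.test(out2$values)$p.value, 0.05)
  withzero <- c(0, exp(rnorm(59, sd = 1.5)))
  expect_warning(out3 <- log_transform_if_nonnormal(withzero),
                 "non-positive")
  expect_false(out3$transformed)
})

test_that("the association table has the study layout and finds the built-in
           links", {
  rep <- suppressWarnings(run_study(study_config(n_subjects = 50, seed = 57,
                                                 run_model1d = FALSE)))
  tab <- rep$assoc
  expect_identical(rownames(tab$r),
                   c(paste0("pc_curv", 1:5), paste0("pc_rad", 1:5),
                     "coarctation_index", "arch_index"))
  expect_identical(colnames(tab$r),
                   c("c_SBP", "p_SBP", "TACi", "BCW", "FCW", "LVMi",
                     "LVEF"))
  expect_identical(tab$multiplicity_adjustment, "none")
  # BCW is generated from radius-mode weights: at least one radius PC cell
  # significant, and no more curvature-BCW cells than chance would allow
  expect_true(any(tab$significant[paste0("pc_rad", 1:5), "BCW"]))
  expect_lte(sum(tab$significant[paste0("pc_curv", 1:5), "BCW"]), 2)
})

test_that("null cohorts produce about 5% significant cells", {
  set.seed(58)
  hits <- 0; cells <- 0
  for (i in 1:40) {
    df <- as.data.frame(matrix(rnorm(30 * 12), ncol = 12))
    names(df) <- c(paste0("pc_curv", 1:5), paste0("pc_rad", 1:5),
                   "coarctation_index", "arch_index")
    df2 <- as.data.frame(matrix(rnorm(30 * 7), ncol = 7))
    names(df2) <- c("c_SBP", "p_SBP", "TACi", "BCW", "FCW", "LVMi", "LVEF")
    tab <- suppressWarnings(table1(cbind(df, df2)))
    hits <- hits + sum(tab$significant)
    cells <- cells + length(tab$significant)
  }
  expect_gt(hits / cells, 0.02)
  expect_lt(hits / cells, 0.09)
})
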