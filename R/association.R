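#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] returning the correlation
#' coefficient and the two-sided p-value from the t statistic
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List with `r` and `p`.
#' @export
pearson_assoc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors with at least 3 observations")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Multivariable linear regression summary
#'
#' Ordinary least squares with intercept via [stats::lm()]; reports
#' coefficients, r-squared, the overall F-test p-value and per-coefficient
#' two-sided Wald t p-values. Rank deficiency is an error naming the
#' collinear columns.
#'
#' @param X Numeric covariate matrix (columns named).
#' @param y Response vector.
#' @return List with `coefficients`, `r_squared`, `p_overall`, `p_coef`
#'   (excluding the intercept entry in neither).
#' @export
ols_multi <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (n <= p + 1L) stop("need n > p + 1 observations")
  qx <- qr(cbind(1, X))
  if (qx$rank < p + 1L) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, p + 1L)] - 1L]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")))
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  p_overall <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  list(coefficients = stats::coef(fit),
       r_squared = sm$r.squared,
       p_overall = p_overall,
       p_coef = sm$coefficients[, "Pr(>|t|)"])
}

#' Logistic regression of a binary label on covariates
#'
#' Maximum-likelihood fit via [stats::glm()] (iteratively reweighted least
#' squares). Perfect separation or non-convergence triggers a warning and is
#' flagged in the result.
#'
#' @param y Binary (0/1 or logical) response; both classes must be present.
#' @param x Numeric covariate vector or matrix.
#' @return List with `coefficients`, `p_wald` (per coefficient) and
#'   `converged`.
#' @export
logistic_assoc <- function(y, x) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  df <- data.frame(y = y, X, check.names = FALSE)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge",
                conditionMessage(w))) sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  aliased <- is.na(cf)
  cf[aliased] <- 0  # constant/collinear covariates carry no effect
  conv <- fit$converged && !sep_warn && max(abs(cf)) < 1e3
  if (!conv) warning("logistic fit did not converge (possible separation)")
  sm <- summary(fit)
  p_wald <- stats::setNames(rep(NA_real_, length(cf)), names(cf))
  p_wald[rownames(sm$coefficients)] <- sm$coefficients[, "Pr(>|z|)"]
  list(coefficients = cf, p_wald = p_wald, converged = conv)
}

#' Log-transform a variable if a normality screen rejects
#'
#' Applies a Shapiro-Wilk normality test at `test_alpha`; when normality is
#' rejected and all values are strictly positive, the natural logarithm is
#' taken and the transform is flagged (the flag is what marks the variable in
#' the association table). Non-positive values block the transform with a
#' warning.
#'
#' @param x Numeric vector.
#' @param test_alpha Significance level of the normality screen.
#' @return List with `values`, `transformed` (logical) and `p_normality`.
#' @export
log_transform_if_nonnormal <- function(x, test_alpha = 0.05) {
  p <- stats::shapiro.test(x)$p.value
  if (p >= test_alpha) {
    return(list(values = x, transformed = FALSE, p_normality = p))
  }
  if (any(x <= 0)) {
    warning("non-normal variable contains non-positive values; left untransformed")
    return(list(values = x, transformed = FALSE, p_normality = p))
  }
  list(values = log(x), transformed = TRUE, p_normality = p)
}

#' Shape-haemodynamics univariable association table
#'
#' Pearson r and p for every pair of shape variable (rows: the five curvature
#' and five radius component weights plus the coarctation and arch indices)
#' and haemodynamic/structural variable (columns: c_SBP, p_SBP, TACi, BCW,
#' FCW, LVMi, LVEF). Each analysed column is screened for normality and
#' log-transformed when rejected (and positive), with transformed variables
#' flagged. Significance is marked at p < 0.05 with *no* multiplicity
#' adjustment; this choice is recorded in the table metadata.
#'
#' @param cohort Data frame with the shape and haemodynamic columns. Row
#'   variables default to `pc_curv1..5`, `pc_rad1..5`, `coarctation_index`,
#'   `arch_index`; column variables to `c_SBP`, `p_SBP`, `TACi`, `BCW`,
#'   `FCW`, `LVMi`, `LVEF`.
#' @param row_vars,col_vars Optional overrides of the variable sets.
#' @param alpha Significance threshold for marking.
#' @return Object of class `assoc_table`: list with matrices `r`, `p`,
#'   `significant`, logical vectors `transformed_rows`/`transformed_cols`,
#'   and metadata `multiplicity_adjustment = "none"`.
#' @export
table1 <- function(cohort,
                   row_vars = c(paste0("pc_curv", 1:5), paste0("pc_rad", 1:5),
                                "coarctation_index", "arch_index"),
                   col_vars = c("c_SBP", "p_SBP", "TACi", "BCW", "FCW",
                                "LVMi", "LVEF"),
                   alpha = 0.05) {
  miss <- setdiff(c(row_vars, col_vars), names(cohort))
  if (length(miss)) {
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyNA(cohort[, c(row_vars, col_vars)])) {
    stop("analysed columns must not contain missing values")
  }
  screen <- function(vars) {
    out <- lapply(cohort[vars], log_transform_if_nonnormal)
    list(values = lapply(out, `[[`, "values"),
         flag = vapply(out, `[[`, logical(1), "transformed"))
  }
  rows <- screen(row_vars); cols <- screen(col_vars)
  r <- p <- matrix(NA_real_, length(row_vars), length(col_vars),
                   dimnames = list(row_vars, col_vars))
  for (i in seq_along(row_vars)) {
    for (j in seq_along(col_vars)) {
      pr <- pearson_assoc(rows$values[[i]], cols$values[[j]])
      r[i, j] <- pr$r; p[i, j] <- pr$p
    }
  }
  structure(list(r = r, p = p, significant = p < alpha,
                 transformed_rows = rows$flag, transformed_cols = cols$flag,
                 alpha = alpha, n = nrow(cohort),
                 multiplicity_adjustment = "none"),
            class = "assoc_table")
}

#' @export
print.assoc_table <- function(x, digits = 3, ...) {
  cat(sprintf("Univariable associations (n = %d, Pearson r / p, * p < %g, no multiplicity adjustment)\n",
              x$n, x$alpha))
  cells <- matrix(sprintf("%s%.*f (p=%.3f)",
                          ifelse(x$significant, "*", " "), digits, x$r, x$p),
                  nrow = nrow(x$r), dimnames = dimnames(x$r))
  rn <- rownames(cells)
  rn[x$transformed_rows] <- paste0(rn[x$transformed_rows], "^log")
  rownames(cells) <- rn
  print(cells, quote = FALSE)
  if (any(x$transformed_cols)) {
    cat("log-transformed columns:",
        paste(colnames(x$r)[x$transformed_cols], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an association table as CSV
#'
#' One row per (shape variable, haemodynamic variable) pair with r, p,
#' significance and transform flags.
#'
#' @param tab An [table1()] result.
#' @param path Output path.
#' @export
write_assoc_csv <- function(tab, path) {
  long <- expand.grid(shape = rownames(tab$r), variable = colnames(tab$r),
                      stringsAsFactors = FALSE)
  long$r <- as.numeric(tab$r)
  long$p <- as.numeric(tab$p)
  long$significant <- as.logical(tab$significant)
  long$shape_log_transformed <- tab$transformed_rows[long$shape]
  long$variable_log_transformed <- tab$transformed_cols[long$variable]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
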