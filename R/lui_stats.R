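# Land-use intensity index (first PCA axis of standardized management
# criteria) and per-metric linear mixed models m ~ LUI + (1 | site).

#' Multicriteria land-use intensity index
#'
#' Criteria are z-scored per column (zero-variance columns dropped with a
#' warning), a PCA is computed, and the field scores on the first axis form
#' the LUI index. The axis sign is oriented so that the anchor criterion
#' (mineral N input by default, else the first retained column) loads
#' positively: higher scores mean more intensive management.
#'
#' @param criteria data.frame with `field_id` (and optionally `site_id`)
#'   plus one numeric column per criterion; or a numeric matrix with field
#'   row names.
#' @param anchor criterion name anchoring the sign convention.
#' @return list of class `lui_result`: scores (named by field, mean 0),
#'   loadings, variance_explained_axis1, dropped (zero-variance criteria).
#' @export
lui_index <- function(criteria, anchor = "n_mineral") {
  if (is.data.frame(criteria)) {
    id_cols <- intersect(c("field_id", "site_id"), names(criteria))
    fields <- if ("field_id" %in% id_cols) criteria$field_id
    else rownames(criteria)
    X <- as.matrix(criteria[, setdiff(names(criteria), id_cols), drop = FALSE])
    rownames(X) <- fields
  } else {
    X <- as.matrix(criteria)
  }
  if (nrow(X) < 2) stop("need at least two fields")
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | is.na(sds)]
  if (length(dropped) > 0) {
    warning("dropping zero-variance criteria: ", paste(dropped, collapse = ", "))
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
  }
  if (ncol(X) < 2) stop("need at least two non-constant criteria")
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  scores <- as.numeric(Z %*% load1)
  anchor_col <- if (anchor %in% names(load1)) anchor else names(load1)[1]
  if (load1[anchor_col] < 0) {
    load1 <- -load1
    scores <- -scores
  }
  structure(list(scores = stats::setNames(scores, rownames(X)),
                 loadings = load1,
                 variance_explained_axis1 = pc$sdev[1]^2 / sum(pc$sdev^2),
                 dropped = dropped),
            class = "lui_result")
}

#' Fit the per-metric mixed model m ~ LUI + (1 | site)
#'
#' Gaussian linear mixed model with a fixed LUI slope and a random site
#' intercept (REML by default), fitted with lme4. The Wald t statistic is
#' referred to a Student t distribution with Satterthwaite denominator
#' degrees of freedom (computed from the REML information of the two variance
#' components), which keeps the test calibrated in small between-site designs
#' where LUI varies mostly among sites. The standardized effect size (SES) is
#' the slope of the same model refitted on z-scored response and predictor. If
#' the random-effect fit fails (e.g. zero residual variance in noiseless
#' data) the model degrades gracefully to ordinary least squares with site
#' variance 0. Fields with missing response are dropped; fewer than 4
#' complete fields is an error.
#'
#' @param y numeric field-level metric values (may contain NA).
#' @param lui numeric LUI scores, same length/order.
#' @param site site labels, same length/order.
#' @param reml use REML (default) or ML.
#' @return list of class `mixed_model_result`: slope, slope_se, p_value, ses,
#'   site_variance, residual_variance, n, method.
#' @export
fit_mixed_model <- function(y, lui, site, reml = TRUE) {
  ok <- stats::complete.cases(y, lui, site)
  n_dropped <- sum(!ok)
  y <- y[ok]; lui <- lui[ok]; site <- as.character(site[ok])
  if (length(y) < 4) stop("fewer than 4 complete fields")
  if (length(unique(site)) < 2) stop("need at least two sites")
  fit1 <- .lmm_slope(y, lui, site, reml)
  zy <- as.numeric(scale(y)); zx <- as.numeric(scale(lui))
  ses <- .lmm_slope(zy, zx, site, reml)$slope
  structure(list(slope = fit1$slope, slope_se = fit1$se, p_value = fit1$p,
                 df = fit1$df,
                 ses = ses, site_variance = fit1$site_var,
                 residual_variance = fit1$resid_var,
                 n = length(y), n_dropped = n_dropped,
                 method = fit1$method),
            class = "mixed_model_result")
}

# Satterthwaite denominator degrees of freedom for the slope of the
# random-intercept model: df = 2 f(theta)^2 / Var(f(theta-hat)), with
# f(theta) the slope sampling variance as a function of the two variance
# components and Var() from the inverse REML information (numerical
# derivatives; the model is small enough for dense algebra). Falls back to
# the OLS df n - 2 at the boundary (zero site variance) or on numerical
# failure.
.satterthwaite_df <- function(y, x, site, theta) {
  n <- length(y)
  X <- cbind(1, x)
  Zi <- outer(site, unique(site), "==") * 1
  ZZt <- tcrossprod(Zi)
  fvar <- function(t2) {
    V <- t2[2] * diag(n) + t2[1] * ZZt
    solve(t(X) %*% solve(V) %*% X)[2, 2]
  }
  remll <- function(t2) {
    V <- t2[2] * diag(n) + t2[1] * ZZt
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    as.numeric(-0.5 * (determinant(V)$modulus +
                         determinant(XtViX)$modulus + t(r) %*% Vi %*% r))
  }
  if (theta[1] < 1e-8 * theta[2]) return(n - 2)
  out <- tryCatch({
    se2 <- fvar(theta)
    h <- pmax(theta * 1e-4, 1e-8)
    g <- numeric(2); H <- matrix(0, 2, 2)
    for (i in 1:2) {
      e <- c(0, 0); e[i] <- h[i]
      g[i] <- (fvar(theta + e) - fvar(theta - e)) / (2 * h[i])
      H[i, i] <- (remll(theta + e) - 2 * remll(theta) +
                    remll(theta - e)) / h[i]^2
    }
    e1 <- c(h[1], 0); e2 <- c(0, h[2])
    H[1, 2] <- H[2, 1] <- (remll(theta + e1 + e2) - remll(theta + e1 - e2) -
                             remll(theta - e1 + e2) +
                             remll(theta - e1 - e2)) / (4 * h[1] * h[2])
    denom <- drop(t(g) %*% solve(-H) %*% g)
    if (denom <= 0) n - 2 else max(1, min(2 * se2^2 / denom, n - 2))
  }, error = function(e) n - 2)
  out
}

.lmm_slope <- function(y, x, site, reml) {
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ x + (1 | site), REML = reml,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- suppressWarnings(summary(fit)$coefficients)
    vc <- as.data.frame(lme4::VarCorr(fit))
    theta <- c(vc$vcov[vc$grp == "site"], vc$vcov[vc$grp == "Residual"])
    df <- .satterthwaite_df(y, x, as.character(site), theta)
    list(slope = co["x", "Estimate"], se = co["x", "Std. Error"],
         p = 2 * stats::pt(-abs(co["x", "t value"]), df),
         df = df,
         site_var = theta[1], resid_var = theta[2],
         method = "lmer")
  } else {
    # degenerate (e.g. zero residual variance): plain OLS, site variance 0
    lm_fit <- stats::lm(y ~ x)
    co <- summary(lm_fit)$coefficients
    se <- co["x", "Std. Error"]
    list(slope = co["x", "Estimate"], se = se,
         p = if (is.finite(se) && se > 0) co["x", "Pr(>|t|)"] else 0,
         df = length(y) - 2,
         site_var = 0, resid_var = summary(lm_fit)$sigma^2,
         method = "ols_fallback")
  }
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("LUI slope = %.4f (SE %.4f, p = %.3g), SES = %.4f, n = %d [%s]\n",
              x$slope, x$slope_se, x$p_value, x$ses, x$n, x$method))
  invisible(x)
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y numeric vectors (n >= 3).
#' @return list(r, p, n)
#' @export
correlate <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Fit mixed models for every metric column
#'
#' @param field_metrics data.frame with field_id, site_id and metric columns.
#' @param lui_scores named numeric LUI per field.
#' @param reml passed to [fit_mixed_model()].
#' @return data.frame: metric, slope, slope_se, p_value, p_bh, ses,
#'   site_variance, residual_variance, n. `p_bh` (Benjamini-Hochberg) is
#'   informational only; inference is per metric.
#' @export
fit_all_metrics <- function(field_metrics, lui_scores, reml = TRUE) {
  meta_cols <- c("field_id", "site_id")
  metrics <- setdiff(names(field_metrics), meta_cols)
  lui <- lui_scores[field_metrics$field_id]
  rows <- lapply(metrics, function(m) {
    res <- tryCatch(
      fit_mixed_model(field_metrics[[m]], lui, field_metrics$site_id, reml),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(metric = m, slope = NA_real_, slope_se = NA_real_,
                        p_value = NA_real_, ses = NA_real_,
                        site_variance = NA_real_, residual_variance = NA_real_,
                        n = sum(!is.na(field_metrics[[m]]))))
    data.frame(metric = m, slope = res$slope, slope_se = res$slope_se,
               p_value = res$p_value, ses = res$ses,
               site_variance = res$site_variance,
               residual_variance = res$residual_variance, n = res$n)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  row.names(out) <- NULL
  out
}
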