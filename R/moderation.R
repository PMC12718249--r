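# Moderation models (maternal affect x synchrony -> child dysregulation),
# Johnson-Neyman probing, and the descriptive/correlation table.

#' Grand-mean centering
#' @param values numeric with at least 2 finite values.
#' @return values minus their (finite-value) mean.
#' @export
mean_center <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("need at least 2 finite values to center")
  values - mean(values[ok])
}

#' Fit a moderation model
#'
#' Ordinary least squares of the outcome on the mean-centered independent
#' variable, the mean-centered moderator, their product, and the covariates
#' (uncentered), after listwise deletion of incomplete rows. Standardized
#' coefficients are \eqn{\beta_j = B_j \, sd(x_j)/sd(y)} computed on the
#' analyzed sample. The coefficient covariance matrix is retained for
#' Johnson-Neyman probing.
#'
#' @param data data.frame of dyad-level variables.
#' @param iv name of the focal predictor column (e.g. maternal positive
#'   affect).
#' @param moderator name of the synchrony column.
#' @param covariates character vector of covariate columns (e.g. the other
#'   affect scale, child gender, income).
#' @param outcome outcome column (default \code{"dysregulation"}).
#' @param alpha significance level carried to probing (default 0.05).
#' @return object of class \code{moderation_fit}: coefficient table
#'   (term, B, SE, beta, t, p), \code{r_squared}, overall \code{F} with df,
#'   \code{vcov}, \code{n}, and the underlying \code{lm} fit.
#' @export
fit_moderation <- function(data, iv, moderator, covariates = character(),
                           outcome = "dysregulation", alpha = 0.05) {
  vars <- c(outcome, iv, moderator, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  p <- length(covariates) + 3L
  if (nrow(d) < p + 2L)
    stop(sprintf("only %d complete cases for %d predictors", nrow(d), p))
  d$.iv_c <- mean_center(d[[iv]])
  d$.mod_c <- mean_center(d[[moderator]])
  d$.int <- d$.iv_c * d$.mod_c
  rhs <- c(".iv_c", ".mod_c", ".int", covariates)
  fm <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(fm, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; collinear terms: ", paste(bad, collapse = ", "))
  }
  sm <- suppressWarnings(summary(fit))  # tolerate exact fits in oracles
  ct <- sm$coefficients
  terms <- rownames(ct)
  pretty <- c("(Intercept)" = "(Intercept)",
              ".iv_c" = iv, ".mod_c" = moderator,
              ".int" = paste0(iv, ":", moderator))
  term_names <- ifelse(terms %in% names(pretty), pretty[terms], terms)
  sdy <- stats::sd(d[[outcome]])
  sdx <- vapply(terms, function(tm)
    if (tm == "(Intercept)") NA_real_ else stats::sd(stats::model.matrix(fit)[, tm]),
    numeric(1))
  coef_table <- data.frame(term = term_names, B = ct[, 1], SE = ct[, 2],
                           beta = ct[, 1] * sdx / sdy, t = ct[, 3], p = ct[, 4],
                           row.names = NULL)
  fstat <- sm$fstatistic
  structure(list(coefficients = coef_table, r_squared = sm$r.squared,
                 f = unname(fstat[1]), df1 = unname(fstat[2]),
                 df2 = unname(fstat[3]),
                 f_p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
                 vcov = sm$sigma^2 * sm$cov.unscaled,
                 n = nrow(d), alpha = alpha,
                 iv = iv, moderator = moderator, covariates = covariates,
                 outcome = outcome,
                 iv_mean = mean(d[[iv]]),
                 moderator_mean = mean(d[[moderator]]),
                 moderator_range = range(d[[moderator]]),
                 lm = fit),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("Moderation model: %s ~ %s * %s%s\n", x$outcome, x$iv, x$moderator,
              if (length(x$covariates))
                paste0(" + ", paste(x$covariates, collapse = " + ")) else ""))
  cat(sprintf("  n = %d, R^2 = %.3f, F(%d, %d) = %.2f, p = %.4g\n",
              x$n, x$r_squared, x$df1, x$df2, x$f, x$f_p))
  tab <- x$coefficients
  tab$B <- round(tab$B, 4); tab$SE <- round(tab$SE, 4)
  tab$beta <- round(tab$beta, 3); tab$t <- round(tab$t, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.moderation_fit <- function(object, ...) {
  print(object)
  int_row <- grep(":", object$coefficients$term)
  if (length(int_row)) {
    pr <- object$coefficients$p[int_row[1]]
    cat(sprintf("Interaction p = %.4g (%ssignificant at alpha = %.2g)\n",
                pr, if (pr < object$alpha) "" else "non", object$alpha))
  }
  invisible(object)
}

#' @export
coef.moderation_fit <- function(object, ...) {
  stats::setNames(object$coefficients$B, object$coefficients$term)
}

#' @export
vcov.moderation_fit <- function(object, ...) object$vcov

#' @export
predict.moderation_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$lm, ...))
  nd <- newdata
  # center new data at the analyzed-sample means used in the fit
  nd$.iv_c <- nd[[object$iv]] - object$iv_mean
  nd$.mod_c <- nd[[object$moderator]] - object$moderator_mean
  nd$.int <- nd$.iv_c * nd$.mod_c
  stats::predict(object$lm, newdata = nd, ...)
}

#' Johnson-Neyman regions of significance
#'
#' The simple slope of the focal predictor at moderator value \eqn{m}
#' (centered) is \eqn{\theta(m) = B_{iv} + B_{int} m} with
#' \eqn{Var(\theta) = V_{11} + 2 m V_{13} + m^2 V_{33}}. Boundaries are the
#' real roots of \eqn{\theta^2 = t_{crit}^2 Var(\theta)} with two-tailed
#' \eqn{t_{crit}} at \code{alpha} and \eqn{df = n - p - 1}; regions between /
#' outside the boundaries are labelled by the sign and significance of the
#' simple slope at their midpoint. Boundaries are reported on both the
#' centered and the raw moderator scale, and flagged when outside the
#' observed range.
#'
#' @param fit a \code{\link{fit_moderation}} result.
#' @param alpha significance level (default the fit's).
#' @return object of class \code{jn_regions}: \code{boundaries} (raw scale),
#'   \code{boundaries_centered}, \code{regions} data.frame, \code{alpha},
#'   \code{df}, \code{t_crit}.
#' @export
johnson_neyman <- function(fit, alpha = fit$alpha) {
  stopifnot(inherits(fit, "moderation_fit"))
  V <- fit$vcov
  b1 <- fit$coefficients$B[fit$coefficients$term == fit$iv]
  int_term <- paste0(fit$iv, ":", fit$moderator)
  b3 <- fit$coefficients$B[fit$coefficients$term == int_term]
  v11 <- V[".iv_c", ".iv_c"]; v13 <- V[".iv_c", ".int"]; v33 <- V[".int", ".int"]
  df <- fit$df2
  tc <- stats::qt(1 - alpha / 2, df)
  degenerate <- v33 <= 0 || (b3 == 0 && v13 == 0)
  if (degenerate || b3^2 == tc^2 * v33) {
    roots <- numeric(0)
  } else {
    A <- b3^2 - tc^2 * v33
    B <- 2 * (b1 * b3 - tc^2 * v13)
    C <- b1^2 - tc^2 * v11
    disc <- B^2 - 4 * A * C
    roots <- if (disc < 0) numeric(0) else sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  }
  ctr_range <- fit$moderator_range - fit$moderator_mean
  edges <- sort(unique(c(ctr_range, roots)))
  mids <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  # include open-ended context when all roots fall outside the observed range
  slope_at <- function(m) b1 + b3 * m
  se_at <- function(m) sqrt(pmax(v11 + 2 * m * v13 + m^2 * v33, 0))
  regions <- data.frame(
    lower = utils::head(edges, -1) + fit$moderator_mean,
    upper = utils::tail(edges, -1) + fit$moderator_mean,
    slope = slope_at(mids),
    t = slope_at(mids) / se_at(mids))
  regions$significant <- abs(regions$t) > tc
  regions$sign <- ifelse(regions$slope >= 0, "positive", "negative")
  int_p <- NA_real_
  if ("p" %in% names(fit$coefficients)) {
    v <- fit$coefficients$p[fit$coefficients$term == int_term]
    if (length(v) == 1) int_p <- v
  }
  structure(list(boundaries = roots + fit$moderator_mean,
                 boundaries_centered = roots,
                 interaction_p = int_p,
                 in_observed_range = roots >= ctr_range[1] & roots <= ctr_range[2],
                 regions = regions, alpha = alpha, df = df, t_crit = tc,
                 b_iv = b1, b_int = b3, v11 = v11, v13 = v13, v33 = v33,
                 moderator_mean = fit$moderator_mean,
                 moderator_range = fit$moderator_range,
                 iv = fit$iv, moderator = fit$moderator,
                 degenerate = degenerate),
            class = "jn_regions")
}

#' @export
print.jn_regions <- function(x, ...) {
  cat(sprintf("Johnson-Neyman probe of %s x %s (alpha = %.2g, df = %d)\n",
              x$iv, x$moderator, x$alpha, round(x$df)))
  if (x$degenerate) {
    cat("  degenerate (no interaction variance): one global region\n")
  } else if (!length(x$boundaries)) {
    cat("  no boundaries: significance status constant over the moderator range\n")
  } else {
    for (i in seq_along(x$boundaries))
      cat(sprintf("  boundary at moderator = %.4g%s\n", x$boundaries[i],
                  if (x$in_observed_range[i]) "" else " (outside observed range)"))
  }
  print(transform(x$regions, slope = round(slope, 4), t = round(t, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Plot a Johnson-Neyman probe
#'
#' Simple slope of the focal predictor against the moderator with its
#' pointwise confidence band; region-of-significance boundaries are drawn as
#' vertical lines.
#'
#' @param x a \code{jn_regions}.
#' @param n_grid grid resolution.
#' @param ... passed to \code{plot}.
#' @export
plot.jn_regions <- function(x, n_grid = 200, ...) {
  m_raw <- seq(x$moderator_range[1], x$moderator_range[2], length.out = n_grid)
  m <- m_raw - x$moderator_mean
  slope <- x$b_iv + x$b_int * m
  se <- sqrt(pmax(x$v11 + 2 * m * x$v13 + m^2 * x$v33, 0))
  lo <- slope - x$t_crit * se; hi <- slope + x$t_crit * se
  graphics::plot(m_raw, slope, type = "n", ylim = range(lo, hi),
                 xlab = x$moderator, ylab = sprintf("simple slope of %s", x$iv), ...)
  graphics::polygon(c(m_raw, rev(m_raw)), c(lo, rev(hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(m_raw, slope, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  if (length(x$boundaries))
    graphics::abline(v = x$boundaries, lty = 2, col = "firebrick")
  invisible(x)
}

#' Multiplicity adjustment of interaction p-values across models
#'
#' Collects the interaction-term p-value of each fitted moderation model and
#' adjusts them jointly (Benjamini-Hochberg by default). Off by default in
#' the pipeline, where the ten models are reported unadjusted; this is the
#' opt-in extension.
#'
#' @param fits named list of \code{\link{fit_moderation}} results.
#' @param method passed to \code{\link[stats]{p.adjust}} (default "BH").
#' @return data.frame with model, interaction term, raw and adjusted p.
#' @export
adjust_interaction_p <- function(fits, method = "BH") {
  rows <- lapply(names(fits), function(k) {
    f <- fits[[k]]
    i <- grep(":", f$coefficients$term)[1]
    data.frame(model = k, term = f$coefficients$term[i],
               p = f$coefficients$p[i])
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = method)
  out
}

#' Descriptive statistics and Pearson correlation table
#'
#' Mean (SD) per variable plus the pairwise-complete Pearson correlation
#' matrix with two-tailed p-values and .05/.01 significance stars.
#'
#' @param table data.frame of numeric variables.
#' @return object of class \code{correlation_table}: \code{descriptives},
#'   \code{r}, \code{p}, \code{stars}.
#' @export
correlation_table <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1))]
  k <- ncol(num)
  desc <- data.frame(variable = names(num),
                     mean = vapply(num, function(v) mean(v, na.rm = TRUE), 0),
                     sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE), 0),
                     row.names = NULL)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names(num), names(num)))
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    ok <- stats::complete.cases(num[[i]], num[[j]])
    if (sum(ok) < 3) next
    if (stats::sd(num[[i]][ok]) == 0 || stats::sd(num[[j]][ok]) == 0) next
    ct <- stats::cor.test(num[[i]][ok], num[[j]][ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  stars <- ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  structure(list(descriptives = desc, r = r, p = p, stars = stars),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, digits = 2, ...) {
  cat("Descriptive statistics\n")
  d <- x$descriptives
  d$mean <- round(d$mean, digits + 1); d$sd <- round(d$sd, digits + 1)
  print(d, row.names = FALSE)
  cat("\nPearson correlations (pairwise complete; * p<.05, ** p<.01)\n")
  rr <- matrix(paste0(format(round(x$r, digits)), x$stars),
               nrow(x$r), dimnames = dimnames(x$r))
  rr[is.na(x$r)] <- "-"
  print(rr, quote = FALSE)
  invisible(x)
}
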