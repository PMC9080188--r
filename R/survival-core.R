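# Survival statistics: Kaplan-Meier product-limit estimator, k-group
# log-rank test, maximally selected cutpoint, Cox proportional-hazards
# regression (Efron ties, Newton-Raphson with step-halving) and
# time-dependent ROC. All take a "survival table": a data.frame with columns
# sample_id (optional), time (> 0, days) and event (0/1).

#' Validate a survival table
#'
#' @param s data.frame with columns `time` (> 0) and `event` (0/1); a
#'   `sample_id` column is added from row names if absent.
#' @return The validated data.frame.
#' @export
as_survival_table <- function(s) {
  if (!is.data.frame(s)) stopf("survival table must be a data.frame")
  miss <- setdiff(c("time", "event"), colnames(s))
  if (length(miss)) stopf("survival table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(s) < 1L) stopf("empty survival table")
  s$time <- as.numeric(s$time)
  s$event <- as.integer(s$event)
  if (any(!is.finite(s$time)) || any(s$time <= 0))
    stopf("survival times must be positive")
  if (any(!s$event %in% 0:1)) stopf("event indicator must be 0 or 1")
  if (is.null(s$sample_id)) s$sample_id <- as.character(seq_len(nrow(s)))
  s
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)` where `d_i` is
#' the number of deaths at `t_i` and `n_i` the number at risk; censored
#' subjects leave the risk set after their censoring time.
#'
#' @param s survival table (see [as_survival_table()]).
#' @return Object of class `km_curve`: data.frame with `time` (distinct event
#'   times, increasing), `n_risk`, `n_event`, `survival`; attribute `n` is
#'   the sample size. With no events the curve is identically 1 (empty
#'   data.frame).
#' @export
km_estimate <- function(s) {
  s <- as_survival_table(s)
  ut <- sort(unique(s$time[s$event == 1L]))
  n_risk <- vapply(ut, function(t) sum(s$time >= t), integer(1))
  d <- vapply(ut, function(t) sum(s$time == t & s$event == 1L), integer(1))
  surv <- cumprod(1 - d / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = d, survival = surv)
  structure(out, class = c("km_curve", "data.frame"), n = nrow(s))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d event time(s)\n",
              attr(x, "n"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, add = FALSE, col = 1, xlab = "time (days)",
                          ylab = "survival probability", ...) {
  t <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[-2 * nrow(x)])
  if (!add) graphics::plot(t, ss, type = "l", ylim = c(0, 1), col = col,
                           xlab = xlab, ylab = ylab, ...)
  else graphics::lines(t, ss, col = col, ...)
  invisible(x)
}

#' Log-rank test
#'
#' Standard k-group log-rank test: at each distinct event time the observed
#' group-wise deaths are compared with their hypergeometric expectation and
#' variance; the chi-square statistic is `U' V^{-1} U` over the first k-1
#' groups with df = k - 1.
#'
#' @param s survival table.
#' @param group group label per subject (>= 2 non-empty groups).
#' @return Object of class `logrank_test`: `chi_square`, `df`, `p_value`,
#'   `observed`, `expected` (per group), `n`.
#' @export
logrank_test <- function(s, group) {
  s <- as_survival_table(s)
  if (length(group) != nrow(s)) stopf("group has wrong length")
  g <- factor(group)
  if (nlevels(g) < 2L) stopf("need at least 2 groups")
  if (any(table(g) == 0L)) stopf("a group has zero subjects")
  k <- nlevels(g)
  ut <- sort(unique(s$time[s$event == 1L]))
  O <- E <- stats::setNames(numeric(k), levels(g))
  V <- matrix(0, k, k, dimnames = list(levels(g), levels(g)))
  for (t in ut) {
    at_risk <- s$time >= t
    n <- sum(at_risk)
    ni <- vapply(levels(g), function(l) sum(at_risk & g == l), numeric(1))
    death <- s$time == t & s$event == 1L
    d <- sum(death)
    di <- vapply(levels(g), function(l) sum(death & g == l), numeric(1))
    O <- O + di
    E <- E + d * ni / n
    if (n > 1) {
      frac <- ni / n
      Vt <- d * (n - d) / (n - 1) * (diag(frac, k) - tcrossprod(frac))
      V <- V + Vt
    }
  }
  U <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chi <- tryCatch(drop(t(U) %*% solve(Vk, U)), error = function(e) {
    # singular variance (e.g. no events): pseudo-inverse
    sv <- svd(Vk)
    pos <- sv$d > max(sv$d) * 1e-12
    if (!any(pos)) return(0)
    drop(t(U) %*% sv$v[, pos, drop = FALSE] %*%
           ((t(sv$u[, pos, drop = FALSE]) %*% U) / sv$d[pos]))
  })
  chi <- max(chi, 0)
  structure(list(chi_square = chi, df = k - 1L,
                 p_value = stats::pchisq(chi, df = k - 1L, lower.tail = FALSE),
                 observed = O, expected = E, n = nrow(s)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  print(data.frame(observed = x$observed, expected = x$expected))
  invisible(x)
}

# Log-rank (martingale-residual) scores: a_i = event_i - H(time_i) with H the
# Nelson-Aalen cumulative hazard. Basis of the maximally selected statistic.
logrank_scores <- function(time, event) {
  ut <- sort(unique(time[event == 1L]))
  if (length(ut) == 0L) return(rep(0, length(time)))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  d <- vapply(ut, function(t) sum(time == t & event == 1L), numeric(1))
  cumhaz <- cumsum(d / n_risk)
  H <- c(0, cumhaz)[findInterval(time, ut) + 1L]
  event - H
}

#' Maximally selected cutpoint for a continuous marker
#'
#' Scans all admissible cutpoints c (distinct observed marker values, with
#' both resulting groups containing at least a `minprop` fraction of
#' subjects) and returns the c maximizing the absolute standardized two-group
#' log-rank statistic for the split `x > c` vs `x <= c`. The statistic is
#' computed in log-rank score form with its permutation variance - the
#' maximally selected rank statistic that `survminer::surv_cutpoint` /
#' `maxstat` maximize. Ties in the maximum are broken toward the smaller
#' cutpoint.
#'
#' The p-value of a subsequent log-rank test on the selected split is not
#' corrected for the selection (see the methods vignette for the caveat).
#'
#' @param x numeric marker, aligned with `s`; at least 2 distinct values.
#' @param s survival table.
#' @param minprop minimum group proportion (default 0.1).
#' @return Object of class `cutpoint_result`: `cutpoint`, `max_statistic`
#'   (absolute standardized statistic), `statistic` (signed), `group`
#'   (factor `"Low"`/`"High"` per subject, High = `x > cutpoint`), and the
#'   scanned candidate table.
#' @export
optimal_cutpoint <- function(x, s, minprop = 0.1) {
  s <- as_survival_table(s)
  n <- nrow(s)
  if (length(x) != n) stopf("marker has wrong length")
  if (!is.numeric(minprop) || minprop <= 0 || minprop >= 0.5 + 1e-12)
    stopf("minprop must lie in (0, 0.5]")
  if (length(unique(x)) < 2L) stopf("marker must have at least 2 distinct values")
  a <- logrank_scores(s$time, s$event)
  if (all(a == 0)) stopf("no events: cutpoint statistic undefined")
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(a[ord])
  abar <- mean(a)
  va <- sum((a - abar)^2)
  # candidate cuts: after position i where the sorted marker strictly increases
  cut_at <- which(xs[-n] < xs[-1L])
  m <- cut_at                             # size of the low group (x <= c)
  tol <- 1e-9
  ok <- m / n >= minprop - tol & (n - m) / n >= minprop - tol
  if (!any(ok)) stopf("no cutpoint satisfies minprop = %g", minprop)
  m <- m[ok]; cut_at <- cut_at[ok]
  S <- cs[cut_at]
  Em <- m * abar
  Vm <- m * (n - m) / (n * (n - 1)) * va
  z <- (S - Em) / sqrt(Vm)
  best <- which.max(abs(z) - 1e-12 * seq_along(z))  # tie -> smaller cutpoint
  cut <- xs[cut_at[best]]
  grp <- factor(ifelse(x > cut, "High", "Low"), levels = c("Low", "High"))
  structure(list(cutpoint = cut, max_statistic = abs(z[best]),
                 statistic = z[best], group = grp,
                 candidates = data.frame(cutpoint = xs[cut_at],
                                         n_low = m, statistic = z)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("optimal cutpoint: %.4g (|standardized log-rank| = %.3f; %d Low / %d High)\n",
              x$cutpoint, x$max_statistic,
              sum(x$group == "Low"), sum(x$group == "High")))
  invisible(x)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the Efron-approximation partial likelihood by Newton-Raphson
#' from `beta = 0`, with step-halving so the log partial likelihood never
#' decreases. Standard errors come from the inverse observed information;
#' Wald p-values are two-sided.
#'
#' @param X covariate matrix (subjects x covariates) or numeric vector; no
#'   constant column; more subjects than covariates.
#' @param s survival table aligned with the rows of `X`.
#' @param tolerance convergence tolerance on the gradient max-norm and the
#'   relative log-likelihood change.
#' @param max_iter maximum Newton iterations; non-convergence is flagged
#'   (with a warning), not an error.
#' @return Object of class `cox_fit`: `coefficients`, `se`, `z`, `p_value`,
#'   `hazard_ratio`, `var` (covariance matrix), `loglik` (null and final),
#'   `iter`, `converged`, `n`, `n_event`.
#' @export
cox_fit <- function(X, s, tolerance = 1e-9, max_iter = 50L) {
  s <- as_survival_table(s)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L,
                                   dimnames = list(NULL, "x"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (n != nrow(s)) stopf("covariate rows (%d) != survival rows (%d)", n, nrow(s))
  if (n <= p) stopf("need more subjects (%d) than covariates (%d)", n, p)
  csd <- apply(X, 2L, stats::sd)
  if (any(csd == 0)) stopf("constant covariate: %s",
                           paste(colnames(X)[csd == 0], collapse = ", "))
  if (sum(s$event) == 0L) stopf("no events: partial likelihood is constant")

  ord <- order(s$time)
  Xo <- X[ord, , drop = FALSE]
  time <- s$time[ord]; event <- s$event[ord]
  ut <- unique(time[event == 1L])
  risk_start <- findInterval(ut - 1e-12, time) + 1L  # first index with time >= t
  death_idx <- lapply(ut, function(t) which(time == t & event == 1L))

  efron <- function(beta, need_deriv = TRUE) {
    eta <- drop(Xo %*% beta)
    w <- exp(eta)
    ll <- 0
    U <- numeric(p)
    I <- matrix(0, p, p)
    for (k in seq_along(ut)) {
      r <- risk_start[k]:n
      Dk <- death_idx[[k]]
      d <- length(Dk)
      wr <- w[r]
      S0 <- sum(wr)
      S0D <- sum(w[Dk])
      if (need_deriv) {
        Xr <- Xo[r, , drop = FALSE]
        S1 <- colSums(Xr * wr)
        S2 <- crossprod(Xr, Xr * wr)
        XD <- Xo[Dk, , drop = FALSE]
        S1D <- colSums(XD * w[Dk])
        S2D <- crossprod(XD, XD * w[Dk])
      }
      ll <- ll + sum(eta[Dk])
      for (l in seq_len(d) - 1L) {
        f <- l / d
        den <- S0 - f * S0D
        ll <- ll - log(den)
        if (need_deriv) {
          xb <- (S1 - f * S1D) / den
          U <- U - xb
          I <- I + (S2 - f * S2D) / den - tcrossprod(xb)
        }
      }
      if (need_deriv) U <- U + colSums(Xo[Dk, , drop = FALSE])
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- numeric(p)
  cur <- efron(beta)
  ll0 <- cur$ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$I, cur$U), error = function(e)
      stopf("singular information matrix (collinear covariates?)"))
    # step-halving: never let the log partial likelihood decrease
    h <- 1
    repeat {
      cand <- beta + h * step
      new_ll <- efron(cand, need_deriv = FALSE)$ll
      if (new_ll >= cur$ll - 1e-12 || h < 1e-10) break
      h <- h / 2
    }
    beta <- beta + h * step
    new <- efron(beta)
    done <- max(abs(new$U)) < tolerance ||
      abs(new$ll - cur$ll) < tolerance * (abs(cur$ll) + tolerance)
    cur <- new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) warnf("cox_fit did not converge in %d iterations", max_iter)
  V <- solve(cur$I)
  se <- sqrt(diag(V))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  names(beta) <- names(se) <- names(z) <- names(pv) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, se = se, z = z, p_value = pv,
                 hazard_ratio = exp(beta), var = V,
                 loglik = c(null = ll0, final = cur$ll),
                 iter = iter, converged = converged,
                 n = n, n_event = sum(event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d%s\n",
              x$n, x$n_event,
              if (x$converged) sprintf(" (converged in %d iterations)", x$iter)
              else " (NOT converged)"))
  print(summary(x))
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, ...) {
  data.frame(beta = object$coefficients, HR = object$hazard_ratio,
             se = object$se, z = object$z, p_value = object$p_value)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik[["final"]], df = length(object$coefficients),
            class = "logLik")
}

#' Linear predictor of a Cox fit
#'
#' @param object a `cox_fit`.
#' @param newdata covariate matrix with the fit's covariate columns.
#' @param ... unused.
#' @return Numeric vector `newdata %*% beta` (uncentered log relative hazard).
#' @export
predict.cox_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata[, names(object$coefficients), drop = FALSE] %*%
         object$coefficients)
}

#' Time-dependent ROC at a fixed horizon
#'
#' Cumulative-case / dynamic-control estimator: cases are subjects with an
#' observed event by the horizon, controls are subjects still under
#' observation beyond it, and subjects censored before the horizon are
#' excluded. The ROC is traced over score thresholds (higher score = higher
#' predicted risk); the AUC is the trapezoid area and equals the
#' Mann-Whitney statistic of case vs control scores.
#'
#' @param score numeric risk score aligned with `s`.
#' @param s survival table.
#' @param horizon time horizon (within the observed time range).
#' @return Object of class `td_roc`: `horizon`, `fpr`, `tpr`, `auc`,
#'   `n_cases`, `n_controls`, `n_excluded`.
#' @export
td_roc <- function(score, s, horizon) {
  s <- as_survival_table(s)
  if (length(score) != nrow(s)) stopf("score has wrong length")
  if (!is.numeric(horizon) || length(horizon) != 1L ||
      horizon <= 0 || horizon >= max(s$time))
    stopf("horizon must lie inside the observed time range (0, %g)", max(s$time))
  case <- s$time <= horizon & s$event == 1L
  control <- s$time > horizon
  excluded <- !case & !control
  if (!any(case)) stopf("no cases by the horizon")
  if (!any(control)) stopf("no controls beyond the horizon")
  sc_case <- score[case]; sc_ctl <- score[control]
  thr <- sort(unique(score[case | control]), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(c) mean(sc_case >= c), numeric(1)))
  fpr <- c(0, vapply(thr, function(c) mean(sc_ctl >= c), numeric(1)))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(horizon = horizon, fpr = fpr, tpr = tpr, auc = auc,
                 n_cases = sum(case), n_controls = sum(control),
                 n_excluded = sum(excluded)),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("time-dependent ROC at t = %g: AUC = %.4f (%d cases, %d controls, %d censored-excluded)\n",
              x$horizon, x$auc, x$n_cases, x$n_controls, x$n_excluded))
  invisible(x)
}

#' @export
plot.td_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("AUC = %.4f at t = %g", x$auc, x$horizon), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Per-lncRNA survival screening
#'
#' For each gene, splits the patients at the maximally selected cutpoint of
#' its expression ("Low"/"High" groups) and tests the split with the
#' log-rank test - the per-marker Kaplan-Meier screening stage. Genes whose
#' cutpoint scan fails (e.g. no admissible split) get NA statistics.
#'
#' @param x an [expr_matrix].
#' @param s survival table (samples must be columns of `x`).
#' @param genes genes to screen; default all lncRNAs in `x`.
#' @param minprop minimum group proportion for the cutpoint scan.
#' @param p_max significance threshold for the `significant` flag.
#' @return Data.frame: `gene_id`, `cutpoint`, `n_low`, `n_high`,
#'   `chi_square`, `p_value`, `significant`.
#' @export
screen_survival <- function(x, s, genes = NULL, minprop = 0.1, p_max = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  s <- as_survival_table(s)
  if (is.null(genes)) genes <- rownames(x$values)[x$role == "lncRNA"]
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing)) stopf("genes not in matrix: %s", paste(missing, collapse = ", "))
  missing_s <- setdiff(s$sample_id, colnames(x$values))
  if (length(missing_s)) stopf("survival samples not in matrix: %s",
                               paste(missing_s, collapse = ", "))
  rows <- lapply(genes, function(g) {
    xv <- x$values[g, s$sample_id]
    res <- tryCatch({
      cp <- optimal_cutpoint(xv, s, minprop = minprop)
      lr <- logrank_test(s, cp$group)
      data.frame(gene_id = g, cutpoint = cp$cutpoint,
                 n_low = sum(cp$group == "Low"),
                 n_high = sum(cp$group == "High"),
                 chi_square = lr$chi_square, p_value = lr$p_value,
                 significant = lr$p_value < p_max,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(gene_id = g, cutpoint = NA_real_, n_low = NA_integer_,
                 n_high = NA_integer_, chi_square = NA_real_,
                 p_value = NA_real_, significant = FALSE,
                 stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
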