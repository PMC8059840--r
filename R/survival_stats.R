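# Survival statistics: Kaplan-Meier, two-group log-rank, optimal cut-point
# stratification (minimizing the log-rank p over observed thresholds), Cox
# proportional-hazards fits, and the minimum-detectable-hazard-ratio power
# relation for a standardized continuous covariate.

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times, > 0.
#' @param events 0/1 (or logical) event indicators.
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv` at the
#'   distinct observed times; S(0) = 1 and the curve drops only at event
#'   times.
#' @export
km_estimate <- function(times, events) {
  check_surv(times, events)
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

check_surv <- function(times, events) {
  if (length(times) == 0) stop("empty survival input", call. = FALSE)
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  if (length(events) != length(times) || !all(events %in% c(0, 1, TRUE, FALSE))) {
    stop("events must be 0/1 and match times in length", call. = FALSE)
  }
  invisible(TRUE)
}

#' Two-group log-rank test
#'
#' @param groups group labels (exactly two distinct values, both present).
#' @param times,events survival outcome as in [km_estimate()].
#' @return list: `chi2` (1 df), `p_value` (two-sided).
#' @export
log_rank <- function(groups, times, events) {
  check_surv(times, events)
  g <- factor(groups)
  if (nlevels(g) != 2L || any(tabulate(g) == 0)) {
    stop("log_rank requires exactly two nonempty groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ g)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Optimal cut-point for survival stratification
#'
#' Scans every distinct observed value c of a continuous biomarker,
#' splitting patients into value > c versus value <= c, and returns the
#' threshold minimizing the two-group log-rank p-value for overall
#' survival. Splits leaving either group smaller than
#' `max(ceiling(min_group_frac * n), min_group_size)` are discarded; ties
#' in p are broken toward the smaller threshold.
#'
#' The minimized p-value is anti-conservative (it is the minimum over many
#' correlated tests) and is reported uncorrected, as is conventional for
#' this methodology; `n_perm > 0` additionally reports a
#' permutation-adjusted p in which the outcome is permuted against the
#' biomarker and the scan re-optimized per permutation.
#'
#' @param values continuous biomarker, one per patient (NAs dropped with
#'   their outcomes).
#' @param times,events survival outcome.
#' @param min_group_frac minimum group size as a fraction of n (in
#'   `[0, 0.5)`, default 0.10).
#' @param min_group_size absolute minimum group size (default 1).
#' @param n_perm number of permutations for the adjusted p (default 0 =
#'   none).
#' @return An object of class `cutpoint_result`: list with `cutpoint`,
#'   `n_low`, `n_high`, `chi2`, `p_value`, `n`, and `p_adjusted` when
#'   requested.
#' @export
optimal_cutpoint <- function(values, times, events, min_group_frac = 0.10,
                             min_group_size = 1L, n_perm = 0L) {
  stopifnot(min_group_frac >= 0, min_group_frac < 0.5, min_group_size >= 1)
  ok <- !is.na(values)
  values <- values[ok]; times <- times[ok]; events <- events[ok]
  check_surv(times, events)
  n <- length(values)
  if (length(unique(values)) < 2L) {
    stop("need >= 2 distinct biomarker values", call. = FALSE)
  }
  min_size <- max(ceiling(min_group_frac * n), min_group_size)
  cands <- sort(unique(values))
  scan <- function(tt, ee) {
    best <- list(p = Inf, cut = NA_real_, chi2 = NA_real_,
                 n_low = NA_integer_, n_high = NA_integer_)
    ord <- order(tt)
    ts <- tt[ord]; es <- ee[ord]; vs <- values[ord]
    first <- !duplicated(ts)             # index of each distinct time
    d_all <- rowsum(as.numeric(es), ts)[, 1]
    n_all <- rev(cumsum(rev(rep(1, n))))[first]
    ev_times <- d_all > 0
    for (cand in cands) {
      hi <- vs > cand
      n_hi <- sum(hi)
      if (n_hi < min_size || n - n_hi < min_size) next
      n1 <- rev(cumsum(rev(as.numeric(hi))))[first]  # high-group at risk
      d1 <- rowsum(as.numeric(es & hi), ts)[, 1]     # high-group events
      dk <- d_all[ev_times]; nk <- n_all[ev_times]
      n1k <- n1[ev_times]; d1k <- d1[ev_times]
      e1 <- dk * n1k / nk
      vk <- ifelse(nk > 1,
                   dk * (n1k / nk) * (1 - n1k / nk) * (nk - dk) / (nk - 1),
                   0)
      V <- sum(vk)
      if (V <= 0) next
      chi2 <- (sum(d1k) - sum(e1))^2 / V
      p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
      if (p < best$p) {  # strict: ties keep the smaller cutpoint
        best <- list(p = p, cut = cand, chi2 = chi2,
                     n_low = n - n_hi, n_high = n_hi)
      }
    }
    best
  }
  obs <- scan(times, events)
  if (!is.finite(obs$p)) {
    stop("no admissible split under the minimum-group constraint",
         call. = FALSE)
  }
  res <- structure(
    list(cutpoint = obs$cut, n_low = obs$n_low, n_high = obs$n_high,
         chi2 = obs$chi2, p_value = obs$p, n = n),
    class = "cutpoint_result")
  if (n_perm > 0) {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      pb <- scan(times[idx], events[idx])$p
      if (is.finite(pb) && pb <= obs$p) hits <- hits + 1L
    }
    res$p_adjusted <- (1 + hits) / (1 + n_perm)
  }
  res
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "optimal cut-point %.6g (n = %d: %d low / %d high); log-rank chi2 = %.3f, p = %.4g\n",
    x$cutpoint, x$n, x$n_low, x$n_high, x$chi2, x$p_value))
  if (!is.null(x$p_adjusted)) {
    cat(sprintf("permutation-adjusted p = %.4g\n", x$p_adjusted))
  }
  invisible(x)
}

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Efron tie handling) of overall survival on the
#' given covariates. `imdc` is treated as a categorical factor with level
#' "1" as reference; age enters untransformed in years; any logical
#' covariate enters as 0/1.
#'
#' @param data data.frame of patients containing `time_col`, `event_col`
#'   and the covariates.
#' @param covariates character vector of covariate column names.
#' @param time_col,event_col outcome column names (defaults `os_months`,
#'   `event`).
#' @return An object of class `cox_result`: data.frame `coefficients` with
#'   term, hr, ci_lower, ci_upper, p_value; plus `loglik`, `n`, `n_events`
#'   and the underlying `fit`.
#' @export
cox_fit <- function(data, covariates, time_col = "os_months",
                    event_col = "event") {
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  miss <- setdiff(c(covariates, time_col, event_col), names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- data[stats::complete.cases(data[c(covariates, time_col, event_col)]), ]
  check_surv(df[[time_col]], df[[event_col]])
  if (sum(df[[event_col]]) < 1) stop("no events", call. = FALSE)
  if ("imdc" %in% covariates) {
    df$imdc <- factor(df$imdc, levels = c("1", "2", "3+"))
  }
  for (v in covariates) {
    if (is.logical(df[[v]])) df[[v]] <- as.integer(df[[v]])
    if (!is.factor(df[[v]]) && stats::sd(as.numeric(df[[v]])) == 0) {
      stop("covariate '", v, "' is constant", call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) {
      if (grepl("did not converge|infinite", conditionMessage(w))) {
        stop("Cox fit did not converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
      }
      suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
    })
  s <- summary(fit)
  co <- data.frame(
    term = rownames(s$coefficients),
    hr = unname(s$coefficients[, "exp(coef)"]),
    ci_lower = unname(s$conf.int[, "lower .95"]),
    ci_upper = unname(s$conf.int[, "upper .95"]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE)
  rownames(co) <- NULL
  structure(
    list(coefficients = co, loglik = fit$loglik[2], n = s$n,
         n_events = s$nevent, fit = fit),
    class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional hazards: n = %d, events = %d\n",
              x$n, x$n_events))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Minimum detectable hazard ratio of a Cox model
#'
#' Post-hoc power relation for a standardized continuous covariate in a
#' univariable Cox regression: with `d = n * p_event` expected events the
#' smallest detectable hazard ratio at two-sided level `alpha` and power
#' `power` is
#' \deqn{MDHR = \exp\left(\frac{z_{1-\alpha/2} + z_{power}}{sd\sqrt{d}}\right).}
#'
#' @param n number of patients.
#' @param p_event event probability in `(0, 1]`.
#' @param alpha two-sided significance level.
#' @param power target power (1 - beta).
#' @param sd standard deviation of the covariate (1 for standardized).
#' @return MDHR > 1.
#' @examples
#' minimum_detectable_hr(35, 0.80) # ~1.70
#' @export
minimum_detectable_hr <- function(n, p_event, alpha = 0.05, power = 0.80,
                                  sd = 1) {
  stopifnot(p_event > 0, p_event <= 1, alpha > 0, alpha < 1,
            power > 0, power < 1, sd > 0)
  events <- n * p_event
  if (events < 1) stop("fewer than one expected event", call. = FALSE)
  exp((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / (sd * sqrt(events)))
}
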