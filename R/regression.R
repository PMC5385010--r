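#' Fit an exponential decay curve
#'
#' Nonlinear least squares of `y = a * exp(-b * x)`, initialized from the
#' log-linear regression `log(y) ~ x` and refined with
#' [minpack.lm::nlsLM()]. `r2` is computed on the original scale as
#' `1 - SS_res / SS_tot`.
#'
#' @param x depths (cm).
#' @param y concentrations (> 0 for the log-linear start).
#' @param init optional named list `list(a=, b=)` overriding the start.
#' @return list of class `decay_fit`: `a`, `b`, `r2`, `half_depth_cm`
#'   (`log(2)/b` when `b > 0`, else `NA`), and `non_decay` (`TRUE` when the
#'   fitted `b <= 0`, e.g. for constant input).
#' @export
fit_exponential_decay <- function(x, y, init = NULL) {
  stop_if(length(x) != length(y) || length(x) < 3, "need >= 3 (x, y) points")
  stop_if(any(y <= 0) && is.null(init),
          "y must be positive for log-linear initialization (or supply init)")
  if (is.null(init)) {
    ll <- stats::lm(log(y) ~ x)
    init <- list(a = exp(unname(stats::coef(ll)[1])),
                 b = -unname(stats::coef(ll)[2]))
    if (init$b <= 1e-8) {
      # no decay signal even on the log scale: flag rather than fit
      pred <- init$a * exp(-max(init$b, 0) * x)
      r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
      return(structure(list(a = init$a, b = max(init$b, 0), r2 = r2,
                            half_depth_cm = NA_real_, non_decay = TRUE),
                       class = "decay_fit"))
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b * x), start = init,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  co <- stats::coef(fit)
  a <- unname(co["a"]); b <- unname(co["b"])
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  non_decay <- b <= 1e-8
  structure(list(a = a, b = b, r2 = r2,
                 half_depth_cm = if (non_decay) NA_real_ else log(2) / b,
                 non_decay = non_decay),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$non_decay) {
    cat("decay_fit: flagged non-decay (fitted rate <= 0)\n")
  } else {
    cat(sprintf("decay_fit: y = %.4g * exp(-%.4g x), r2 = %.3f, half-depth %.2f cm\n",
                x$a, x$b, x$r2, x$half_depth_cm))
  }
  invisible(x)
}

#' Half-depth of an exponential decay
#'
#' @param fit a `decay_fit`, or a decay rate per cm.
#' @return `log(2) / b` in cm.
#' @export
half_depth <- function(fit) {
  b <- if (inherits(fit, "decay_fit")) fit$b else fit
  stop_if(!is.numeric(b) || b <= 0, "decay rate must be positive")
  log(2) / b
}

#' Depth-to-age model
#'
#' Either a constant sedimentation rate (`age = depth / rate`) or monotone
#' piecewise-linear interpolation between (depth, age) anchor points, as
#' obtained from radiometric dating.
#'
#' @param rate_cm_per_year sedimentation rate for `mode = "linear_rate"`.
#' @param anchors data frame with strictly increasing `depth_cm` and
#'   `age_years` for `mode = "anchor_points"`.
#' @return object of class `age_model`.
#' @export
age_model <- function(rate_cm_per_year = NULL, anchors = NULL) {
  if (!is.null(rate_cm_per_year)) {
    stop_if(rate_cm_per_year <= 0, "sedimentation rate must be positive")
    return(structure(list(mode = "linear_rate", rate = rate_cm_per_year),
                     class = "age_model"))
  }
  stop_if(is.null(anchors), "supply a rate or anchor points")
  stop_if(any(diff(anchors$depth_cm) <= 0) || any(diff(anchors$age_years) <= 0),
          "anchors must be strictly increasing in depth and age")
  structure(list(mode = "anchor_points", anchors = anchors), class = "age_model")
}

#' Convert depth to age
#'
#' @param z depth(s) in cm.
#' @param model an [age_model()].
#' @return age(s) in years.
#' @export
depth_to_age <- function(z, model) {
  stop_if(!inherits(model, "age_model"), "need an age_model")
  if (model$mode == "linear_rate") return(z / model$rate)
  a <- model$anchors
  stats::approx(c(0, a$depth_cm), c(0, a$age_years), xout = z, rule = 2)$y
}

#' Inverse of [depth_to_age()] for linear-rate models
#' @param age age in years.
#' @param model an [age_model()] with `mode = "linear_rate"`.
#' @return depth in cm.
#' @export
age_to_depth <- function(age, model) {
  stop_if(model$mode != "linear_rate", "inverse implemented for linear rate")
  age * model$rate
}

#' Half-life of a decay fit under an age model
#'
#' @param fit a `decay_fit`.
#' @param model an [age_model()].
#' @return half-life in years (`depth_to_age(half_depth)`).
#' @export
half_life_years <- function(fit, model) depth_to_age(half_depth(fit), model)

#' Sequential variance partition of a multiple regression
#'
#' Ordinary least squares of `y` on the predictors in the given order, with
#' each predictor's explained share taken from the sequential (type I) sums
#' of squares as a fraction of total SS; shares therefore sum to the model
#' R-squared. Residual diagnostics (Shapiro--Wilk p, max Cook's distance)
#' are reported.
#'
#' @param y response vector.
#' @param predictors data frame or matrix of predictors, in fitting order
#'   (e.g. arc-sine-square-root transformed domain proportions).
#' @param exclude optional integer indices of rows to drop before fitting
#'   (stated outlier exclusions).
#' @return list with `shares` (named, per predictor), `r2`, `shapiro_p`,
#'   `max_cooks`, `fit`.
#' @export
variance_partition_regression <- function(y, predictors, exclude = NULL) {
  predictors <- as.data.frame(predictors)
  if (!is.null(exclude) && length(exclude) > 0) {
    y <- y[-exclude]
    predictors <- predictors[-exclude, , drop = FALSE]
  }
  stop_if(length(y) <= ncol(predictors) + 1, "too few rows after exclusions")
  X <- as.matrix(predictors)
  stop_if(kappa(cbind(1, scale(X))) > 1e8, "predictors are collinear")
  dat <- data.frame(y = y, predictors)
  fit <- stats::lm(y ~ ., data = dat)
  an <- stats::anova(fit)
  ss <- an$`Sum Sq`
  total_ss <- sum(ss)
  shares <- ss[-length(ss)] / total_ss
  names(shares) <- rownames(an)[-nrow(an)]
  res <- stats::resid(fit)
  shapiro_p <- if (stats::sd(res) > 1e-10) {
    stats::shapiro.test(res)$p.value
  } else NA_real_ # perfect fit: normality test undefined
  cooks <- stats::cooks.distance(fit)
  list(shares = shares, r2 = summary(fit)$r.squared,
       shapiro_p = shapiro_p,
       max_cooks = if (all(is.finite(cooks))) max(cooks) else NA_real_,
       fit = fit)
}

#' Linear trend of the richness component with depth
#'
#' OLS of the richness-difference component on layer midpoint depth, with
#' the depth at which the fitted component reaches 1 (complete dominance of
#' richness loss) obtained by extrapolating the fitted line.
#'
#' @param depths layer midpoint depths (cm).
#' @param richness_components per-layer richness components (surface
#'   profile, see [surface_distance_profile()]).
#' @param exclude optional indices of layers to drop (e.g. a surface
#'   outlier).
#' @return list with `slope`, `intercept`, `r2`, `f`, `df`, `p`,
#'   `extrapolated_depth_cm` (`NA` with a flag when the slope is not
#'   positive).
#' @export
richness_trend <- function(depths, richness_components, exclude = NULL) {
  if (!is.null(exclude) && length(exclude) > 0) {
    depths <- depths[-exclude]
    richness_components <- richness_components[-exclude]
  }
  stop_if(length(depths) < 3, "need >= 3 layers after exclusions")
  fit <- stats::lm(richness_components ~ depths)
  s <- suppressWarnings(summary(fit)) # tolerate exact linear input
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  extrap <- if (slope > 0) (1 - intercept) / slope else NA_real_
  list(slope = slope, intercept = intercept, r2 = s$r.squared,
       f = unname(s$fstatistic[1]), df = unname(s$fstatistic[3]),
       p = stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                     lower.tail = FALSE),
       extrapolated_depth_cm = extrap, non_increasing = slope <= 0)
}
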