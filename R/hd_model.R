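# Height-diameter allometry: second-order polynomial in log-log space,
# ln(H) = a + b ln(D) + c (ln D)^2 + eps, eps ~ N(0, sigma).

#' Fit a height-diameter model
#'
#' Ordinary least squares of \eqn{\ln H} on \eqn{[1, \ln D, (\ln D)^2]} over
#' trees with a measured height. The residual SD \code{sigma} feeds the
#' Baskerville back-transformation correction \eqn{\exp(\sigma^2/2)} applied
#' when predicting heights on the natural scale.
#'
#' @param trees data.frame with columns \code{dbh_cm} and \code{h_m}
#'   (trees without height are ignored), or a numeric vector of diameters
#'   when \code{h} is given.
#' @param h optional numeric vector of heights (m) matching \code{trees}
#'   given as diameters.
#' @param min_n minimum number of height-measured trees (default 30).
#' @return an object of class \code{hd_model} with coefficients \code{a},
#'   \code{b}, \code{c}, residual SD \code{sigma}, coefficient covariance,
#'   sample size and back-transformed fit statistics.
#' @export
fit_hd <- function(trees, h = NULL, min_n = 30) {
  if (is.data.frame(trees)) {
    keep <- !is.na(trees$h_m) & !is.na(trees$dbh_cm)
    d <- trees$dbh_cm[keep]; hh <- trees$h_m[keep]
  } else {
    d <- trees; hh <- h
  }
  if (length(d) < min_n) {
    stop("need at least ", min_n, " height-measured trees (got ",
         length(d), ")", call. = FALSE)
  }
  if (any(d <= 0) || any(hh <= 0)) {
    stop("D and H must be > 0", call. = FALSE)
  }
  if (length(unique(round(d, 10))) < 3) {
    stop("rank-deficient design: need at least 3 distinct diameters",
         call. = FALSE)
  }
  ld <- log(d)
  fit <- lm(log(hh) ~ ld + I(ld^2))
  cf <- unname(coef(fit))
  s <- summary(fit)$sigma
  pred <- exp(fitted(fit) + s^2 / 2)
  rmse_m <- sqrt(mean((hh - pred)^2))
  r2 <- 1 - sum((hh - pred)^2) / sum((hh - mean(hh))^2)
  structure(
    list(a = cf[1], b = cf[2], c = cf[3], sigma = s,
         coef_vcov = unname(vcov(fit)), n = length(d),
         coef_se = unname(summary(fit)$coefficients[, 2]),
         r2 = r2, rmse_m = rmse_m,
         baskerville = exp(s^2 / 2)),
    class = "hd_model"
  )
}

#' Construct an H-D model from known coefficients
#'
#' Useful for published coefficient tables or generative truths; the
#' coefficient covariance defaults to zero (coefficients treated as fixed).
#'
#' @param a,b,c coefficients of \eqn{\ln H = a + b \ln D + c (\ln D)^2}.
#' @param sigma residual SD (log units).
#' @param coef_vcov optional 3x3 coefficient covariance.
#' @param n optional training-sample size.
#' @return an \code{hd_model}.
#' @export
hd_model <- function(a, b, c, sigma, coef_vcov = matrix(0, 3, 3), n = NA) {
  stopifnot(sigma >= 0, all(dim(coef_vcov) == c(3, 3)))
  if (max(abs(coef_vcov - t(coef_vcov))) > 1e-8) {
    stop("coef_vcov must be symmetric", call. = FALSE)
  }
  structure(
    list(a = a, b = b, c = c, sigma = sigma, coef_vcov = coef_vcov,
         n = n, coef_se = sqrt(diag(coef_vcov)), r2 = NA, rmse_m = NA,
         baskerville = exp(sigma^2 / 2)),
    class = "hd_model"
  )
}

#' @export
print.hd_model <- function(x, ...) {
  cat("Height-diameter model: ln(H) = a + b ln(D) + c (ln D)^2\n")
  cat(sprintf("  a = %.4f, b = %.4f, c = %.4f, sigma = %.4f (n = %s)\n",
              x$a, x$b, x$c, x$sigma, format(x$n)))
  if (!is.na(x$r2)) {
    cat(sprintf("  back-transformed R2 = %.3f, RMSE = %.2f m\n",
                x$r2, x$rmse_m))
  }
  invisible(x)
}

#' @export
coef.hd_model <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @export
vcov.hd_model <- function(object, ...) object$coef_vcov

#' @export
sigma.hd_model <- function(object, ...) object$sigma

#' @export
summary.hd_model <- function(object, ...) {
  out <- data.frame(
    coefficient = c("a", "b", "c"),
    estimate = c(object$a, object$b, object$c),
    se = if (length(object$coef_se)) object$coef_se else rep(NA_real_, 3)
  )
  attr(out, "sigma") <- object$sigma
  attr(out, "n") <- object$n
  out
}

#' Predict tree height from diameter
#'
#' \eqn{H = \exp(a + b \ln D + c (\ln D)^2)}, optionally multiplied by the
#' Baskerville lognormal correction \eqn{\exp(\sigma^2/2)}.
#'
#' @param model an \code{hd_model}.
#' @param dbh diameters in cm (>= 10 in routine use; must be > 0).
#' @param correct apply the Baskerville correction (default TRUE).
#' @return predicted heights in m.
#' @export
predict_height <- function(model, dbh, correct = TRUE) {
  stopifnot(inherits(model, "hd_model"))
  if (any(dbh <= 0)) stop("dbh must be > 0", call. = FALSE)
  ld <- log(dbh)
  h <- exp(model$a + model$b * ld + model$c * ld^2)
  if (correct) h <- h * model$baskerville
  h
}

#' @export
predict.hd_model <- function(object, newdata, correct = TRUE, ...) {
  dbh <- if (is.data.frame(newdata)) newdata$dbh_cm else newdata
  predict_height(object, dbh, correct = correct)
}
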