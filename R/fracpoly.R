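# Fractional polynomial selection for continuous covariates.
# Candidate powers {-2,-1,-0.5,0,0.5,1,2,3}, 0 meaning log. An FP transform
# is adopted only when it improves the deviance over both the linear and the
# quadratic fit by more than a chi-square threshold.

fp_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

# FP basis columns for powers p (repeated power p,p -> x^p, x^p log x)
fp_basis <- function(x, powers) {
  one <- function(p) if (p == 0) log(x) else x^p
  if (length(powers) == 1) {
    m <- cbind(one(powers))
  } else if (powers[1] == powers[2]) {
    m <- cbind(one(powers[1]), one(powers[1]) * log(x))
  } else {
    m <- cbind(one(powers[1]), one(powers[2]))
  }
  colnames(m) <- paste0("fp", seq_len(ncol(m)))
  m
}

#' Select a fractional polynomial transform for one covariate
#'
#' Compares linear, quadratic, best first-degree (FP1) and best second-degree
#' (FP2) fractional polynomial fits of `outcome` on `covariate` (optionally
#' adjusted for further linear terms), using the Gaussian deviance
#' `n * log(RSS/n)`. FP2 is preferred over FP1 when it gains more than
#' `threshold`; the winning FP is adopted only when it improves on the better
#' of the linear and quadratic fits by more than `threshold`, otherwise the
#' quadratic is kept if it beats the linear by `threshold`, else the linear.
#'
#' Non-positive covariates are shifted before transformation and covariates
#' are rescaled to order 1; both constants are recorded and reapplied by
#' [fp_transform()].
#'
#' @param data data.frame.
#' @param outcome,covariate column names.
#' @param adjust optional character vector of additional linear adjustment
#'   terms.
#' @param threshold chi-square deviance gain required (default 4.605, the
#'   0.10-level on 2 df).
#' @return Object of class `fp_selection` with the chosen model
#'   (`"linear"`, `"quadratic"`, `"fp1"`, `"fp2"` or `"omit"`), its powers,
#'   the deviance table, and the shift/scale constants.
#' @export
select_fractional_polynomial <- function(data, outcome, covariate,
                                         adjust = NULL, threshold = 4.605) {
  keep <- complete.cases(data[, c(outcome, covariate, adjust), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  y <- d[[outcome]]
  x <- d[[covariate]]
  n <- length(y)
  if (length(unique(x)) < 2) {
    return(structure(list(covariate = covariate, chosen = "omit",
                          powers = NULL, deviances = NULL,
                          shift = 0, scale = 1, threshold = threshold),
                     class = "fp_selection"))
  }
  shift <- if (min(x) <= 0) -min(x) + sd(x) / 100 else 0
  xs <- x + shift
  scl <- 10^floor(log10(max(xs)))
  xs <- xs / scl

  Z <- if (is.null(adjust)) {
    matrix(1, n, 1)
  } else {
    model.matrix(as.formula(paste("~", paste(adjust, collapse = "+"))), d)
  }
  dev <- function(M) {
    f <- lm.fit(cbind(Z, M), y)
    n * log(sum(f$residuals^2) / n)
  }
  dev_lin <- dev(cbind(xs))
  dev_quad <- dev(cbind(xs, xs^2))

  p1 <- fp_powers()
  dev_fp1 <- vapply(p1, function(p) dev(fp_basis(xs, p)), numeric(1))
  best1 <- which.min(dev_fp1)

  pairs <- expand.grid(a = p1, b = p1)
  pairs <- pairs[pairs$a <= pairs$b, ]
  dev_fp2 <- mapply(function(a, b) dev(fp_basis(xs, c(a, b))),
                    pairs$a, pairs$b)
  best2 <- which.min(dev_fp2)

  fp_pow <- if (dev_fp1[best1] - dev_fp2[best2] > threshold) {
    c(pairs$a[best2], pairs$b[best2])
  } else {
    p1[best1]
  }
  dev_fp <- if (length(fp_pow) == 2) dev_fp2[best2] else dev_fp1[best1]

  base <- min(dev_lin, dev_quad)
  chosen <- if (base - dev_fp > threshold) {
    if (length(fp_pow) == 2) "fp2" else "fp1"
  } else if (dev_lin - dev_quad > threshold) {
    "quadratic"
  } else {
    "linear"
  }
  powers <- switch(chosen,
                   linear = 1, quadratic = c(1, 2),
                   fp1 = fp_pow, fp2 = fp_pow, NULL)
  structure(list(
    covariate = covariate, chosen = chosen, powers = powers,
    deviances = c(linear = dev_lin, quadratic = dev_quad,
                  fp1 = dev_fp1[best1], fp2 = dev_fp2[best2]),
    fp1_power = p1[best1],
    fp2_powers = c(pairs$a[best2], pairs$b[best2]),
    shift = shift, scale = scl, threshold = threshold
  ), class = "fp_selection")
}

#' Evaluate the selected transform on new covariate values
#'
#' @param sel an [select_fractional_polynomial()] result.
#' @param x covariate values on the original scale.
#' @return Numeric matrix with one column per basis term of the chosen model.
#' @export
fp_transform <- function(sel, x) {
  stopifnot(inherits(sel, "fp_selection"))
  if (sel$chosen == "omit") stop("covariate was omitted (constant)")
  xs <- (x + sel$shift) / sel$scale
  m <- switch(sel$chosen,
              linear = cbind(fp1 = xs),
              quadratic = cbind(fp1 = xs, fp2 = xs^2),
              fp_basis(xs, sel$powers))
  colnames(m) <- paste0(sel$covariate, "..", seq_len(ncol(m)))
  m
}

#' @export
print.fp_selection <- function(x, ...) {
  cat("Fractional polynomial selection for", x$covariate, "\n")
  cat("  chosen:", x$chosen,
      if (!is.null(x$powers)) paste0("(powers ",
                                     paste(x$powers, collapse = ", "), ")"),
      "\n")
  if (!is.null(x$deviances)) {
    print(round(x$deviances, 2))
  }
  invisible(x)
}
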