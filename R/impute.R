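# Multiple imputation by chained equations, with proper (Bayesian-draw)
# linear and logistic imputation models, and Rubin's rules for pooling.

# proper linear imputation: draw sigma^2 and beta from their posterior,
# then draw the missing outcomes
draw_norm <- function(X, y, obs, Xmis) {
  f <- lm.fit(X[obs, , drop = FALSE], y[obs])
  ok <- !is.na(f$coefficients)
  if (!all(ok)) {               # drop aliased columns
    X <- X[, ok, drop = FALSE]
    Xmis <- Xmis[, ok, drop = FALSE]
    f <- lm.fit(X[obs, , drop = FALSE], y[obs])
  }
  p <- ncol(X)
  df <- sum(obs) - p
  rss <- sum(f$residuals^2)
  sigma2 <- rss / rchisq(1, df)
  R <- qr.R(f$qr)
  beta <- f$coefficients + sqrt(sigma2) * backsolve(R, rnorm(p))
  drop(Xmis %*% beta) + rnorm(nrow(Xmis), 0, sqrt(sigma2))
}

# proper logistic imputation via a normal approximation to the posterior
draw_logit <- function(X, y, obs, Xmis, levels2) {
  yb <- as.integer(y[obs] == levels2[2])
  f <- suppressWarnings(glm.fit(X[obs, , drop = FALSE], yb,
                                family = binomial()))
  co <- f$coefficients
  ok <- !is.na(co)
  X2 <- X[obs, ok, drop = FALSE]
  w <- f$weights
  V <- chol2inv(chol(crossprod(X2 * sqrt(w))))
  beta <- co[ok] + drop(chol(V) %*% rnorm(sum(ok)))
  p <- plogis(drop(Xmis[, ok, drop = FALSE] %*% beta))
  levels2[1 + rbinom(nrow(Xmis), 1, p)]
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed datasets. Each incomplete column is imputed from a
#' regression on all other modelled columns: a proper Bayesian linear model
#' for continuous columns and a logistic model for binary columns, cycled
#' `maxit` times per imputation from a random starting fill.
#'
#' @param records data.frame with missing values only in imputable columns.
#' @param m number of imputations (default 20).
#' @param maxit chained-equation cycles per imputation (default 10).
#' @param seed optional integer seed.
#' @param exclude columns excluded from both imputation and prediction
#'   (identifiers).
#' @return An object of class `imputation_set`: list with `imputations`
#'   (list of `m` complete data.frames), the missingness pattern, and
#'   per-chain means of each imputed column for convergence checks.
#' @export
impute_chained <- function(records, m = 20, maxit = 10, seed = NULL,
                           exclude = c("patient_id", "hospital_id")) {
  if (m < 1) stop("m must be >= 1")
  m <- as.integer(m)
  maxit <- as.integer(maxit)
  if (!is.null(seed)) set.seed(seed)
  vars <- setdiff(names(records), exclude)
  miss_frac <- vapply(records[vars], function(x) mean(is.na(x)), numeric(1))
  if (any(miss_frac == 1)) {
    stop("column(s) 100% missing: ",
         paste(vars[miss_frac == 1], collapse = ", "))
  }
  targets <- vars[miss_frac > 0]

  if (length(targets) == 0) {
    return(structure(list(
      imputations = replicate(m, records, simplify = FALSE),
      m = m, maxit = maxit, targets = character(0),
      missing = lapply(records[vars], function(x) which(is.na(x))),
      chain_means = NULL, seed = seed
    ), class = "imputation_set"))
  }

  miss_idx <- lapply(records[targets], function(x) which(is.na(x)))
  preds <- vars
  is_binary <- vapply(records[targets], function(x) {
    length(unique(na.omit(x))) == 2
  }, logical(1))
  bin_levels <- lapply(records[targets], function(x) sort(unique(na.omit(x))))

  imps <- vector("list", m)
  chain_means <- array(NA_real_, dim = c(m, maxit, length(targets)),
                       dimnames = list(NULL, NULL, targets))
  for (k in seq_len(m)) {
    d <- records
    for (j in targets) {      # random draw from the observed margin
      idx <- miss_idx[[j]]
      d[[j]][idx] <- sample(na.omit(records[[j]]), length(idx),
                            replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (j in targets) {
        idx <- miss_idx[[j]]
        obs <- rep(TRUE, nrow(d))
        obs[idx] <- FALSE
        rhs <- setdiff(preds, j)
        X <- model.matrix(~ ., data = d[rhs])
        if (is_binary[[j]]) {
          d[[j]][idx] <- draw_logit(X, d[[j]], obs, X[idx, , drop = FALSE],
                                    bin_levels[[j]])
        } else {
          d[[j]][idx] <- draw_norm(X, d[[j]], obs, X[idx, , drop = FALSE])
        }
        chain_means[k, it, j] <- mean(as.numeric(d[[j]][idx]))
      }
    }
    imps[[k]] <- d
  }
  structure(list(imputations = imps, m = m, maxit = maxit, targets = targets,
                 missing = miss_idx, chain_means = chain_means, seed = seed),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set: m =", x$m, ", cycles =", x$maxit, "\n")
  if (length(x$targets)) {
    cat("  imputed columns:", paste(x$targets, collapse = ", "), "\n")
  } else {
    cat("  no missing data (datasets identical to input)\n")
  }
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the total
#' variance is the mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance.
#'
#' @param estimates numeric vector (one scalar per imputation) or an
#'   `m x p` matrix of coefficient vectors.
#' @param variances numeric vector of variances, or a list of `m` `p x p`
#'   covariance matrices.
#' @return List with `estimate`, `variance` (total; a matrix when pooling
#'   coefficient vectors), `within`, `between`, and `m`.
#' @export
pool_rubin <- function(estimates, variances) {
  if (is.matrix(estimates)) {
    m <- nrow(estimates)
    if (m < 2) stop("Rubin's rules require m >= 2")
    if (length(variances) != m) {
      stop("estimates and variances must have equal length")
    }
    qbar <- colMeans(estimates)
    ubar <- Reduce(`+`, variances) / m
    dev <- sweep(estimates, 2, qbar)
    B <- crossprod(dev) / (m - 1)
    list(estimate = qbar, variance = ubar + (1 + 1 / m) * B,
         within = ubar, between = B, m = m)
  } else {
    m <- length(estimates)
    if (m < 2) stop("Rubin's rules require m >= 2")
    if (length(variances) != m) {
      stop("estimates and variances must have equal length")
    }
    qbar <- mean(estimates)
    ubar <- mean(variances)
    B <- var(estimates)
    list(estimate = qbar, variance = ubar + (1 + 1 / m) * B,
         within = ubar, between = B, m = m)
  }
}
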