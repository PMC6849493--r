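#' Partial correlations implied by a precision matrix
#'
#' `rho_ij = -kappa_ij / sqrt(kappa_ii * kappa_jj)`, with the diagonal set
#' to zero.
#'
#' @param precision Symmetric matrix with strictly positive diagonal.
#' @return Symmetric partial-correlation matrix with zero diagonal.
#' @export
partial_correlations <- function(precision) {
  if (!isTRUE(all.equal(precision, t(precision), tolerance = 1e-8)))
    stop("`precision` must be symmetric")
  d <- diag(precision)
  if (any(d <= 0)) stop("`precision` must have a positive diagonal")
  s <- 1 / sqrt(d)
  R <- -precision * outer(s, s)
  diag(R) <- 0
  R
}

#' Extended Bayesian information criterion
#'
#' `EBIC = -2 * loglik + k * ln(n) + 2 * gamma * k * ln(p)`. With
#' `gamma = 0` this is the ordinary BIC.
#'
#' @param loglik Model log-likelihood.
#' @param k Number of free parameters (edges).
#' @param n Sample size.
#' @param p Number of variables.
#' @param gamma EBIC hyperparameter (0 or larger); larger values favor
#'   sparser models.
#' @return The EBIC value (smaller is better).
#' @export
ebic_score <- function(loglik, k, n, p, gamma) {
  stopifnot(n >= 1, p >= 1, k >= 0, gamma >= 0)
  -2 * loglik + k * log(n) + 2 * gamma * k * log(p)
}

#' Estimation settings
#'
#' @param data_kind `"continuous"` (partial-correlation model) or
#'   `"binary"` (Ising model).
#' @param gamma EBIC hyperparameter; defaults to 0.5 for continuous data
#'   and 0.25 for binary data, the conventions of the standard fitting
#'   tools in this field.
#' @param n_lambda Size of the penalty grid.
#' @param lambda_min_ratio Smallest-to-largest penalty ratio.
#' @param rule Edge reconciliation for nodewise Ising fits: `"AND"`
#'   (default; both directed coefficients nonzero) or `"OR"`.
#' @return An `estimation_config` list.
#' @export
estimation_config <- function(data_kind = c("continuous", "binary"),
                              gamma = NULL, n_lambda = 100,
                              lambda_min_ratio = 0.01,
                              rule = c("AND", "OR")) {
  data_kind <- match.arg(data_kind)
  rule <- match.arg(rule)
  if (is.null(gamma)) gamma <- if (data_kind == "continuous") 0.5 else 0.25
  stopifnot(gamma >= 0, n_lambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(data_kind = data_kind, gamma = gamma,
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio, rule = rule),
            class = "estimation_config")
}

# Graphical lasso by block coordinate descent (Friedman-style sweep over
# columns, inner lasso solved by coordinate descent). S must be a
# correlation/covariance matrix; returns the estimated precision. Only
# off-diagonal entries are penalized, the convention of EBIC-glasso
# network estimation in psychometrics.
glasso_fit <- function(S, lambda, W_init = NULL, tol = 1e-5, maxit = 200) {
  p <- nrow(S)
  W <- if (is.null(W_init)) S else W_init
  B <- matrix(0, p - 1, p)
  thr <- tol * mean(abs(S[upper.tri(S)]))
  if (!is.finite(thr) || thr == 0) thr <- tol
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[, j]
      # inner lasso: 0.5 b'W11 b - s12'b + lambda|b|_1
      for (inner in seq_len(100)) {
        bmax <- 0
        for (k in seq_len(p - 1)) {
          r <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
          bnew <- sign(r) * max(abs(r) - lambda, 0) / W11[k, k]
          if (bnew != beta[k]) {
            bmax <- max(bmax, abs(bnew - beta[k]))
            beta[k] <- bnew
          }
        }
        if (bmax < thr) break
      }
      B[, j] <- beta
      w12 <- drop(W11 %*% beta)
      W[idx, j] <- W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)[upper.tri(W)]) < thr) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    Theta[j, j] <- theta_jj
    Theta[idx, j] <- -B[, j] * theta_jj
  }
  Theta <- (Theta + t(Theta)) / 2
  list(Theta = Theta, W = W)
}

# Unpenalized Gaussian MLE of the precision matrix constrained to a fixed
# zero pattern (same block coordinate descent, no soft threshold). Used to
# score candidate supports with EBIC free of shrinkage bias.
constrained_mle <- function(S, mask, tol = 1e-6, maxit = 200) {
  p <- nrow(S)
  W <- S
  B <- matrix(0, p - 1, p)
  thr <- tol * mean(abs(S[upper.tri(S)]))
  if (!is.finite(thr) || thr == 0) thr <- tol
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      allowed <- mask[idx, j]
      beta <- B[, j]
      if (any(allowed)) {
        W11 <- W[idx, idx, drop = FALSE]
        s12 <- S[idx, j]
        for (inner in seq_len(100)) {
          bmax <- 0
          for (k in which(allowed)) {
            r <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
            bnew <- r / W11[k, k]
            if (bnew != beta[k]) {
              bmax <- max(bmax, abs(bnew - beta[k]))
              beta[k] <- bnew
            }
          }
          if (bmax < thr) break
        }
        B[, j] <- beta
        W[idx, j] <- W[j, idx] <- drop(W[idx, idx, drop = FALSE] %*% beta)
      } else {
        B[, j] <- 0
        W[idx, j] <- W[j, idx] <- 0
      }
    }
    if (mean(abs(W - W_old)[upper.tri(W)]) < thr) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    Theta[j, j] <- theta_jj
    Theta[idx, j] <- -B[, j] * theta_jj
  }
  (Theta + t(Theta)) / 2
}

#' Estimate a regularized partial-correlation network from continuous data
#'
#' Fits a graphical-lasso solution path over a log-spaced penalty grid
#' running from the smallest penalty that empties the graph down to
#' `lambda_min_ratio` times that value, scores every candidate with the
#' EBIC (Gaussian log-likelihood of the penalized precision estimate), and
#' returns the minimizing model as a weighted network of partial
#' correlations.
#'
#' @param data Numeric matrix, observations by symptoms (at least 3 rows,
#'   no zero-variance column). Column names become symptom labels.
#' @param config An [estimation_config()] with `data_kind = "continuous"`.
#' @return An `estimated_network`: `network` (a `symptom_network` of
#'   partial correlations), `selected_lambda`, `ebic_path` (data frame of
#'   lambda, edge count, EBIC), `gamma`.
#' @export
estimate_ggm <- function(data, config = estimation_config("continuous")) {
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (n < 3) stop("need at least 3 observations")
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(data)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  labels <- colnames(data)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  S <- stats::cor(data)
  lam_max <- max(abs(S[upper.tri(S)]))
  lambdas <- exp(seq(log(lam_max), log(lam_max * config$lambda_min_ratio),
                     length.out = config$n_lambda))
  best <- NULL
  path <- data.frame(lambda = lambdas, k = NA_real_, ebic = NA_real_)
  W <- NULL
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(lambdas)) {
    fit <- tryCatch(glasso_fit(S, lambdas[i], W_init = W),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("graphical lasso failed to converge at lambda = ",
              signif(lambdas[i], 4), "; candidate dropped")
      next
    }
    W <- fit$W
    mask <- abs(fit$Theta) > 1e-7
    diag(mask) <- FALSE
    k <- sum(mask[upper.tri(mask)])
    # EBIC on the support-constrained unpenalized MLE: one score per
    # distinct support along the path
    key <- paste0("s", paste(which(mask[upper.tri(mask)]), collapse = ","))
    if (is.null(seen[[key]])) {
      Theta <- tryCatch(constrained_mle(S, mask), error = function(e) NULL)
      if (is.null(Theta)) { seen[[key]] <- list(ebic = Inf); next }
      ld <- determinant(Theta, logarithm = TRUE)
      if (ld$sign <= 0) { seen[[key]] <- list(ebic = Inf); next }
      loglik <- (n / 2) * (as.numeric(ld$modulus) - sum(S * Theta))
      seen[[key]] <- list(ebic = ebic_score(loglik, k, n, p, config$gamma),
                          Theta = Theta)
    }
    cand <- seen[[key]]
    path$k[i] <- k; path$ebic[i] <- cand$ebic
    if (is.finite(cand$ebic) && (is.null(best) || cand$ebic < best$ebic))
      best <- list(ebic = cand$ebic, lambda = lambdas[i], Theta = cand$Theta)
  }
  if (is.null(best)) stop("no graphical-lasso candidate converged")
  pc <- partial_correlations(best$Theta)
  pc[abs(pc) < 1e-7] <- 0
  dimnames(pc) <- list(labels, labels)
  structure(list(network = symptom_network(pc, labels = labels),
                 selected_lambda = best$lambda,
                 ebic_path = path,
                 gamma = config$gamma),
            class = "estimated_network")
}

#' Estimate an Ising network from binary data
#'
#' Each symptom is regressed on all others by L1-penalized logistic
#' regression; the per-node penalty is chosen by EBIC. An edge is kept when
#' both directed coefficients are nonzero (`rule = "AND"`, default) or when
#' either is (`"OR"`); its weight is the arithmetic mean of the two
#' directed coefficients.
#'
#' @param data 0/1 matrix, observations by symptoms; every column must show
#'   both values.
#' @param config An [estimation_config()] with `data_kind = "binary"`.
#' @return An `estimated_network` with per-node `selected_lambda`.
#' @export
estimate_ising <- function(data, config = estimation_config("binary")) {
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (p < 3) stop("need at least 3 symptoms for nodewise fits")
  if (!all(data %in% c(0, 1))) stop("`data` must contain only 0 and 1")
  cm <- colMeans(data)
  if (any(cm == 0 | cm == 1)) {
    bad <- which(cm == 0 | cm == 1)
    stop("constant column(s): ", paste(bad, collapse = ", "))
  }
  labels <- colnames(data)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  B <- matrix(0, p, p)
  sel_lambda <- numeric(p)
  for (j in seq_len(p)) {
    fit <- tryCatch(
      glmnet::glmnet(data[, -j, drop = FALSE], data[, j], family = "binomial",
                     alpha = 1, nlambda = config$n_lambda,
                     lambda.min.ratio = config$lambda_min_ratio),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("nodewise fit failed for ", labels[j],
              " (possible separation); falling back to the empty neighborhood")
      sel_lambda[j] <- Inf
      next
    }
    loglik <- -(1 - fit$dev.ratio) * fit$nulldev / 2
    k <- fit$df
    e <- ebic_score(loglik, k, n, p, config$gamma)
    i <- which.min(e)
    sel_lambda[j] <- fit$lambda[i]
    B[j, -j] <- as.numeric(fit$beta[, i])
  }
  nz <- B != 0
  keep <- if (config$rule == "AND") nz & t(nz) else nz | t(nz)
  Wm <- ifelse(keep, (B + t(B)) / 2, 0)
  diag(Wm) <- 0
  dimnames(Wm) <- list(labels, labels)
  structure(list(network = symptom_network(Wm, labels = labels),
                 selected_lambda = sel_lambda,
                 ebic_path = NULL,
                 gamma = config$gamma,
                 rule = config$rule),
            class = "estimated_network")
}

#' @export
print.estimated_network <- function(x, ...) {
  cat("estimated_network (gamma = ", x$gamma, ")\n", sep = "")
  print(x$network)
  invisible(x)
}
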