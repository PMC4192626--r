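# Pedigree-aware linear mixed model:
#   y = X beta + g + e,   g ~ (0, sigma2_g * A),   e ~ (0, sigma2_e * I)
# where A is the expected additive relationship matrix (2 x kinship) derived
# from the pedigree by the recursive tabular method. Variance components are
# estimated by REML after rotating the model through the eigendecomposition
# of A, which reduces the problem to a 1-D search over the variance ratio
# lambda = sigma2_g / sigma2_e.

#' Additive relationship matrix from a pedigree
#'
#' Computes the expected additive relationship (twice the kinship
#' coefficient) by the recursive tabular method, with founders unrelated and
#' non-inbred: A(i,i) = 1 + A(f_i, m_i)/2 and A(i,j) = (A(f_i,j) + A(m_i,j))/2
#' for a non-founder i with j already placed. The matrix is symmetric,
#' positive semidefinite and block-diagonal across families.
#'
#' @param ped pedigree_table.
#' @return n x n numeric matrix with sample-id dimnames and a `families`
#'   attribute giving each individual's family.
#' @export
relationship_matrix <- function(ped) {
  ord <- ped_topological_order(ped)
  ids <- ped$individual_id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  pos <- match(ids, ids)
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  placed <- integer(0)
  for (i in ord) {
    f <- fa[i]
    m <- mo[i]
    if (is.na(f) && is.na(m)) {
      A[i, i] <- 1
    } else {
      # one recorded parent is treated as an unrelated, non-inbred founder
      row_f <- if (is.na(f)) 0 else A[f, placed]
      row_m <- if (is.na(m)) 0 else A[m, placed]
      if (length(placed) > 0L) {
        val <- (row_f + row_m) / 2
        A[i, placed] <- val
        A[placed, i] <- val
      }
      A[i, i] <- 1 + (if (is.na(f) || is.na(m)) 0 else A[f, m] / 2)
    }
    placed <- c(placed, i)
  }
  attr(A, "families") <- stats::setNames(ped$family_id, ids)
  A
}

# Rotate y and X through the eigendecomposition of A. When a family grouping
# is supplied the matrix is block-diagonal and the decomposition is done per
# family block, which is far cheaper than a dense eigendecomposition.
rotate_by_relationship <- function(y, X, A, families = NULL) {
  n <- length(y)
  d <- numeric(n)
  ty <- numeric(n)
  tX <- matrix(0, n, ncol(X), dimnames = list(NULL, colnames(X)))
  blocks <- if (is.null(families)) list(seq_len(n)) else
    split(seq_len(n), families)
  for (idx in blocks) {
    if (length(idx) == 1L) {
      d[idx] <- A[idx, idx]
      ty[idx] <- y[idx]
      tX[idx, ] <- X[idx, , drop = FALSE]
    } else {
      e <- eigen(A[idx, idx, drop = FALSE], symmetric = TRUE)
      vals <- e$values
      if (min(vals) < -1e-8 * max(abs(vals))) {
        stop("relationship matrix is not positive semidefinite", call. = FALSE)
      }
      d[idx] <- pmax(vals, 0)
      ty[idx] <- crossprod(e$vectors, y[idx])
      tX[idx, ] <- crossprod(e$vectors, X[idx, , drop = FALSE])
    }
  }
  list(d = d, ty = ty, tX = tX)
}

# Profiled REML log-likelihood at variance ratio lambda, using rotated data.
# Returns the log-likelihood and the GLS quantities at that lambda.
reml_profile <- function(lambda, rot, n, p) {
  v <- lambda * rot$d + 1
  w <- 1 / v
  sw <- sqrt(w)
  Xw <- rot$tX * sw
  yw <- rot$ty * sw
  qr_x <- qr(Xw)
  beta <- qr.coef(qr_x, yw)
  rss <- sum((yw - Xw %*% beta)^2)
  sigma2_e <- rss / (n - p)
  logdet_xtx <- 2 * sum(log(abs(diag(qr.R(qr_x)))))
  ll <- -0.5 * ((n - p) * (log(2 * pi * sigma2_e) + 1) +
                  sum(log(v)) + logdet_xtx)
  list(ll = ll, beta = beta, sigma2_e = sigma2_e, qr = qr_x, w = w)
}

#' Fit a pedigree linear mixed model by REML
#'
#' Estimates `sigma2_g` and `sigma2_e` by restricted maximum likelihood via a
#' bounded scalar search over `log(lambda)`, `lambda = sigma2_g/sigma2_e`,
#' after a one-time eigendecomposition of the relationship matrix (blockwise
#' per family when a grouping is available). Fixed effects are the GLS
#' estimates at the optimum. The boundary `sigma2_g = 0` is checked
#' explicitly and permitted.
#'
#' @param y numeric response vector (complete cases only).
#' @param X design matrix including the intercept column.
#' @param A relationship matrix over the same samples, in row order of
#'   `y`/`X`. A family grouping in `attr(A, "families")` (or `families`)
#'   enables blockwise eigendecomposition.
#' @param families optional grouping vector overriding the attribute.
#' @param lambda_range search range for the variance ratio.
#' @param tol optimizer tolerance on log(lambda).
#' @return An object of class `lmm_fit`: coefficients, standard errors,
#'   `vcov`, `sigma2_g`, `sigma2_e`, `h2`, `lambda`, REML `loglik`, `n`, and
#'   the residual-df convention `df_residual = n - 2` used for Wald F
#'   reference distributions and effect-size conversion.
#' @export
reml_fit <- function(y, X, A, families = NULL,
                     lambda_range = c(1e-8, 1e6), tol = 1e-8) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n != nrow(X) || n != nrow(A)) {
    stop("y, X and A must agree in size", call. = FALSE)
  }
  if (n < p + 2L) stop("need n >= ncol(X) + 2", call. = FALSE)
  qr_full <- qr(X)
  if (qr_full$rank < p) {
    bad <- colnames(X)[qr_full$pivot[(qr_full$rank + 1L):p]]
    stop("rank error: collinear design column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(families)) families <- attr(A, "families")
  if (!is.null(families) && length(families) != n) families <- NULL
  rot <- rotate_by_relationship(y, X, A, families)

  obj <- function(log_lambda) reml_profile(exp(log_lambda), rot, n, p)$ll
  opt <- stats::optimize(obj, interval = log(lambda_range),
                         maximum = TRUE, tol = tol)
  cands <- rbind(c(0, reml_profile(0, rot, n, p)$ll),
                 c(exp(opt$maximum), opt$objective),
                 c(lambda_range[2], obj(log(lambda_range[2]))))
  best <- cands[which.max(cands[, 2]), ]
  lambda <- best[1]
  prof <- reml_profile(lambda, rot, n, p)

  R <- qr.R(prof$qr)
  pivot_order <- order(prof$qr$pivot)
  Rinv <- backsolve(R, diag(p))
  vcov <- tcrossprod(Rinv)[pivot_order, pivot_order, drop = FALSE] * prof$sigma2_e
  dimnames(vcov) <- list(colnames(X), colnames(X))
  beta <- prof$beta
  names(beta) <- colnames(X)

  structure(list(
    coefficients = beta,
    se = sqrt(diag(vcov)),
    vcov = vcov,
    sigma2_g = lambda * prof$sigma2_e,
    sigma2_e = prof$sigma2_e,
    h2 = lambda / (1 + lambda),
    lambda = lambda,
    loglik = prof$ll,
    n = n,
    p = p,
    df_residual = n - 2L
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("pedigree LMM (REML): n =", x$n, "\n")
  cat("  sigma2_g =", format(x$sigma2_g, digits = 4),
      " sigma2_e =", format(x$sigma2_e, digits = 4),
      " h2 =", format(x$h2, digits = 3), "\n")
  print(data.frame(estimate = x$coefficients, se = x$se), digits = 4)
  invisible(x)
}

#' Wald F test for a fixed-effect term
#'
#' For a single coefficient, F = (beta/se)^2 with reference distribution
#' F(1, n - 2); for a multi-column term (e.g. a categorical genotype) the
#' joint Wald statistic beta' V^{-1} beta / q is referred to F(q, n - 2).
#'
#' @param fit lmm_fit.
#' @param term coefficient name, or vector of names for a joint test.
#' @return List with `f_value`, `p_value`, `df1`.
#' @export
wald_f <- function(fit, term) {
  idx <- match(term, names(fit$coefficients))
  if (anyNA(idx)) {
    stop("unknown term(s): ", paste(term[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  q <- length(idx)
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  f <- if (q == 1L) {
    # b^2 / var(b); a noise-free fit has var(b) = 0 and F diverges
    if (b[1L] == 0) 0 else unname(b[1L]^2 / V[1L, 1L])
  } else {
    drop(crossprod(b, solve(V, b))) / q
  }
  list(f_value = f,
       p_value = stats::pf(f, q, fit$df_residual, lower.tail = FALSE),
       df1 = q)
}

#' Convert a single-df F statistic to Cohen's d
#'
#' d = 2 * sqrt(F / (n - 2)), the standardized effect size implied by a
#' single-degree-of-freedom F with residual degrees of freedom n - 2.
#'
#' @param f_value nonnegative F statistic.
#' @param n sample size (> 2).
#' @return Cohen's d (nonnegative).
#' @export
#' @examples
#' cohens_d_from_f(26.37, 817) # ~0.36
cohens_d_from_f <- function(f_value, n) {
  if (any(n <= 2)) stop("cohens_d_from_f domain error: need n > 2",
                        call. = FALSE)
  if (any(f_value < 0)) stop("f_value must be nonnegative", call. = FALSE)
  2 * sqrt(f_value / (n - 2))
}
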