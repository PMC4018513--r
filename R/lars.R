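#' Non-negative LARS regularization path
#'
#' Traces the solution path of the non-negative LASSO
#' \deqn{\hat\beta = \arg\min \|s - \Phi\beta\|^2 + \lambda \sum_i \beta_i,
#' \quad \beta_i \ge 0}
#' by least angle regression restricted to positive coefficients: a column
#' enters the active set when its correlation with the residual ties the
#' active set's common correlation, and is dropped (LASSO modification) when
#' its coefficient would cross zero. Each path point solves the problem
#' exactly for its implicit lambda (lambda = 2 x the active correlation).
#'
#' @param X Numeric matrix (observations x candidates). Columns are
#'   L2-normalized internally; returned coefficients are on the original
#'   column scale.
#' @param y Non-negative observation vector.
#' @param max_steps Safety cap on path length (default `3 * ncol(X) + 10`).
#' @return Object of class `nn_lars_path`: list with `beta` (steps x p matrix,
#'   original scale), `lambda`, `rss`, `df` (support size per step), `n_obs`.
#'   All-zero `y` yields a path with only the null solution.
#' @export
nn_lars <- function(X, y, max_steps = 3L * ncol(X) + 10L) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- nrow(X)
  norms <- sqrt(colSums(X^2))
  norms[norms == 0] <- 1
  Xs <- sweep(X, 2, norms, "/")
  eps <- 1e-10

  beta <- numeric(p)
  active <- integer(0)
  excluded <- rep(FALSE, p)
  r <- y
  cvec <- drop(crossprod(Xs, r))
  Cmax <- max(cvec, 0)

  betas <- list(beta)
  lambdas <- c(2 * Cmax)
  rsss <- c(sum(r^2))

  if (Cmax > eps * max(1, sqrt(sum(y^2)))) {
    step <- 0L
    repeat {
      step <- step + 1L
      if (step > max_steps) break
      if (length(active) == 0) {
        cand <- which(!excluded)
        if (length(cand) == 0) break
        j <- cand[which.max(cvec[cand])]
        if (cvec[j] <= eps) break
        active <- j
      }
      G <- crossprod(Xs[, active, drop = FALSE])
      w <- tryCatch(solve(G, rep(1, length(active))), error = function(e) NULL)
      if (is.null(w) || any(!is.finite(w))) {
        # newest column is collinear with the rest: exclude it
        excluded[active[length(active)]] <- TRUE
        active <- active[-length(active)]
        if (length(active) == 0) next
        G <- crossprod(Xs[, active, drop = FALSE])
        w <- solve(G, rep(1, length(active)))
      }
      a_const <- 1 / sqrt(sum(w))
      w <- w * a_const
      u <- drop(Xs[, active, drop = FALSE] %*% w)
      a_all <- drop(crossprod(Xs, u))

      gamma_max <- Cmax / a_const
      gamma <- gamma_max
      joiner <- NA_integer_
      inact <- setdiff(which(!excluded), active)
      for (j in inact) {
        denom <- a_const - a_all[j]
        if (denom > eps) {
          g <- (Cmax - cvec[j]) / denom
          if (g > eps && g < gamma - eps) {
            gamma <- g
            joiner <- j
          }
        }
      }
      dropper <- NA_integer_
      neg <- which(w < -eps)
      if (length(neg) > 0) {
        gd <- -beta[active[neg]] / w[neg]
        ok <- which(gd > eps)
        if (length(ok) > 0 && min(gd[ok]) < gamma - eps) {
          gamma <- min(gd[ok])
          dropper <- active[neg[ok[which.min(gd[ok])]]]
          joiner <- NA_integer_
        }
      }

      beta[active] <- beta[active] + gamma * w
      beta[beta < 0 & beta > -1e-12] <- 0
      r <- y - drop(Xs %*% beta)
      cvec <- drop(crossprod(Xs, r))
      Cmax <- max(Cmax - gamma * a_const, 0)

      if (!is.na(dropper)) {
        beta[dropper] <- 0
        active <- setdiff(active, dropper)
      } else if (!is.na(joiner)) {
        active <- c(active, joiner)
      }

      betas[[length(betas) + 1L]] <- beta
      lambdas <- c(lambdas, 2 * Cmax)
      rsss <- c(rsss, sum(r^2))

      if (gamma >= gamma_max - eps || Cmax <= eps) break
      if (is.na(joiner) && is.na(dropper) && length(active) == p) break
    }
  }

  bmat <- do.call(rbind, betas)
  # back to original column scale
  bmat <- sweep(bmat, 2, norms, "/")
  structure(list(beta = bmat, lambda = lambdas, rss = rsss,
                 df = rowSums(bmat > 0), n_obs = n),
            class = "nn_lars_path")
}

#' Select a path point by BIC
#'
#' Applies the classical Bayesian information criterion
#' `BIC = n ln(RSS/n) + k ln(n)` with n the number of observed peaks and k
#' the support size; ties break toward smaller k.
#'
#' @param path An `nn_lars_path`.
#' @param n Number of observations (defaults to the path's).
#' @return List with `beta`, `rss`, `bic`, `lambda`, `df`, `step` of the
#'   selected solution.
#' @export
select_bic <- function(path, n = path$n_obs) {
  rss <- pmax(path$rss, 1e-12)
  bic <- n * log(rss / n) + path$df * log(n)
  ord <- order(bic, path$df)
  i <- ord[1]
  list(beta = path$beta[i, ], rss = path$rss[i], bic = bic[i],
       lambda = path$lambda[i], df = path$df[i], step = i)
}

#' @export
print.nn_lars_path <- function(x, ...) {
  cat(sprintf("<nn_lars_path> %d path points, %d candidates, final df %d\n",
              nrow(x$beta), ncol(x$beta), x$df[length(x$df)]))
  invisible(x)
}
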