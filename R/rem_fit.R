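# Maximum likelihood for the ordinal relational event model.
#
# The probability that the realized onset is candidate a out of its risk set
# is exp(theta . s_a) / sum_a' exp(theta . s_a'), i.e. a stratified
# conditional (multinomial) logit. The log-likelihood is concave; it is
# maximised by Newton-Raphson with analytic gradient and Hessian and a
# step-halving safeguard. Waiting times contribute nothing in the ordinal
# form, so there is no intercept: per-stratum constants cancel.

#' Softmax event probabilities within one stratum
#'
#' @param theta Coefficient vector.
#' @param stats Numeric matrix, one row per candidate event, columns
#'   matching `theta`.
#' @return Probability per row (sums to 1). Computed with max-subtraction
#'   for overflow safety.
#' @export
event_probabilities <- function(theta, stats) {
  stats <- as.matrix(stats)
  if (any(!is.finite(stats))) stop("non-finite statistics")
  eta <- drop(stats %*% theta)
  e <- exp(eta - max(eta))
  e / sum(e)
}

# log-likelihood, gradient, negative Hessian at theta for design pieces;
# g must be a factor with levels in row order, y the 0/1 outcome
clogit_pieces <- function(theta, X, g, y) {
  eta <- drop(X %*% theta)
  M <- tapply(eta, g, max)                       # per-stratum max (level order)
  lseg <- log(rowsum(exp(eta - M[g]), g))[, 1] + M   # per-stratum logsumexp
  p <- as.vector(exp(eta - lseg[g]))
  ll <- sum(eta[y == 1L]) - sum(lseg)
  grad <- drop(t(X) %*% (y - p))
  S <- rowsum(X * p, g)                    # per-stratum E[x]
  Hn <- t(X * p) %*% X - t(S) %*% S        # negative Hessian (PSD)
  list(ll = ll, grad = grad, Hn = Hn, p = p)
}

clogit_ll <- function(theta, X, g, y) {
  eta <- drop(X %*% theta)
  M <- tapply(eta, g, max)
  sum(eta[y == 1L]) - sum(log(rowsum(exp(eta - M[g]), g))[, 1] + M)
}

#' Fit the relational event model by conditional logistic regression
#'
#' Maximises the stratified conditional-logit log-likelihood
#' \eqn{\ell(\theta)=\sum_s [\theta\cdot s_{actual} - \log\sum_r
#' \exp(\theta\cdot s_r)]} over the strata of a design built by
#' [build_strata()] (normally after [normalize_statistics()]). Columns with
#' no within-stratum variation anywhere are inestimable under the
#' conditional likelihood and are reported as `NA`. Complete or
#' quasi-complete separation (a coefficient diverging with a one-signed
#' score) is flagged as non-convergence, naming the effect.
#'
#' @param design A `rem_design` with at least one stratum, each containing
#'   exactly one row with `outcome == 1`.
#' @param effects Character vector of statistic columns to use.
#' @param tol_grad Convergence tolerance on the score max-norm.
#' @param tol_step Convergence tolerance on the parameter change max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `rem_fit`: `theta`, `se`, `z`, `p`, `stars`,
#'   `loglik`, `loglik_null`, `n_strata`, `converged`, `iterations`,
#'   `effects`, `dropped` (inestimable effects) and `diagnostics`.
#' @export
fit_conditional_logit <- function(design, effects = EFFECTS,
                                  tol_grad = 1e-8, tol_step = 1e-10,
                                  max_iter = 100L) {
  stopifnot(nrow(design) > 0, all(effects %in% names(design)))
  g <- factor(design$stratum_id, levels = unique(design$stratum_id))
  y <- as.integer(design$outcome)
  ok <- tapply(y, g, sum)
  if (any(ok != 1L))
    stop("every stratum must contain exactly one realized onset")
  X <- as.matrix(design[effects])
  storage.mode(X) <- "double"

  # effects constant within every stratum carry no conditional information
  ctr <- X - rowsum(X, g)[g, , drop = FALSE] / as.vector(table(g))[g]
  estimable <- apply(abs(ctr), 2, max) > 1e-12
  dropped <- effects[!estimable]
  Xe <- X[, estimable, drop = FALSE]
  k <- ncol(Xe)

  theta <- rep(0, k)
  converged <- FALSE; iter <- 0L; diag_msg <- NULL
  ll <- clogit_ll(theta, Xe, g, y)
  pieces <- NULL
  if (k > 0) {
    for (iter in seq_len(max_iter)) {
      pieces <- clogit_pieces(theta, Xe, g, y)
      if (max(abs(pieces$grad)) < tol_grad) { converged <- TRUE; break }
      step <- tryCatch(solve(pieces$Hn, pieces$grad), error = function(e) {
        bad <- colnames(Xe)[abs(diag(qr(pieces$Hn)$qr)) < 1e-10]
        stop("singular Hessian; collinear columns: ",
             paste(if (length(bad)) bad else colnames(Xe), collapse = ", "),
             call. = FALSE)
      })
      # step-halving keeps the concave likelihood increasing monotonically
      h <- 1
      repeat {
        ll_new <- clogit_ll(theta + h * step, Xe, g, y)
        if (ll_new >= pieces$ll - 1e-12 || h < 2^-30) break
        h <- h / 2
      }
      theta <- theta + h * step
      ll <- ll_new
      if (max(abs(h * step)) < tol_step) { converged <- TRUE; break }
      # separation: estimate runs away while the score stays one-signed
      if (any(abs(theta) > 15)) {
        gr <- clogit_pieces(theta, Xe, g, y)$grad
        run <- abs(theta) > 15 & abs(gr) > tol_grad & sign(gr) == sign(theta)
        if (any(run)) {
          diag_msg <- paste0("separation suspected for effect(s): ",
                             paste(colnames(Xe)[run], collapse = ", "))
          converged <- FALSE
          break
        }
      }
    }
    pieces <- clogit_pieces(theta, Xe, g, y)
    if (!converged && is.null(diag_msg) && max(abs(pieces$grad)) < 1e-6)
      converged <- TRUE
    ll <- pieces$ll
  } else {
    converged <- TRUE
  }

  nm <- setNames(rep(NA_real_, length(effects)), effects)
  th <- se <- nm
  th[estimable] <- theta
  if (k > 0 && converged) {
    vcv <- tryCatch(solve(pieces$Hn), error = function(e) NULL)
    if (!is.null(vcv)) se[estimable] <- sqrt(pmax(diag(vcv), 0))
  }
  z <- th / se
  p <- 2 * pnorm(-abs(z))
  sizes <- as.vector(table(g))
  structure(
    list(theta = th, se = se, z = z, p = p, stars = star_codes(p),
         loglik = ll, loglik_null = -sum(log(sizes)),
         n_strata = nlevels(g), converged = converged,
         iterations = iter, effects = effects, dropped = dropped,
         diagnostics = diag_msg),
    class = "rem_fit")
}

# significance flags: * P<0.05, ** P<0.01
star_codes <- function(p) {
  s <- ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  setNames(s, names(p))
}

#' Wald summary table of a fitted model
#'
#' @param fit A converged `rem_fit`.
#' @return Data frame with columns `effect`, `B`, `SE`, `z`, `p`, `stars`
#'   (`*` P < 0.05, `**` P < 0.01).
#' @export
wald_report <- function(fit) {
  stopifnot(inherits(fit, "rem_fit"))
  if (!fit$converged)
    warning("model did not converge: ", fit$diagnostics)
  data.frame(effect = fit$effects, B = unname(fit$theta), SE = unname(fit$se),
             z = unname(fit$z), p = unname(fit$p),
             stars = unname(fit$stars), stringsAsFactors = FALSE)
}

#' @export
print.rem_fit <- function(x, digits = 3, ...) {
  cat("Relational event model (conditional logit), ",
      x$n_strata, " strata\n", sep = "")
  tab <- wald_report(if (x$converged) x else structure(x, class = "rem_fit"))
  tab$B <- round(tab$B, digits); tab$SE <- round(tab$SE, digits)
  tab$z <- round(tab$z, digits); tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  cat("logLik ", format(x$loglik), " (null ", format(x$loglik_null), "), ",
      x$iterations, " iterations, ",
      if (x$converged) "converged" else paste0("NOT converged (", x$diagnostics, ")"),
      "\n", sep = "")
  if (length(x$dropped))
    cat("inestimable (no within-stratum variation): ",
        paste(x$dropped, collapse = ", "), "\n", sep = "")
  invisible(x)
}
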