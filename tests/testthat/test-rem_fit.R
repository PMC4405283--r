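# random design fixture: n strata of the given size, k effects
random_design <- function(n, size = 3, k = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    X <- matrix(rnorm(size * k), size, k)
    data.frame(stratum_id = sprintf("s%03d", i), outcome = sample(c(1, rep(0, size - 1))),
               setNames(as.data.frame(X), EFFECTS[seq_len(k)]))
  })
  do.call(rbind, rows)
}

test_that("softmax probabilities are uniform at theta = 0 and sum to one", {
  S <- matrix(rnorm(15), 3, 5)
  expect_equal(event_probabilities(rep(0, 5), S), rep(1 / 3, 3))
  set.seed(5)
  for (i in 1:20) {
    th <- rnorm(5)
    p <- event_probabilities(th, matrix(rnorm(15, sd = 30), 3, 5))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  expect_error(event_probabilities(rep(0, 5), matrix(c(Inf, rnorm(14)), 3, 5)),
               "non-finite")
})

test_that("softmax is invariant to per-stratum constant shifts", {
  th <- rnorm(5)
  S <- matrix(rnorm(15), 3, 5)
  shift <- matrix(rep(rnorm(5), each = 3), 3, 5)
  expect_equal(event_probabilities(th, S), event_probabilities(th, S + shift))
})

test_that("an unfamiliarity-only model weights rows proportional to exp", {
  S <- cbind(unfam = c(0, 1, 1), matrix(0, 3, 4))
  p <- event_probabilities(c(1, 0, 0, 0, 0), S)
  expect_equal(p, c(1, exp(1), exp(1)) / (1 + 2 * exp(1)))
})

test_that("null log-likelihood has its closed form", {
  d3 <- random_design(7, size = 3, seed = 1)
  d2 <- random_design(5, size = 2, seed = 2)
  f3 <- fit_conditional_logit(d3)
  f2 <- fit_conditional_logit(d2)
  expect_equal(f3$loglik_null, -7 * log(3))
  expect_equal(f2$loglik_null, -5 * log(2))
  expect_gte(f3$loglik, f3$loglik_null - 1e-9)
  expect_gte(f2$loglik, f2$loglik_null - 1e-9)
})

test_that("MLE on tiny one-effect data matches a dense grid search", {
  set.seed(33)
  for (rep in 1:5) {
    des <- random_design(3, size = 3, k = 1)
    fit <- fit_conditional_logit(des, effects = "unfam")
    grid <- seq(-10, 10, by = 0.001)
    ll <- vapply(grid, function(th) brute_loglik(c(unfam = th), des), 0)
    expect_equal(unname(fit$theta["unfam"]), grid[which.max(ll)],
                 tolerance = 2e-3)
    expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
  }
})

test_that("fitted likelihood equals brute-force stratum enumeration", {
  set.seed(44)
  for (rep in 1:20) {
    des <- random_design(sample(2:6, 1), size = sample(2:3, 1))
    th <- setNames(rnorm(5, sd = 0.7), EFFECTS)
    expect_equal(remtriad:::clogit_ll(th, as.matrix(des[EFFECTS]),
                                      factor(des$stratum_id,
                                             levels = unique(des$stratum_id)),
                                      des$outcome),
                 brute_loglik(th, des), tolerance = 1e-10)
  }
})

test_that("the likelihood is invariant to per-stratum constant shifts", {
  des <- random_design(6, seed = 9)
  shifted <- des
  for (sid in unique(des$stratum_id)) {
    i <- des$stratum_id == sid
    shifted[i, EFFECTS] <- des[i, EFFECTS] +
      matrix(rep(rnorm(5), each = sum(i)), sum(i), 5)
  }
  f1 <- fit_conditional_logit(des)
  f2 <- fit_conditional_logit(shifted)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("Newton iterations converge with a near-zero score", {
  des <- random_design(40, seed = 12)
  fit <- fit_conditional_logit(des)
  expect_true(fit$converged)
  g <- remtriad:::clogit_pieces(unname(fit$theta), as.matrix(des[EFFECTS]),
                                factor(des$stratum_id,
                                       levels = unique(des$stratum_id)),
                                des$outcome)$grad
  expect_lt(max(abs(g)), 1e-6)
  expect_true(all(fit$se > 0))
})

test_that("estimates and errors agree with an independent stratified fitter", {
  skip_if_not_installed("survival")
  des <- random_design(60, seed = 21)
  fit <- fit_conditional_logit(des)
  cl <- survival::coxph(
    survival::Surv(rep(1, nrow(des)), outcome) ~ unfam + pair_hour +
      pair_day + group_hour + group_day + survival::strata(stratum_id),
    data = des, method = "exact")
  expect_equal(unname(fit$theta), unname(coef(cl)), tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cl)))), tolerance = 1e-5)
  expect_equal(fit$loglik, cl$loglik[2], tolerance = 1e-6)
})

test_that("inestimable effects are reported NA, not silently zero", {
  des <- random_design(10, seed = 7)
  des$unfam <- stats::ave(des$unfam, des$stratum_id)  # constant within strata
  fit <- fit_conditional_logit(des)
  expect_true(is.na(fit$theta["unfam"]))
  expect_equal(fit$dropped, "unfam")
  expect_true(all(!is.na(fit$theta[c("pair_hour", "pair_day")])))
})

test_that("complete separation is flagged, not silently reported", {
  # outcome always the row with the largest unfam: likelihood maximised at
  # +infinity
  rows <- lapply(1:12, function(i) {
    x <- c(1, 0, 0)
    data.frame(stratum_id = sprintf("s%d", i), outcome = c(1, 0, 0),
               unfam = x + i * 1e-3, pair_hour = rnorm(3), pair_day = rnorm(3),
               group_hour = rnorm(3), group_day = rnorm(3))
  })
  des <- do.call(rbind, rows)
  fit <- suppressWarnings(fit_conditional_logit(des))
  expect_false(fit$converged)
  expect_match(fit$diagnostics, "separation")
  expect_match(fit$diagnostics, "unfam")
})

test_that("Wald stars follow the reporting convention", {
  p_of <- function(b, se) 2 * pnorm(-abs(b / se))
  expect_equal(unname(remtriad:::star_codes(p_of(-0.49, 0.09))), "**")
  expect_equal(unname(remtriad:::star_codes(p_of(-0.09, 0.05))), "")
  expect_equal(unname(remtriad:::star_codes(p_of(0.31, 0.13))), "*")
  expect_equal(unname(remtriad:::star_codes(1)), "")

  des <- random_design(50, seed = 3)
  fit <- fit_conditional_logit(des)
  tab <- wald_report(fit)
  expect_equal(names(tab), c("effect", "B", "SE", "z", "p", "stars"))
  expect_equal(tab$z, tab$B / tab$SE)
  expect_equal(tab$stars, unname(remtriad:::star_codes(tab$p)))
})
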