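# Surrogate fitting, the interventional value function, exact Shapley
# enumeration and its axioms, and planted-driver recovery.

lin_data <- function(n = 200, p = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  list(x = x, w = seq_len(p))
}

test_that("surrogate learns linear targets and handles degenerate ones", {
  d <- lin_data(400, 5)
  y <- d$x %*% d$w + rnorm(400, 0, 0.01)
  sur <- fit_surrogate(d$x, as.vector(y), seed = 2)
  expect_gte(sur$r2_holdout, 0.95)
  # refit with same seed reproduces predictions exactly
  sur2 <- fit_surrogate(d$x, as.vector(y), seed = 2)
  newx <- d$x[1:10, ]
  expect_identical(sur$predict_fn(newx), sur2$predict_fn(newx))
  # permuting named columns does not change predictions
  perm <- d$x[1:10, c(3, 1, 5, 2, 4)]
  expect_equal(esdrought:::predict_surrogate(sur, perm),
               sur$predict_fn(newx), tolerance = 1e-12)
  # constant target degenerates to the constant with a warning
  expect_warning(cst <- fit_surrogate(d$x, rep(3.3, 400)), "constant")
  expect_true(all(cst$predict_fn(d$x[1:7, ]) == 3.3))
  expect_error(fit_surrogate(d$x[1:10, ], rnorm(10)), class = "esd_data_error")
})

test_that("value function obeys its closed forms", {
  d <- lin_data(120, 3, seed = 3)
  w <- c(2, -1, 0.5)
  y <- as.vector(d$x %*% w)
  sur <- fit_surrogate(d$x, y, seed = 1)
  bg <- d$x[1:40, ]
  inst <- d$x[7, ]
  # S = N: the prediction at the instance; S = empty: background mean
  expect_equal(value_function(sur, inst, colnames(d$x), bg),
               sur$predict_fn(rbind(inst)), tolerance = 1e-8)
  expect_equal(value_function(sur, inst, integer(0), bg),
               mean(sur$predict_fn(bg)), tolerance = 1e-8)
  # linear predictor: f_x(S) = sum_{j in S} w_j x_j + sum_{j notin S} w_j xbar_j
  xbar <- colMeans(bg)
  for (S in list(1L, c(1L, 3L), 2:3)) {
    manual <- sum(w[S] * inst[S]) + sum(w[-S] * xbar[-S])
    expect_equal(value_function(sur, inst, S, bg), manual, tolerance = 1e-8)
  }
  expect_error(value_function(sur, inst, 1L, bg[0, ]),
               class = "esd_config_error")
  expect_error(value_function(sur, inst, "nope", bg),
               class = "esd_config_error")
})

test_that("exact Shapley matches the linear closed form and its axioms", {
  d <- lin_data(150, 4, seed = 4)
  w <- c(2, 3, 0, -1.5)      # f3 is a dummy feature
  y <- as.vector(d$x %*% w)
  sur <- fit_surrogate(d$x, y, seed = 1)
  bg <- d$x[1:50, ]
  xbar <- colMeans(bg)
  for (row in c(1, 17, 60)) {
    inst <- d$x[row, ]
    att <- exact_shapley(sur, inst, bg)
    # closed form phi_i = w_i (x_i - xbar_i), matched to 1e-10
    expect_equal(unname(att$phi), unname(w * (inst - xbar)), tolerance = 1e-10)
    # efficiency axiom
    expect_lt(abs(sum(att$phi) - (att$fx - att$baseline)), 1e-8)
    # dummy axiom
    expect_lt(abs(att$phi["f3"]), 1e-10)
  }
})

test_that("enumeration agrees with the permutation-averaged oracle (|N| <= 5)", {
  set.seed(5)
  n <- 80
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  # nonlinear target so the agreement is not a linear-model triviality
  y <- x[, 1] * x[, 2] + sin(x[, 3]) + 0.5 * x[, 4]^2
  sur <- fit_surrogate(x, y, method = "gam", seed = 6)
  bg <- x[1:12, ]
  for (row in c(2, 33)) {
    inst <- x[row, ]
    att <- exact_shapley(sur, inst, bg)
    oracle <- perm_shapley(sur, inst, bg)
    expect_equal(att$phi, oracle, tolerance = 1e-10)
    expect_lt(abs(sum(att$phi) - (att$fx - att$baseline)), 1e-8)
  }
})

test_that("symmetric treatment of duplicated features splits their importance", {
  set.seed(8)
  n <- 60
  x1 <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  xd <- cbind(x1, a2 = x1[, 1])   # exact copy of the driving feature
  # a predictor symmetric in the two copies (the attribution contract is
  # model-agnostic, so a hand-built prediction function is admissible)
  sym <- structure(list(
    predict_fn = function(X) 1.5 * X[, "a"] + 1.5 * X[, "a2"] + 2 * X[, "b"],
    feature_names = c("a", "b", "a2")), class = "surrogate_predictor")
  single <- structure(list(
    predict_fn = function(X) 3 * X[, "a"] + 2 * X[, "b"],
    feature_names = c("a", "b")), class = "surrogate_predictor")
  att <- exact_shapley(sym, xd[5, ], xd[1:30, ])
  att1 <- exact_shapley(single, x1[5, ], x1[1:30, ])
  expect_equal(att$phi[["a"]], att$phi[["a2"]], tolerance = 1e-10)
  # the copies jointly carry what the single column carried alone
  expect_equal(att$phi[["a"]] + att$phi[["a2"]], att1$phi[["a"]],
               tolerance = 1e-10)
  expect_equal(att$phi[["b"]], att1$phi[["b"]], tolerance = 1e-10)
})

test_that("a planted driver dominates the importance ranking with aligned signs", {
  set.seed(9)
  n <- 300
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, c("PRE", "TEM", "EL", "SOC", "POP")))
  y <- 2 * x[, "PRE"] + rnorm(n, 0, 0.3)
  sm <- shap_summary(x, y, n_instances = 60, n_background = 40, seed = 10)
  expect_equal(sm$importance$feature[1], "PRE")
  pre_rows <- sm$values[sm$values$feature == "PRE", ]
  expect_gt(cor(pre_rows$value, pre_rows$phi), 0.9)
  # pure-noise target: every spurious importance stays near zero on the
  # scale of the planted driver's importance (which is ~1.6 here)
  signal_top <- sm$importance$mean_abs_phi[1]
  flat_hits <- vapply(1:10, function(s) {
    set.seed(300 + s)
    yn <- rnorm(n)
    smn <- shap_summary(x, yn, n_instances = 25, n_background = 25,
                        seed = 400 + s)
    max(smn$importance$mean_abs_phi) < 0.15 * signal_top
  }, TRUE)
  expect_gte(mean(flat_hits), 0.9)
})

test_that("growing the background set converges phi toward the full-background value", {
  d <- lin_data(120, 3, seed = 12)
  y <- as.vector(d$x %*% c(1, -2, 0.5))
  sur <- fit_surrogate(d$x, y, seed = 1)
  inst <- d$x[99, ]
  full <- exact_shapley(sur, inst, d$x[1:90, ])$phi
  dev <- vapply(c(5, 30, 90), function(m) {
    max(abs(exact_shapley(sur, inst, d$x[1:m, ])$phi - full))
  }, 0)
  expect_lt(dev[3], 1e-12)
  expect_lt(dev[2], dev[1])
})

test_that("enumeration bound and empty background are explicit errors", {
  d <- lin_data(80, 2, seed = 11)
  y <- as.vector(d$x %*% c(1, 2))
  sur <- fit_surrogate(d$x, y, seed = 1)
  expect_error(exact_shapley(sur, d$x[1, ], d$x[0, ]),
               class = "esd_config_error")
  sur$feature_names <- paste0("f", 1:16)
  expect_error(exact_shapley(sur, d$x[1, ], d$x[1:5, ]), "15",
               class = "esd_config_error")
})
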