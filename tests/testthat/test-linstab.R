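# characteristic-polynomial coefficients by Faddeev-LeVerrier; combined with
# polyroot() this gives an eigenvalue oracle independent of eigen()
charpoly_roots <- function(M) {
  n <- nrow(M)
  a <- numeric(n)
  Nk <- diag(n)
  for (k in 1:n) {
    Mk <- M %*% Nk
    a[k] <- -sum(diag(Mk)) / k
    Nk <- Mk + a[k] * diag(n)
  }
  polyroot(c(rev(a), 1))
}

random_min_params <- function() {
  min_params(10^rnorm(1, 0, 1.5), 10^rnorm(1, -0.5, 1),
             10^rnorm(1, -0.5, 1), 0.33, 10^rnorm(1, 0, 1.5))
}

test_that("Jacobian entries match the linearized reaction-diffusion model", {
  p <- reference_params()
  D <- reference_diffusion()
  ss <- uniform_steady_state(p, reference_totals())
  q <- pi / 3
  A <- min_jacobian(ss$u, p, D, q)
  expect_equal(A[1, 1], -p$k_ADP_ATP - D$D_D * q^2)
  expect_equal(A[5, 5], -p$k_de - D$D_de * q^2)
  expect_equal(A[2, 2], -p$k_D - p$k_dD * ss$u[["c_d"]] - D$D_D * q^2)
  expect_equal(A[1, 5], p$k_de)
  expect_equal(A[4, 2], p$k_D + p$k_dD * ss$u[["c_d"]])
  expect_equal(A[2, 1], p$k_ADP_ATP)
  expect_equal(A[3, 4], -p$k_dE * ss$u[["c_E"]])
  expect_equal(A[5, 4], p$k_dE * ss$u[["c_E"]])
})

test_that("mass conservation gives zero eigenvalues at q = 0", {
  set.seed(31)
  for (rep in 1:10) {
    p <- random_min_params()
    ss <- uniform_steady_state(p, reference_totals())
    A <- min_jacobian(ss$u, p, reference_diffusion(), q = 0)
    # left null vectors along the MinD and MinE mass directions
    expect_equal(as.numeric(c(1, 1, 0, 1, 1) %*% A), rep(0, 5),
                 tolerance = 1e-10)
    expect_equal(as.numeric(c(0, 0, 1, 0, 1) %*% A), rep(0, 5),
                 tolerance = 1e-10)
  }
})

test_that("analytic Jacobian matches the finite-difference oracle", {
  set.seed(32)
  for (rep in 1:100) {
    p <- random_min_params()
    u <- c(c_DD = runif(1, 1, 500), c_DT = runif(1, 1, 500),
           c_E = runif(1, 1, 500), c_d = runif(1, 1, 500),
           c_de = runif(1, 1, 500))
    A <- min_jacobian(u, p, reference_diffusion(), q = 0)
    J <- minwave:::numeric_jacobian(u, p)
    expect_lt(max(abs(A - J) / pmax(abs(A), 1)), 1e-6)
  }
})

test_that("eigenvalues of the real matrix come in conjugate pairs", {
  set.seed(33)
  for (rep in 1:20) {
    p <- random_min_params()
    ss <- uniform_steady_state(p, reference_totals())
    ev <- eigen(min_jacobian(ss$u, p, reference_diffusion(), pi / 15),
                only.values = TRUE)$values
    cplx <- ev[abs(Im(ev)) > 1e-10]
    if (length(cplx))
      expect_equal(sort(Re(Conj(cplx))), sort(Re(cplx)), tolerance = 1e-8)
    expect_equal(sum(Im(ev)), 0, tolerance = 1e-8)
  }
})

test_that("verdict agrees with a characteristic-polynomial root oracle", {
  set.seed(34)
  n_checked <- 0
  for (rep in 1:50) {
    p <- random_min_params()
    v <- tryCatch(classify_instability(p, length = 3.0),
                  error = function(e) NULL)
    if (is.null(v) || v$multiple_roots) next
    M <- min_jacobian(v$u_star, p, reference_diffusion(), v$q)
    roots <- charpoly_roots(M)
    lead <- roots[order(Re(roots), decreasing = TRUE)][1]
    if (abs(Re(lead)) < 1e-8) next   # numerically marginal either way
    expect_identical(v$oscillatory, Re(lead) > 0)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 30)
})

test_that("strong diffusion damping suppresses the instability", {
  # shrinking the cell 100-fold raises q to the diffusion-dominated regime
  v <- classify_instability(reference_params(), length = 3.0 / 100)
  expect_false(v$oscillatory)
  expect_lt(Re(v$sigma), 0)
})

test_that("linearized dynamics grow and oscillate when the verdict says so", {
  # time-domain oracle: integrate delta_u' = A_q delta_u with deSolve and
  # check growth of the norm and sign changes of a detrended component
  skip_if_not_installed("deSolve")
  p <- reference_params()
  # a long domain keeps q small enough that the growing pole-to-pole mode
  # also rotates in time (strict Hopf + Turing verdict)
  v <- classify_instability(p, length = 30, criterion = "hopf_turing")
  expect_true(v$oscillatory)
  expect_gt(abs(Im(v$sigma)), 1e-4)
  M <- min_jacobian(v$u_star, p, reference_diffusion(), v$q)
  set.seed(35)
  u0 <- rnorm(5)
  tt <- seq(0, 400, by = 0.5)
  sol <- deSolve::ode(u0, tt, function(t, y, parms) list(as.numeric(M %*% y)),
                      parms = NULL)
  nrm <- sqrt(rowSums(sol[, -1]^2))
  # the norm grows at the predicted exponential rate
  rate <- coef(lm(log(nrm[tt > 100]) ~ tt[tt > 100]))[2]
  expect_equal(unname(rate), Re(v$sigma), tolerance = 0.02)
  # and a normalized component oscillates (sign changes) on the way up
  y <- sol[, 2] / nrm
  expect_gt(sum(diff(sign(y[y != 0])) != 0), 2)
  # diffusion-dominated case decays monotonically in norm
  v2 <- classify_instability(p, length = 0.03)
  expect_false(v2$oscillatory)
})

test_that("batch classification appends verdict columns", {
  set.seed(36)
  df <- sample_parameter_sets(5)
  out <- classify_instability_batch(df)
  expect_true(all(c("re_sigma", "im_sigma", "oscillatory") %in% names(out)))
  expect_true(all(out$oscillatory %in% c(0L, 1L)))
  expect_equal(nrow(out), 5)
})
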