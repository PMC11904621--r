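test_that("Windkessel outlet reduces to Ohm's law and equilibrium limits", {
  # tiny compliance: pure series resistance, p = q (Rp + Rd); the L-stable
  # backward-Euler update is the right integrator for this stiff limit
  wk <- windkessel_params(1, 1, 1e-10)
  p <- windkessel_outlet(rep(2, 2000), wk, dt = 1e-3,
                         method = "backward_euler")
  expect_equal(tail(p, 1), 4, tolerance = 1e-8)
  # zero flow stays at the reference pressure
  wk2 <- windkessel_params(1, 1, 1)
  expect_equal(windkessel_outlet(rep(0, 50), wk2, dt = 1e-3, p_ref = 7),
               rep(7, 50))
  wk3 <- windkessel_params(1, 1, 1)
  wk3$rp <- 0
  expect_error(windkessel_outlet(1, wk3, dt = 1e-3), "nonpositive")
})

test_that("Windkessel capacitor matches the closed-form step response", {
  # q = 1 from t = 0, Rp negligible, Rd = C = 1: p_d(t) = 1 - exp(-t)
  wk <- windkessel_params(1e-12, 1, 1)
  dt <- 1e-4
  tt <- seq(dt, 1, by = dt)
  p <- windkessel_outlet(rep(1, length(tt)), wk, dt)
  expect_lt(abs(p[length(tt)] - (1 - exp(-1))), 1e-6)
  expect_lt(max(abs(p - (1 - exp(-tt)))), 1e-6)
})

test_that("structured-tree enumeration matches a brute-force recursion", {
  st0 <- structured_tree_params(alpha = 0.5, beta = 0.5, rmin = 0.0049)
  # root 0.01: daughters at 0.005 >= rmin, grand-daughters 0.0025 < rmin
  bt <- build_structured_tree(0.01, st0)
  expect_equal(bt$n_vessels, 3)
  expect_equal(bt$n_terminal, 2)
  # root below rmin: a single leaf
  bt1 <- build_structured_tree(0.004, st0)
  expect_equal(bt1$n_vessels, 1)
  expect_true(all(bt1$segments$terminal))
  # asymmetric tree vs explicit recursive enumeration
  st <- structured_tree_params(alpha = 0.9, beta = 0.6, lrr = 10,
                               rmin = 0.01)
  brute <- function(r) {
    n <- 1
    if (0.9 * r >= 0.01) n <- n + brute(0.9 * r)
    if (0.6 * r >= 0.01) n <- n + brute(0.6 * r)
    n
  }
  expect_equal(build_structured_tree(0.02, st)$n_vessels, brute(0.02))
  expect_error(structured_tree_params(alpha = 1.01), "terminate")
})

test_that("impedance at zero frequency equals the Poiseuille recursion", {
  st <- structured_tree_params(alpha = 0.8, beta = 0.6, lrr = 10,
                               rmin = 0.005)
  fl <- fluid_properties()
  mu_dyn <- fl$mu        # literal momentum-equation convention
  pois <- function(r) {
    R <- 8 * mu_dyn * (st$lrr * r) / (pi * r^4) / 1333.223874
    da <- st$alpha * r >= st$rmin
    db <- st$beta * r >= st$rmin
    if (da && db) R + 1 / (1 / pois(st$alpha * r) + 1 / pois(st$beta * r))
    else if (da) R + pois(st$alpha * r)
    else if (db) R + pois(st$beta * r)
    else R
  }
  Z <- structured_tree_impedance(0.02, st, fl, cycle_T = 0.11,
                                 n_harmonics = 16)
  expect_lt(abs(Z$dc_resistance / pois(0.02) - 1), 1e-8)
  expect_equal(Im(Z$Z[1]), 0)
  # leaf-only tree: single-segment Poiseuille value
  Z1 <- structured_tree_impedance(0.004, st, fl, 0.11, 8)
  expect_lt(abs(Z1$dc_resistance /
                  (8 * mu_dyn * (10 * 0.004) / (pi * 0.004^4) / 1333.223874)
                - 1), 1e-12)
})

test_that("memoized impedance equals an independent per-branch recursion", {
  # independent implementation: same Womersley segment formula, no sharing,
  # plain branch-by-branch recursion on a <= 3 generation tree
  st <- structured_tree_params(alpha = 0.7, beta = 0.55, lrr = 12,
                               rmin = 0.004)
  fl <- fluid_properties()
  nu <- fl$mu / fl$rho
  mu_dyn <- fl$mu
  cycle_T <- 0.11
  nh <- 8
  omega <- 2 * pi * (1:nh) / cycle_T
  seg_z <- function(r, ZL) {
    L <- st$lrr * r
    A0 <- pi * r^2
    ehr <- (st$k1SA * exp(-st$k2SA * r) + st$k3SA) * 1333.223874
    CA <- 1.5 * A0 / ehr
    Z <- complex(nh + 1)
    Z[1] <- 8 * mu_dyn * L / (pi * r^4) + ZL[1]
    for (k in 1:nh) {
      w0 <- r * sqrt(omega[k] / nu)
      zeta <- complex(modulus = w0, argument = 3 * pi / 4)
      B <- pwemu:::besselJ01_complex(zeta)
      FJ <- 2 * B$J1 / (zeta * B$J0)
      cc <- sqrt(A0 * (1 - FJ) / (fl$rho * CA))
      g <- CA * cc
      s <- sin(omega[k] * L / cc); cs <- cos(omega[k] * L / cc)
      Z[k + 1] <- (1i * s / g + ZL[k + 1] * cs) /
                  (cs + 1i * g * ZL[k + 1] * s)
    }
    Z
  }
  plain <- function(r) {
    da <- st$alpha * r >= st$rmin
    db <- st$beta * r >= st$rmin
    ZL <- if (da && db) {
      Z1 <- plain(st$alpha * r); Z2 <- plain(st$beta * r)
      1 / (1 / Z1 + 1 / Z2)
    } else if (da) plain(st$alpha * r)
    else if (db) plain(st$beta * r)
    else rep(0 + 0i, nh + 1)
    seg_z(r, ZL)
  }
  Zref <- plain(0.008) / 1333.223874
  Z <- structured_tree_impedance(0.008, st, fl, cycle_T, nh)
  expect_equal(Z$Z, Zref, tolerance = 1e-12)
})

test_that("complex Bessel series agrees with base besselJ on the real axis", {
  for (x in c(0.1, 1, 4, 9)) {
    B <- pwemu:::besselJ01_complex(x + 0i)
    expect_equal(Re(B$J0), besselJ(x, 0), tolerance = 1e-12)
    expect_equal(Re(B$J1), besselJ(x, 1), tolerance = 1e-12)
  }
})

test_that("impedance outlet honours resistive, DC and single-harmonic limits", {
  st <- structured_tree_params()
  Z <- structured_tree_impedance(0.03, st, fluid_properties(), 0.11, 16)
  M <- 32
  # constant flow sees only the DC resistance
  p <- impedance_outlet(rep(0.2, M), Z, p_ref = 3)
  expect_equal(p, rep(0.2 * Z$dc_resistance + 3, M), tolerance = 1e-10)
  # purely resistive spectrum: p = R q pointwise
  Zres <- Z
  Zres$Z <- rep(5 + 0i, 17)
  Zres$dc_resistance <- 5
  q <- sin(2 * pi * (0:(M - 1)) / M) + 1
  expect_equal(impedance_outlet(q, Zres), 5 * q, tolerance = 1e-10)
  # single harmonic k: amplitude |Z_k|, phase arg Z_k
  k <- 3
  ph <- 2 * pi * k * (0:(M - 1)) / M
  qk <- cos(ph)
  pk <- impedance_outlet(qk, Z)
  expect_equal(pk, Mod(Z$Z[k + 1]) * cos(ph + Arg(Z$Z[k + 1])),
               tolerance = 1e-9)
  expect_error(impedance_outlet(0.1, Z), "shorter")
})

test_that("time-domain kernel reproduces the harmonic relation and is real", {
  Z <- structured_tree_impedance(0.035, structured_tree_params(),
                                 fluid_properties(), 0.11, 16)
  M <- 32
  z <- impedance_kernel(Z, M)
  expect_true(is.numeric(z))
  # periodic convolution with the kernel = frequency-domain product
  q <- 0.3 + 0.1 * sin(2 * pi * (0:(M - 1)) / M) +
       0.05 * cos(2 * pi * 5 * (0:(M - 1)) / M)
  conv <- (Z$cycle_T / M) * vapply(0:(M - 1), function(n)
    sum(z * q[((n - (0:(M - 1))) %% M) + 1]), numeric(1))
  direct <- impedance_outlet(q, Z)
  expect_equal(conv, direct, tolerance = 1e-9)
})
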