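test_that("tube law holds at the reference state and inverts exactly", {
  expect_equal(wall_pressure(0.01, 0.01, 3e4, p_ref = 2), 2)
  expect_equal(wall_pressure(4 * 0.01, 0.01, 3e4), 3e4)  # sqrt(4) - 1 = 1
  A <- seq(0.005, 0.02, length.out = 11)
  for (law in c("sqrt", "linear")) {
    p <- wall_pressure(A, 0.01, 2.5e4, p_ref = 1, law = law)
    expect_true(all(diff(p) > 0))
    expect_equal(wall_area(p, 0.01, 2.5e4, p_ref = 1, law = law), A,
                 tolerance = 1e-12)
  }
  expect_error(wall_pressure(-1, 0.01, 3e4), "area")
})

test_that("uniform equilibrium is a fixed point of the interior update", {
  A0 <- pi * 0.05^2
  A <- rep(A0, 17); q <- rep(0, 17)
  dx <- 0.5 / 16
  dt <- 0.25 * dx / sqrt(stiffness(0.05, wall_model()) * 1333.223874 / 2.11)
  for (i in 1:10000) {
    st <- step_vessel(A, q, dt, dx, 0.05)
    A <- st$A; q <- st$q
  }
  expect_equal(A, rep(A0, 17), tolerance = 1e-14)
  expect_equal(q, rep(0, 17), tolerance = 1e-14)
})

test_that("interior mass change is exactly the half-step boundary fluxes", {
  A0 <- pi * 0.05^2
  set.seed(3)
  A <- A0 * (1 + 0.02 * sin(seq(0, pi, length.out = 25)))
  q <- 0.1 * cos(seq(0, 2 * pi, length.out = 25))
  dx <- 1 / 24
  dt <- 0.2 * dx / sqrt(stiffness(0.05, wall_model()) * 1333.223874 / 2)
  st <- step_vessel(A, q, dt, dx, 0.05)
  interior <- 2:24
  dmass <- sum(st$A[interior] - A[interior]) * dx
  flux <- st$mass_flux_half
  expect_equal(dmass, -dt * (flux[24] - flux[1]), tolerance = 1e-10)
  # CFL violation is reported with the wave speed
  expect_error(step_vessel(A, q, dt * 100, dx, 0.05), "CFL")
})

test_that("a small-amplitude pulse travels at the analytic wave speed", {
  topo <- load_topology(textConnection("id,parent,length_cm,r0_cm\n1,,4,0.05"))
  cfg <- simulation_config(cycle_T = 9e-4, m = 8, cells_per_vessel = 400,
                           n_cycles_max = 1,
                           inflow = inflow_spec(Q_max = 0.01,
                                                systole_fraction = 1 / 9))
  wf <- simulate_waveform(NULL, topo, cfg,
                          probes = rbind(c(0L, 100L), c(0L, 300L)))
  peak_t <- function(tv, pv) {
    i <- which.max(pv)
    tv[i] + 0.5 * (pv[i - 1] - pv[i + 1]) /
      (pv[i - 1] - 2 * pv[i] + pv[i + 1]) * (tv[2] - tv[1])
  }
  speed <- 2 / (peak_t(wf$probe_t, wf$probe_p[[2]]) -
                peak_t(wf$probe_t, wf$probe_p[[1]]))
  c0 <- sqrt(stiffness(0.05, wall_model()) * 1333.223874 / (2 * 1.055))
  expect_lt(abs(speed / c0 - 1), 0.02)
})

test_that("junction coupling respects symmetry and conservation", {
  r0 <- c(0.05, 0.035, 0.035)
  cc <- sqrt(stiffness(r0, wall_model()) * 1333.223874 / (2 * 1.055))
  j <- couple_junction(10 + 4 * cc[1], -4 * cc[2], -4 * cc[3], r0)
  expect_equal(j$u_d1, j$u_d2, tolerance = 1e-12)
  expect_equal(j$A_p * j$u_p, j$A_d1 * j$u_d1 + j$A_d2 * j$u_d2,
               tolerance = 1e-10)
  expect_lt(j$residual, 1e-10)
  # equilibrium invariants: zero flow is already the solution
  j0 <- couple_junction(4 * cc[1], -4 * cc[2], -4 * cc[3], r0)
  expect_equal(j0$u_p, 0, tolerance = 1e-10)
  expect_equal(j0$A_p, pi * 0.05^2, tolerance = 1e-12)
})

test_that("steady flow matches the lumped series/parallel DC prediction", {
  # constant inflow; viscous drop per vessel uses the profile-consistent
  # resistance 2*pi*mu*(gamma+2)*L/A^2 (gamma = 2 recovers Poiseuille)
  topo <- fixture_network("bifurcation3")
  cfg <- simulation_config(inflow = inflow_spec(Q_max = 0.1,
                                                shape = "constant"))
  wf <- simulate_waveform(NULL, topo, cfg)
  fl <- fluid_properties()
  rvisc <- function(L, r) {
    A <- pi * r^2
    2 * pi * fl$mu * (fl$gamma + 2) * L / A^2 / 1333.223874
  }
  lumped <- 0.1 * (130 + rvisc(0.5, 0.05) + rvisc(0.35, 0.035) / 2)
  expect_lt(abs(mean(wf$p) / lumped - 1), 0.03)
})

test_that("zero inflow leaves the network at the reference pressure", {
  cfg <- simulation_config(inflow = inflow_spec(Q_max = 1e-12),
                           n_cycles_max = 3)
  wf <- simulate_waveform(NULL, fixture_network("bifurcation3"), cfg)
  expect_lt(max(abs(wf$p)), cfg$periodicity_tol)
})

test_that("distal resistance raises mean pressure as the DC oracle predicts", {
  topo <- fixture_network("bifurcation3")
  wa <- simulate_waveform(c(rd = 1), topo, simulation_config())
  wb <- simulate_waveform(c(rd = 2), topo, simulation_config())
  expect_gt(mean(wb$p), mean(wa$p))
  # lumped oracle: extra mean pressure ~ qbar * (Rd_tot extra)
  qbar <- 0.5 * 0.45 / 2
  expect_equal(mean(wb$p) - mean(wa$p), qbar * 0.9 * 130, tolerance = 0.15)
})

test_that("simulation is deterministic and converges on every fixture x BC", {
  topo <- fixture_network("bifurcation3")
  a <- simulate_waveform(NULL, topo, simulation_config(n_cycles_max = 4))
  b <- simulate_waveform(NULL, topo, simulation_config(n_cycles_max = 4))
  expect_identical(a$p, b$p)
  for (kind in c("bifurcation3", "tree7")) {
    for (bc in c("WK", "ST")) {
      wf <- simulate_waveform(NULL, fixture_network(kind),
                              simulation_config(bc_kind = bc))
      expect_true(wf$converged, info = paste(kind, bc))
      expect_length(wf$p, 32)
      expect_true(all(diff(wf$t) > 0))
      # periodicity approach is monotone after the first recorded deltas
      cd <- wf$cycle_delta
      if (length(cd) > 2) expect_true(all(diff(cd[-1]) <= 1e-10))
    }
  }
})

test_that("halving the grid changes the waveform by less than 1 percent", {
  topo <- fixture_network("bifurcation3")
  w1 <- simulate_waveform(NULL, topo, simulation_config(cells_per_vessel = 24))
  w2 <- simulate_waveform(NULL, topo, simulation_config(cells_per_vessel = 48))
  expect_lt(sqrt(sum((w1$p - w2$p)^2) / sum(w2$p^2)), 0.01)
})

test_that("batch simulation preserves row order and records failures", {
  sp <- default_parameter_space("WK", reduced = TRUE)
  Theta <- rbind(sp$nominal, sp$nominal * c(1.1, 0.9, 1, 1, 1))
  colnames(Theta) <- sp$names
  cfg <- simulation_config(n_cycles_max = 6)
  ws <- batch_simulate(Theta, fixture_network("bifurcation3"), cfg)
  expect_equal(dim(ws$F), c(32, 2))
  one <- simulate_waveform(Theta[1, ], fixture_network("bifurcation3"), cfg)
  expect_identical(ws$F[, 1], one$p)
  expect_false(identical(ws$F[, 1], ws$F[, 2]))
})
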