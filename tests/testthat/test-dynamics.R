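test_that("output function is piecewise linear with exact corners", {
  expect_equal(outputActivity(-60, -50, 0), 0)
  expect_equal(outputActivity(0, -50, 0), 1)
  expect_equal(outputActivity(-25, -50, 0), 0.5)
  expect_equal(outputActivity(50, -50, 0), 1)
  # monotone and bounded over a dense grid
  v <- seq(-120, 80, by = 0.25)
  f <- outputActivity(v, -50, 0)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(outputActivity(0, -50, -50), "Vmax")
})

test_that("drive law is exactly linear", {
  expect_equal(driveStrength(0, 1.35, 3.95), 3.95)
  expect_equal(driveStrength(1.0, 1.35, 3.95), 5.30)
  expect_equal(driveStrength(1.05, 1.1, 2.45), 3.605)
})

test_that("persistent-sodium kinetics obey gate identities", {
  p <- defaultNapParams()
  # multiplicative gate: h = 0 kills the current at any voltage
  for (V in c(-80, -50, -20, 10))
    expect_equal(napKinetics(V, 0, p)$INaP, 0)
  # sigmoid midpoint of inactivation
  expect_equal(napKinetics(p$Vh, 0.5, p)$hinf, 0.5)
  expect_error(napKinetics(-50, 1.5, p), "corruption")
})

test_that("h relaxes to hinf within five time constants at fixed V", {
  p <- defaultNapParams()
  for (V in c(-60, -48, -40)) {
    kin0 <- napKinetics(V, 0.5, p)
    # independent oracle: exact solution of the linear relaxation
    tEnd <- 5 * kin0$tauh
    exact <- kin0$hinf + (0.9 - kin0$hinf) * exp(-tEnd / kin0$tauh)
    # forward-Euler integration of dh/dt
    h <- 0.9; dt <- kin0$tauh / 2000
    for (i in seq_len(10000)) h <- h + dt * napKinetics(V, h, p)$dh
    expect_equal(h, exact, tolerance = 1e-4)
    expect_lt(abs(h - kin0$hinf), 1e-2)
  }
})

test_that("currents vanish for zero driving force or zero conductance", {
  syn <- defaultSynapseParams()
  r <- evaluateCurrents(V = -60, gL = 5, EL = -60, syn, 0, 0, 0)
  expect_equal(unname(r), c(0, 0, 0))
  # zero excitatory conductance regardless of voltage
  for (V in c(-80, -30, 0))
    expect_equal(evaluateCurrents(V, 5, -60, syn, 0, 2, 0)[["ISynE"]], 0)
  # zero inhibitory driving force at the inhibitory reversal
  expect_equal(evaluateCurrents(syn$EsynI, 5, -60, syn, 1, 3, 1)[["ISynI"]],
               0)
  expect_error(evaluateCurrents(-60, 5, -60, syn, -1, 0, 0), "contract")
})

test_that("noise update: zero-noise fixed point and determinism", {
  expect_equal(noiseStep(0, dt = 0.1, sigma = 0), 0)
  # pure decay toward zero when sigma = 0
  x <- 5
  for (i in 1:1000) x <- noiseStep(x, 0.5, 0, tau = 10)
  expect_lt(abs(x), 1e-6)
  set.seed(42); a <- replicate(50, noiseStep(1, 0.1, 2))
  set.seed(42); b <- replicate(50, noiseStep(1, 0.1, 2))
  expect_identical(a, b)
})

test_that("noise process reaches the stated stationary standard deviation", {
  # Monte-Carlo estimate vs the closed-form Ornstein-Uhlenbeck stationary sd
  set.seed(7)
  sigma <- 1.5; tau <- 10; dt <- 0.2
  n <- 2000
  x <- numeric(n)
  nSteps <- 600
  for (s in seq_len(nSteps)) x <- noiseStep(x, dt, sigma, tau)
  expect_equal(sd(x), sigma, tolerance = 0.02)
})

test_that("isolated plain population rests at its leak reversal", {
  net <- plainPopNet()
  d <- stateDerivative(net, c(-60, 0, 0))
  expect_equal(d, c(0, 0))
  # integrated from elsewhere it relaxes to EL
  fin <- rk4Reference(net, c(-40, 0, 0), numeric(), duration = 100,
                      dt = 0.05)
  expect_equal(fin[1], -60, tolerance = 1e-6)
})

test_that("analytic fixed point under constant drive matches integration", {
  net <- plainPopNet()
  D <- 3
  # V* solves gL (V - EL) + gD D (V - EsynE) = 0
  syn <- synapseParams(net)
  Vstar <- (5 * -60 + D * syn$EsynE) / (5 + D)
  fin <- rk4Reference(net, c(-60, 0, 0), c("P:l" = D), duration = 200,
                      dt = 0.05)
  expect_equal(fin[1], Vstar, tolerance = 1e-6)
})

test_that("compiled derivative agrees with the R reference", {
  hc <- buildHalfcenterFixture(0.4)
  st <- locomotoR:::.initialState(hc$net)
  st[1:2] <- c(-47, -52)  # asymmetric, mid-range voltages
  cn <- locomotoR:::.compileNetwork(hc$net, hc$drives)
  dCpp <- locomotoR:::cpp_state_derivative(cn, st)
  dR <- stateDerivative(hc$net, st, hc$drives)
  expect_equal(dCpp, dR, tolerance = 1e-12)
})

test_that("compiled integration matches the R reference trajectory", {
  hc <- buildHalfcenterFixture(0.4)
  st <- locomotoR:::.initialState(hc$net)
  cn <- locomotoR:::.compileNetwork(hc$net, hc$drives)
  out <- locomotoR:::cpp_simulate(cn, st, 200, 0.05, 200, 0:1, FALSE)
  ref <- rk4Reference(hc$net, st, hc$drives, duration = 200, dt = 0.05)
  expect_equal(out$final[1:4], ref[1:4], tolerance = 1e-9)
})

test_that("deterministic integration is exactly reproducible and keeps h in [0,1]", {
  hc <- buildHalfcenterFixture(0.5)
  st <- locomotoR:::.initialState(hc$net)
  cn <- locomotoR:::.compileNetwork(hc$net, hc$drives)
  a <- locomotoR:::cpp_simulate(cn, st, 2000, 0.1, 1, 0:1, FALSE)
  b <- locomotoR:::cpp_simulate(cn, st, 2000, 0.1, 1, 0:1, FALSE)
  expect_identical(a$V, b$V)
  expect_identical(a$final, b$final)
  h <- a$final[3:4]
  expect_true(all(h >= 0 & h <= 1))
})
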