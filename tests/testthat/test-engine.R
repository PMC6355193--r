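net <- buildDefaultNetwork()

test_that("stimulation targets resolve names, aliases and groups", {
  expect_equal(locomotoR:::.stimTargets(net, "CnF-Glu", "l"), "CnF-Glu:l")
  expect_equal(locomotoR:::.stimTargets(net, "CnF-GABA/Gly", "l"),
               "CnF-Inh:l")
  expect_setequal(locomotoR:::.stimTargets(net, "LPGi-Glu", "l"),
                  c("LPGi-Glu-1:l", "LPGi-Glu-2:l"))
  expect_setequal(locomotoR:::.stimTargets(net, "CnF-Glu", "both"),
                  c("CnF-Glu:l", "CnF-Glu:r"))
  expect_error(locomotoR:::.stimTargets(net, "CnF-Gloo", "l"),
               "unknown stimulation target")
})

test_that("protocol drives combine network constants, laws and fixed drives", {
  pr <- Protocol(net, "CnF-Glu", "l", m = 1.35, b = 3.95, alpha = 0.5,
                 fixedDrives = data.frame(target = "PPN-Inh", side = "l",
                                          value = 2))
  d <- locomotoR:::.driveVector(net, pr)
  expect_equal(d[["VN:l"]], 2.15)
  expect_equal(d[["CnF-Glu:l"]], 1.35 * 0.5 + 3.95)
  expect_equal(d[["PPN-Inh:l"]], 2)
  expect_false("CnF-Glu:r" %in% names(d))
  expect_error(Protocol(net, "CnF-Glu", alpha = 2), "alpha")
})

test_that("deterministic and seeded stochastic runs are reproducible", {
  pr <- Protocol(net, "CnF-Glu", "l", m = 1.35, b = 3.95, alpha = 0.6,
                 duration = 1500)
  a <- simulateNetwork(net, pr)
  b <- simulateNetwork(net, pr)
  expect_identical(a@f, b@f)
  prn <- Protocol(net, "CnF-Glu", "l", m = 1.35, b = 3.95, alpha = 0.6,
                  duration = 1000, sigmaNoise = 1, dt = 0.2, seed = 11)
  n1 <- simulateNetwork(net, prn)
  n2 <- simulateNetwork(net, prn)
  expect_identical(n1@f, n2@f)
  prn2 <- prn; prn2@seed <- 12
  n3 <- simulateNetwork(net, prn2)
  expect_false(identical(n1@f, n3@f))
})

test_that("simulated activities stay in [0,1] and extensors are tonic at rest", {
  pr <- Protocol(net, duration = 6000)
  res <- simulateNetwork(net, pr, record = c("RG-F:l:hind", "RG-E:l:hind"))
  expect_true(all(res@f >= 0 & res@f <= 1))
  late <- res@time > 3000
  # vestibular drive alone: extensors tonic, no flexor rhythm
  expect_lt(diff(range(res@f[late, 1])), 0.05)
  expect_gt(mean(res@f[late, 2]), 0.1)
  expect_lt(diff(range(res@f[late, 2])), 0.05)
})

test_that("settling reports quiescence without stimulation and a fixed point with it", {
  q <- settleAtAlpha(net, target = NULL, alpha = 0, chunk = 4000,
                     cap = 8000)
  expect_equal(q$status, "quiescent")
  s1 <- settleAtAlpha(net, "CnF-Glu", "l", m = 1.35, b = 3.95, alpha = 0.6,
                      chunk = 5000, cap = 40000)
  expect_equal(s1$status, "converged")
  expect_gt(s1$freq, 1)
  # re-settling from the converged state reproduces the phases
  s2 <- settleAtAlpha(net, "CnF-Glu", "l", m = 1.35, b = 3.95, alpha = 0.6,
                      state = s1$state, chunk = 5000, cap = 40000)
  expect_equal(s2$status, "converged")
  expect_true(all(pmin(abs(s2$phase - s1$phase),
                       1 - abs(s2$phase - s1$phase)) < 0.005))
  expect_equal(s2$freq, s1$freq, tolerance = 0.01)
})

test_that("right-side stimulation mirrors the left-side phase differences", {
  # the mirrored run starts from the mirrored initial state: phase-locked
  # attractors come in side-swapped pairs and the initial state selects
  # between them
  st0 <- locomotoR:::.initialState(net)
  aL <- settleAtAlpha(net, "CnF-Glu", "l", m = 1.35, b = 3.95, alpha = 0.5,
                      state = st0, chunk = 5000, cap = 40000)
  aR <- settleAtAlpha(net, "CnF-Glu", "r", m = 1.35, b = 3.95, alpha = 0.5,
                      state = mirrorState(net, st0), chunk = 5000,
                      cap = 40000)
  expect_equal(aL$status, "converged")
  expect_equal(aR$status, "converged")
  expect_equal(aR$freq, aL$freq, tolerance = 0.02)
  circ <- function(a, b) min(abs(a - b), 1 - abs(a - b))
  # left-right relabelling: both left-right phases map to 1 - phi
  expect_lt(circ(aR$phase[["hindLR"]], (1 - aL$phase[["hindLR"]]) %% 1),
            0.02)
  expect_lt(circ(aR$phase[["foreLR"]], (1 - aL$phase[["foreLR"]]) %% 1),
            0.02)
  # homolateral phase of the mirrored run equals the left run's right-side
  # homolateral phase, i.e. diagonal minus hind left-right
  expect_lt(circ(aR$phase[["homolateral"]],
                 (aL$phase[["diagonal"]] - aL$phase[["hindLR"]]) %% 1),
            0.03)
})

test_that("a vanishing noise level reproduces deterministic frequencies", {
  alpha <- 0.6
  det <- settleAtAlpha(net, "CnF-Glu", "l", m = 1.35, b = 3.95,
                       alpha = alpha, chunk = 5000, cap = 40000)
  rec <- noisySweep(net, "CnF-Glu", "l", m = 1.35, b = 3.95,
                    alphaStep = alpha, alphaMax = alpha,
                    durationPerStep = 8000, sigmaNoise = 1e-6, seed = 3,
                    dt = 0.2, discard = 4000)
  rec <- rec[rec$alpha == alpha, ]
  expect_gt(nrow(rec), 10)
  expect_equal(mean(rec$freq), det$freq, tolerance = 0.01)
  expect_lt(min(abs(mean(rec$hindLR) - det$phase[["hindLR"]]),
                1 - abs(mean(rec$hindLR) - det$phase[["hindLR"]])), 0.01)
})

test_that("noisy cycle records carry one row per detected cycle with labels", {
  rec <- noisySweep(net, "CnF-Glu", "l", m = 1.35, b = 3.95,
                    alphaStep = 0.5, alphaMax = 1, durationPerStep = 4000,
                    sigmaNoise = 1, seed = 5, dt = 0.2, discard = 1000)
  expect_true(all(c("freq", "hindLR", "foreLR", "homolateral", "diagonal",
                    "gait", "alpha") %in% names(rec)))
  expect_gt(nrow(rec), 20)
  expect_true(all(rec$gait %in% c("walk", "trot", "gallop", "bound",
                                  "unclassified")))
})

test_that("robustness suite is seeded and classifies the unperturbed model", {
  r1 <- robustnessSuite(net, sigmaP = 0, nModels = 1, seed = 2,
                        nSteps = 10, chunk = 4000, cap = 12000)
  r2 <- robustnessSuite(net, sigmaP = 0, nModels = 1, seed = 2,
                        nSteps = 10, chunk = 4000, cap = 12000)
  expect_identical(r1$models$class, r2$models$class)
  expect_equal(nrow(r1$summary), 1)
  # the unperturbed model is never unstable
  expect_equal(r1$summary$unstable, 0)
})

test_that("rhythm-generator calibration finds a monotone spanning curve", {
  cal <- calibrateRGCenter()
  expect_true(cal$success)
  expect_true(all(diff(cal$curve$freq) > -0.1))
  expect_lt(abs(cal$curve$freq[1] - 3), 0.5)
  expect_lt(abs(cal$curve$freq[nrow(cal$curve)] - 10.5), 0.5)
  expect_error(calibrateRGCenter(c(100, 200)), "target range")
})
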