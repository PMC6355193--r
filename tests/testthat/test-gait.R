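test_that("onset detection finds interpolated threshold crossings", {
  t <- seq(0, 400, by = 1)
  sq <- as.numeric(t %% 100 >= 50)  # rising edges at 50, 150, 250, 350
  on <- detectOnsets(sq, t)
  expect_equal(length(on), 4)
  expect_equal(on, c(50, 150, 250, 350), tolerance = 1)
  expect_identical(detectOnsets(rep(0.5, 100), seq_len(100)), numeric(0))
  # 10-Hz sinusoid rescaled to [0, 1]: onsets spaced 100 ms
  t <- seq(0, 2000, by = 0.5)
  s <- (sin(2 * pi * t / 100) + 1) / 2
  on <- detectOnsets(s, t)
  expect_equal(diff(on), rep(100, length(on) - 1), tolerance = 0.1)
  # refractory gap suppresses chatter
  ch <- c(0, 1, 0, 1, 0, 1, rep(0, 10))
  expect_equal(length(detectOnsets(ch, seq_along(ch) * 2, refractory = 20)),
               1)
})

test_that("phase difference is the wrapped normalized lag", {
  expect_equal(phaseDifference(0, 0, 100), 0)
  expect_equal(phaseDifference(0, 50, 100), 0.5)
  expect_equal(phaseDifference(0, 125, 100), 0.25)
  expect_error(phaseDifference(0, 1, 0), "period")
  # full-cycle wrap property over assorted offsets
  for (x in c(0, 13.7, 99))
    expect_equal(phaseDifference(x, x + 80, 80), 0)
})

test_that("cycle frequency is the reciprocal period per cycle", {
  expect_equal(cycleFrequency(c(0, 100, 200)), c(10, 10))
  expect_equal(cycleFrequency(c(0, 250)), 4)
  f <- cycleFrequency(0)
  expect_true(is.na(f))
  expect_true(attr(f, "undefined"))
})

test_that("gait classification matches the window definitions", {
  expect_equal(classifyGait(0.5, 0.5, 0.5, 0.0), "trot")
  expect_equal(classifyGait(0.02, 0.98, 0.5, 0.5), "bound")
  expect_equal(classifyGait(0.5, 0.5, 0.75, 0.25), "walk")
  expect_equal(classifyGait(0.8, 0.8, 0.3, 0.3), "gallop")
  expect_equal(classifyGait(c(0.3, 0.5, 0.2, 0.7)), "gallop")
  expect_error(classifyGait(1.2, 0.5, 0.5, 0.5), "phase")
})

test_that("gait labels have no side preference", {
  # left-right relabelling: hind and fore left-right phases map to 1 - phi,
  # homolateral and diagonal swap
  set.seed(11)
  for (i in 1:200) {
    phi <- runif(4)
    mirrored <- c((1 - phi[1]) %% 1, (1 - phi[2]) %% 1, phi[4], phi[3])
    expect_identical(classifyGait(phi), classifyGait(mirrored))
  }
})

test_that("cycle records segment a synthetic four-limb pattern", {
  # synthetic trot at 5 Hz: hind pair alternates, diagonal pairs synchronous
  t <- seq(0, 4000, by = 1)
  burst <- function(lag) as.numeric(((t - lag) %% 200) < 80 & t >= lag)
  rec <- cycleRecords(t, burst(0), burst(100), burst(100), burst(0))
  rec <- rec[rec$cycle > 1, ]
  expect_equal(mean(rec$freq), 5, tolerance = 0.01)
  expect_equal(mean(rec$hindLR), 0.5, tolerance = 0.01)
  expect_equal(mean(rec$foreLR), 0.5, tolerance = 0.01)
  expect_equal(mean(rec$diagonal), 0, tolerance = 0.01)
  expect_true(all(rec$gait == "trot"))
})

test_that("phase-frequency histogram conserves mass", {
  rec <- data.frame(freq = c(4.1, 4.1, 4.1), hindLR = c(0.5, 0.5, 0.5))
  h <- phaseFrequencyHistogram(rec)
  expect_equal(sum(h$density), 1)
  expect_equal(max(h$density), 1)
  expect_equal(dim(h$density), c(65, 56))
  # two equal groups
  rec2 <- data.frame(freq = c(2, 2, 8, 8), hindLR = c(0.1, 0.1, 0.9, 0.9))
  h2 <- phaseFrequencyHistogram(rec2)
  expect_equal(sort(h2$density[h2$density > 0]), c(0.5, 0.5))
  # out-of-range cycles count in the total but not the bins
  rec3 <- data.frame(freq = c(4, 20), hindLR = c(0.5, 0.5))
  h3 <- phaseFrequencyHistogram(rec3)
  expect_equal(sum(h3$density) + h3$outOfRange, 1)
  expect_error(phaseFrequencyHistogram(rec3[0, ]), "empty")
})

test_that("gait probability map groups gallop with bound and conserves mass", {
  rec <- data.frame(freq = c(4, 4, 9, 9.1), hindLR = 0,
                    gait = c("trot", "trot", "gallop", "bound"))
  g <- gaitProbabilityMap(rec)
  expect_equal(sum(g$prob), 1)
  expect_equal(sum(g$prob["trot", ]), 0.5)
  expect_equal(sum(g$prob["gallop.bound", ]), 0.5)
  expect_equal(g$total, 4)
  # same records, same totals as the histogram
  h <- phaseFrequencyHistogram(rec)
  expect_equal(h$total, g$total)
  expect_error(gaitProbabilityMap(rec[0, ]), "empty")
})
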