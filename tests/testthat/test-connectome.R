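net <- buildDefaultNetwork()

test_that("default network has the full bilateral roster", {
  pops <- populations(net)
  expect_equal(nrow(pops), 84)
  expect_equal(sum(pops$side == "l"), sum(pops$side == "r"))
  # four rhythm generators per side of the body: flexor + extensor,
  # fore + hind
  expect_equal(sum(pops$name == "RG-F"), 4)
  expect_equal(sum(pops$name == "RG-E"), 4)
  expect_setequal(pops$id[pops$name == "dIni"],
                  c("dIni:l:fore", "dIni:l:hind", "dIni:r:fore",
                    "dIni:r:hind"))
  # vestibular drive attached on both sides
  expect_setequal(drives(net)$target, c("VN:l", "VN:r"))
  expect_equal(drives(net)$value, c(2.15, 2.15))
})

test_that("published spot-check weights are realized", {
  expect_equal(connectionWeight(net, "CnF-Glu:l", "PPN-Glu:l"), 0.56)
  expect_equal(connectionWeight(net, "CnF-Inh:l", "CnF-Glu:l"), -0.5)
  expect_equal(connectionWeight(net, "CnF-Glu:r", "LPGi-Glu-1:l"), 0.45)
  expect_equal(connectionWeight(net, "CnF-Glu:l", "LPGi-Glu-1:r"), 0.45)
  expect_equal(connectionWeight(net, "CnF-Glu:l", "LPGi-Glu-1:l"), 0.95)
  # the inhibitory relay rows are printed as magnitudes; they are realized
  # as inhibition
  expect_equal(connectionWeight(net, "dIni:l:hind", "V0D:l:hind"), -4)
  expect_equal(connectionWeight(net, "dIni:l:fore", "V0D-LPN:l:fore"), -7.5)
})

test_that("every printed table row is realized with its printed weight", {
  tab <- table1Weights()
  conn <- connections(net)
  key <- paste(conn$source, conn$target)
  for (i in seq_len(nrow(tab))) {
    ids <- expandTableRow(tab[i, ])
    for (k in seq_len(nrow(ids))) {
      j <- match(paste(ids[k, 1], ids[k, 2]), key)
      expect_false(is.na(j),
                   info = paste("missing:", ids[k, 1], "->", ids[k, 2]))
      expect_equal(conn$printed[j], abs(tab$weight[i]),
                   info = paste(ids[k, 1], "->", ids[k, 2]))
      # realized sign follows the source transmitter, not the printed sign
      src <- populations(net)
      inh <- src$transmitter[match(ids[k, 1], src$id)] == "inh"
      expect_equal(sign(conn$weight[j]), if (inh) -1 else 1,
                   info = paste("sign:", ids[k, 1], "->", ids[k, 2]))
    }
  }
  # and nothing beyond the table: counts match
  nExpected <- sum(vapply(seq_len(nrow(tab)), function(i)
    nrow(expandTableRow(tab[i, ])), integer(1)))
  expect_equal(nrow(conn), nExpected)
})

test_that("default network passes structural validation", {
  expect_identical(validateNetwork(net), character(0))
})

test_that("validation flags sign and mirror violations", {
  bad <- net
  conn <- connections(bad)
  i <- which(conn$source == "CnF-Inh:l" & conn$target == "CnF-Glu:l")
  conn$weight[i] <- 0.5
  bad@connections <- conn
  v <- validateNetwork(bad)
  expect_true(any(grepl("sign violation", v)))
  expect_true(any(grepl("mirror violation", v)))
  bad2 <- net
  bad2@connections <- connections(net)[-1, ]
  expect_true(any(grepl("mirror violation", validateNetwork(bad2))))
})

test_that("lesioning silences outgoing weights of the region only", {
  les <- applyLesion(net, "PPN")
  conn <- connections(les)
  ppn <- grepl("^PPN-", conn$source)
  expect_true(all(conn$weight[ppn] == 0))
  expect_identical(conn$weight[!ppn], connections(net)$weight[!ppn])
  # input network untouched
  expect_equal(connectionWeight(net, "PPN-Glu:l", "LPGi-Glu-1:l"), 1)
  expect_equal(connectionWeight(les, "CnF-Glu:l", "LPGi-Glu-1:l"), 0.95)
  # one-sided lesion
  lesL <- applyLesion(net, "PPN", sides = "l")
  expect_equal(connectionWeight(lesL, "PPN-Glu:l", "LPGi-Glu-1:l"), 0)
  expect_equal(connectionWeight(lesL, "PPN-Glu:r", "LPGi-Glu-1:r"), 1)
  expect_identical(applyLesion(net, character()), net)
  expect_error(applyLesion(net, "PPPN"), "unknown region")
})

test_that("weight perturbation is unbiased, seeded, and pure", {
  expect_identical(connections(perturbWeights(net, 0, seed = 1))$weight,
                   connections(net)$weight)
  a <- perturbWeights(net, 0.1, seed = 7)
  b <- perturbWeights(net, 0.1, seed = 7)
  expect_identical(connections(a)$weight, connections(b)$weight)
  expect_false(identical(connections(a)$weight, connections(net)$weight))
  expect_error(perturbWeights(net, -0.1), "sigmaP")
  # Monte-Carlo check that the multiplier has unit mean
  w0 <- connections(net)$weight[1]
  ws <- vapply(1:2000, function(s)
    connections(perturbWeights(net, 0.1, seed = s))$weight[1], numeric(1))
  se <- 0.1 * abs(w0) / sqrt(2000)
  expect_lt(abs(mean(ws) - w0), 3 * se)
})

test_that("half-center fixture: rest at zero drive, anti-phase at mid drive", {
  hc0 <- buildHalfcenterFixture(0)
  cn <- locomotoR:::.compileNetwork(hc0$net, hc0$drives)
  out <- locomotoR:::cpp_simulate(cn, locomotoR:::.initialState(hc0$net),
                                  6000, 0.1, 1, 0:1, FALSE)
  late <- out$time > 3000
  expect_lt(diff(range(out$f[late, 1])), 0.01)
  expect_lt(diff(range(out$f[late, 2])), 0.01)

  hc <- buildHalfcenterFixture(0.8)
  cn <- locomotoR:::.compileNetwork(hc$net, hc$drives)
  st <- locomotoR:::.initialState(hc$net)
  st[1] <- st[1] + 3   # break the symmetric in-phase solution
  out <- locomotoR:::cpp_simulate(cn, st, 14000, 0.1, 1, 0:1, FALSE)
  late <- out$time > 8000
  onA <- detectOnsets(out$f[late, 1], out$time[late])
  onB <- detectOnsets(out$f[late, 2], out$time[late])
  expect_gt(length(onA), 4)
  per <- mean(diff(onA))
  phi <- phaseDifference(onA[2], onB[onB > onA[2]][1], per)
  expect_equal(phi, 0.5, tolerance = 0.02)
})

test_that("half-center populations are swap-symmetric", {
  hc <- buildHalfcenterFixture(0.5)
  cn <- locomotoR:::.compileNetwork(hc$net, hc$drives)
  st <- locomotoR:::.initialState(hc$net)
  # swap-symmetric initial state: exchanging the two cells (V, h, noise)
  stSwap <- st[c(2, 1, 4, 3, 6, 5)]
  a <- locomotoR:::cpp_simulate(cn, st, 500, 0.1, 1, 0:1, FALSE)
  b <- locomotoR:::cpp_simulate(cn, stSwap, 500, 0.1, 1, 0:1, FALSE)
  expect_equal(a$V[, 1], b$V[, 2], tolerance = 1e-12)
  expect_equal(a$V[, 2], b$V[, 1], tolerance = 1e-12)
})

test_that("connectome exports as a three-column table", {
  path <- tempfile(fileext = ".tsv")
  writeConnectomeTSV(net, path)
  d <- read.delim(path)
  expect_equal(names(d), c("source", "target", "weight"))
  expect_equal(nrow(d), nrow(connections(net)))
})

test_that("connectome weights round-trip through the TSV format", {
  path <- tempfile(fileext = ".tsv")
  writeConnectomeTSV(net, path)
  d <- read.delim(path)
  d$weight[1] <- 99
  path2 <- tempfile(fileext = ".tsv")
  write.table(d, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  net2 <- readConnectomeTSV(net, path2)
  expect_equal(connections(net2)$weight[1], 99)
  expect_equal(connections(net2)$weight[-1], connections(net)$weight[-1])
  d$source[1] <- "Nope:l"
  write.table(d, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readConnectomeTSV(net, path2), "unknown connection")
})
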