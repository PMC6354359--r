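test_that("Skellam pmf normalizes, reduces to Poisson, and matches a series oracle", {
  for (mus in list(c(3, 1), c(0.5, 2), c(8, 4))) {
    k <- -80:120
    expect_lt(abs(sum(skellamPmf(k, mus[1], mus[2])) - 1), 1e-9)
  }
  expect_equal(skellamPmf(0:12, 3, 0), stats::dpois(0:12, 3))
  expect_equal(skellamPmf(-1, 3, 0), 0)
  expect_equal(skellamPmf(c(-3, 0, 2), 0, 2),
               c(stats::dpois(3, 2), stats::dpois(0, 2), 0))
  # s_0(1,1) = e^-2 I_0(2); independent power-series evaluation of I_0
  i0 <- sum(vapply(0:40, function(m) 1 / factorial(m)^2, 0))
  expect_equal(skellamPmf(0, 1, 1), exp(-2) * i0, tolerance = 1e-12)
  expect_error(skellamPmf(0, -1, 1), "nonnegative")
  expect_error(skellamPmf(0.5, 1, 1), "integer")
})

test_that("fitness terms obey the degenerate limits", {
  p0 <- GameParams(r = 0.3, f = 0, muC = 0, muD = 1, a = 0.2)
  for (s in c("INDISCRIMINATE", "DISCRIMINATE")) {
    w <- pairedMaleFitness(p0, s)
    expect_equal(w$direct, 1)
    expect_equal(w$indirect, 0)
  }
  # f = 0 or r = 0 kills the indirect term
  pf <- GameParams(r = 0.5, f = 0, muC = 3, muD = 1, a = 0.2)
  pr <- GameParams(r = 0, f = 0.5, muC = 3, muD = 1, a = 0.2)
  expect_equal(pairedMaleFitness(pf, "DISCRIMINATE")$indirect, 0)
  expect_equal(pairedMaleFitness(pr, "INDISCRIMINATE")$indirect, 0)
  expect_equal(cuckolderFitness(pr, "RELATED")$indirect, 0)
  expect_equal(cuckolderFitness(pr, "UNRELATED")$indirect, 0)
})

test_that("model inequalities hold across a parameter grid", {
  grid <- expand.grid(muC = c(0.5, 2, 6), a = c(0.1, 0.5, 0.9),
                      r = c(0.1, 0.5), f = c(0.3, 0.9))
  for (i in seq_len(nrow(grid))) {
    p <- GameParams(r = grid$r[i], f = grid$f[i], muC = grid$muC[i],
                    muD = 1, a = grid$a[i])
    wi <- pairedMaleFitness(p, "INDISCRIMINATE")
    wd <- pairedMaleFitness(p, "DISCRIMINATE")
    expect_gt(wi$direct, wd$direct)
    expect_lt(wi$indirect, wd$indirect)
    cr <- cuckolderFitness(p, "RELATED")
    cu <- cuckolderFitness(p, "UNRELATED")
    expect_gt(cr$direct, cu$direct)
    expect_lt(cr$indirect, cu$indirect)
    # breakdown invariants
    for (w in list(wi, wd, cr, cu)) {
      expect_true(w$direct >= 0 && w$direct <= 1)
      expect_true(w$indirect >= 0 && w$indirect <= p@r)
      expect_lte(w$total, 1 + p@r)
    }
  }
})

test_that("costless discrimination is weakly adaptive when f r > 0", {
  p <- GameParams(r = 0.5, f = 0.5, muC = 2, muD = 1, a = 0)
  wi <- pairedMaleFitness(p, "INDISCRIMINATE")
  wd <- pairedMaleFitness(p, "DISCRIMINATE")
  expect_equal(wd$direct, wi$direct)
  expect_gte(wd$indirect, wi$indirect)
  expect_gte(wd$total, wi$total)
})

test_that("analytic terms agree with the Monte-Carlo oracle at a test point", {
  p <- GameParams(r = 0.25, f = 0.5, muC = 3, muD = 1, a = 0.2)
  for (s in c("INDISCRIMINATE", "DISCRIMINATE")) {
    an <- pairedMaleFitness(p, s)
    mc <- monteCarloGame(p, "paired", s, nDraws = 1e5, seed = 31)
    expect_lt(abs(an$direct - mc$direct), 3 * mc$directSE)
    expect_lt(abs(an$indirect - mc$indirect), 3 * mc$indirectSE)
  }
  for (s in c("RELATED", "UNRELATED")) {
    an <- cuckolderFitness(p, s)
    mc <- monteCarloGame(p, "cuckolder", s, nDraws = 1e5, seed = 32)
    expect_lt(abs(an$direct - mc$direct), 3 * mc$directSE)
    expect_lt(abs(an$indirect - mc$indirect), 3 * mc$indirectSE)
  }
})

test_that("Monte-Carlo machinery scales and its two egg modes agree", {
  p <- GameParams(r = 0.25, f = 0.5, muC = 3, muD = 1, a = 0.2)
  # no competitors, no relative: direct = 1 in every draw
  p0 <- GameParams(r = 0.25, f = 0, muC = 0, muD = 1, a = 0.2)
  mc0 <- monteCarloGame(p0, "paired", "INDISCRIMINATE", nDraws = 500)
  expect_equal(mc0$direct, 1)
  expect_equal(mc0$directSE, 0)
  # SE shrinks like 1/sqrt(n)
  s1 <- monteCarloGame(p, "paired", "INDISCRIMINATE", nDraws = 1e4,
                       seed = 1)$directSE
  s2 <- monteCarloGame(p, "paired", "INDISCRIMINATE", nDraws = 1e6,
                       seed = 1)$directSE
  expect_equal(s1 / s2, 10, tolerance = 0.15)
  # per-egg multinomial allocation has the same mean as expected shares
  me <- monteCarloGame(p, "paired", "DISCRIMINATE", nDraws = 2e5, seed = 2)
  mm <- monteCarloGame(p, "paired", "DISCRIMINATE", nDraws = 2e5, seed = 3,
                       mode = "multinomial")
  expect_lt(abs(me$direct - mm$direct),
            3 * sqrt(me$directSE^2 + mm$directSE^2))
})

test_that("decision map reproduces the qualitative tolerance regions", {
  dm <- decisionMap(r = 0.5, f = 0.5, muD = 1,
                    muCGrid = c(0.05, 0.5, 2, 5, 8, 10),
                    aGrid = c(0, 0.05, 0.2, 0.5, 0.9))
  # strong sperm competition, cheap discrimination: tolerance adaptive
  expect_true(dm$tolerate_adaptive[dm$muC == 10 & dm$a == 0.05])
  # vanishing sperm competition: defend indiscriminately
  expect_true(all(!dm$tolerate_adaptive[dm$muC == 0.05 & dm$a >= 0.05]))
  # the tolerate region never shrinks as the cost a decreases
  as <- sort(unique(dm$a))
  for (m in unique(dm$muC)) {
    tol <- dm$tolerate_adaptive[order(dm$a)][dm$muC[order(dm$a)] == m]
    # once tolerance is lost at some a it stays lost at higher a
    expect_true(all(diff(tol) <= 0))
  }
})

test_that("brood fitness increase follows the allelic-value formula", {
  expect_equal(round(broodValueIncrease(0.038, 0.449), 1), 3.1)
  expect_equal(broodValueIncrease(0, 0.449), 0)
  expect_equal(broodValueIncrease(0.5, 0.449), 100 * 0.449 * 0.5 / 0.551)
  expect_error(broodValueIncrease(0.5, 1), "baseline")
  expect_error(broodValueIncrease(1.5, 0.3), "rBar")
})
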