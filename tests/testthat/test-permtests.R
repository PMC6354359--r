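test_that("moment statistics match a direct-formula oracle", {
  expect_equal(momentStats(c(1, 2, 3)),
               c(mean = 2, variance = 1, skewness = 0))
  v <- c(0, 0, 1)
  expect_equal(momentStats(v), oracleMoments(v))
  v2 <- c(-0.1, 0.05, 0.3, 0.02, 0.7)
  expect_equal(momentStats(v2), oracleMoments(v2))
  # degenerate: zero variance has undefined skewness
  z <- momentStats(c(0, 0, 0))
  expect_equal(unname(z[c("mean", "variance")]), c(0, 0))
  expect_true(is.na(z["skewness"]))
  expect_error(momentStats(c(1, 2)), "skewness")
  expect_error(momentStats(1), "variance")
})

test_that("degenerate exchangeability gives p = 1 for the mean", {
  ids <- c("a", "b", "c", "p1", "p2", "p3")
  m <- matrix(0.2, 6, 6, dimnames = list(ids, ids))
  obs <- data.frame(focal_id = c("a", "b", "c"),
                    partner_id = c("p1", "p2", "p3"), season = "dry")
  res <- randomizePairings(obs, m, "WITHIN_PAIR", nPerm = 200, seed = 1)
  expect_equal(res$p[res$statistic == "mean"], 1)
})

test_that("permutation p matches the exhaustive arrangement oracle", {
  set.seed(42)
  ids <- c(paste0("f", 1:3), paste0("c", 1:3))
  m <- matrix(stats::runif(36, -0.1, 0.5), 6, 6, dimnames = list(ids, ids))
  obs <- data.frame(focal_id = paste0("f", 1:3),
                    partner_id = paste0("c", 1:3), season = "dry")
  # exhaustive oracle: all 6 assignments of the 3 partners
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  stats_exh <- t(vapply(perms, function(p) {
    v <- m[cbind(paste0("f", 1:3), paste0("c", p))]
    c(mean(v), stats::var(v))
  }, numeric(2)))
  obs_v <- m[cbind(paste0("f", 1:3), paste0("c", 1:3))]
  p_exh <- c(mean(stats_exh[, 1] >= mean(obs_v)),
             mean(stats_exh[, 2] >= stats::var(obs_v)))
  nP <- 4000
  res <- randomizePairings(obs, m, "FOCAL_VS_SET", nPerm = nP, seed = 9)
  for (j in 1:2) {
    se <- sqrt(p_exh[j] * (1 - p_exh[j]) / nP)
    expect_lt(abs(res$p[j] - p_exh[j]), 3 * se + 2 / nP)
  }
})

test_that("the permutation scheme preserves pools and set sizes per season", {
  set.seed(3)
  ids <- c(paste0("f", 1:6), paste0("c", 1:10))
  m <- matrix(stats::runif(256), 16, 16, dimnames = list(ids, ids))
  obs <- data.frame(
    focal_id = rep(paste0("f", 1:6), c(1, 2, 2, 1, 3, 1)),
    partner_id = paste0("c", 1:10),
    season = rep(c("dry", "rainy"), c(5, 5)))
  # checkInvariants re-verifies the partner multiset on every permutation
  expect_silent(randomizePairings(obs, m, "FOCAL_VS_SET", nPerm = 50,
                                  seed = 2, checkInvariants = TRUE))
  # identical seeds reproduce identical p values
  r1 <- randomizePairings(obs, m, nPerm = 100, seed = 7)
  r2 <- randomizePairings(obs, m, nPerm = 100, seed = 7)
  expect_identical(r1, r2)
  # WITHIN_PAIR rejects multi-partner focals
  expect_error(randomizePairings(obs, m, "WITHIN_PAIR", nPerm = 10),
               "exactly one partner")
  # missing relatedness values are reported by pair
  m2 <- m; m2["f1", "c1"] <- NA
  expect_error(randomizePairings(obs, m2, nPerm = 10), "f1.*c1")
})

test_that("zero-paternity broods are excluded exactly at the boundary", {
  mkBrood <- function(bid, nWP, nEP) {
    data.frame(brood_id = bid, season = "dry", mother_id = paste0("F", bid),
               paired_male_id = paste0("M", bid),
               offspring_id = paste0(bid, "_o", seq_len(nWP + nEP)),
               sire_label = c(rep("WITHIN_PAIR", nWP),
                              rep("EP_1", nEP)))
  }
  b <- BroodSet(rbind(mkBrood("b1", 0, 30), mkBrood("b2", 1, 29),
                      mkBrood("b3", 15, 15)))
  expect_message(kept <- excludeZeroPaternity(b), "1 zero-paternity")
  expect_setequal(broodIds(kept), c("b2", "b3"))
  # no zero-paternity broods: identity
  b2 <- BroodSet(rbind(mkBrood("b2", 1, 29), mkBrood("b3", 15, 15)))
  expect_identical(broodTable(excludeZeroPaternity(b2)), broodTable(b2))
  expect_equal(unname(paternityFraction(b)), c(0, 1 / 30, 0.5))
})

test_that("Benjamini-Hochberg flags follow the step-up rule", {
  expect_identical(bhAdjust(c(0.001, 0.001, 0.001)), rep(TRUE, 3))
  expect_identical(bhAdjust(c(0.01, 0.02, 0.2, 0.9)),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bhAdjust(0.9), FALSE)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # step-through oracle on an unsorted vector
  p <- c(0.04, 0.005, 0.3, 0.03, 0.9)
  m <- length(p)
  ord <- order(p)
  thresh <- seq_len(m) * 0.10 / m
  imax <- max(c(0, which(p[ord] <= thresh)))
  manual <- logical(m)
  if (imax > 0) manual[ord[seq_len(imax)]] <- TRUE
  expect_identical(bhAdjust(p), manual)
})

test_that("pairing observations assemble the three tables correctly", {
  tab <- rbind(
    data.frame(brood_id = "b1", season = "dry", mother_id = "F1",
               paired_male_id = "M1", offspring_id = paste0("o", 1:4),
               sire_label = c("WITHIN_PAIR", "EP_1", "EP_1", "EP_2")),
    data.frame(brood_id = "b2", season = "rainy", mother_id = "F2",
               paired_male_id = "M2", offspring_id = paste0("q", 1:2),
               sire_label = c("EP_1", "EP_1")))
  broods <- BroodSet(tab)
  info <- data.frame(sire_id = c("b1_EP_1", "b1_EP_2", "b2_EP_1"),
                     brood_id = c("b1", "b1", "b2"),
                     ep_group = c("EP_1", "EP_2", "EP_1"),
                     n_fry = c(2L, 1L, 2L), n_loci_complete = 14L,
                     n_loci_inconsistent = 0L)
  a1 <- matrix("A", 3, 1, dimnames = list(info$sire_id, "L1"))
  sires <- new("SireReconstruction", genotypes = GenotypeSet(a1, a1),
               info = info)
  obs <- suppressMessages(pairingObservations(broods, sires))
  # brood b2 has zero paternity: its sire drops from the cuckolder tables
  expect_setequal(obs$male_cuckolder$partner_id, c("b1_EP_1", "b1_EP_2"))
  expect_identical(unique(obs$male_cuckolder$focal_id), "M1")
  expect_setequal(obs$female_cuckolder$focal_id, "F1")
  # the within-pair table keeps all social pairs
  expect_setequal(obs$within_pair$focal_id, c("M1", "M2"))
})
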