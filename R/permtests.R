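## Season-stratified randomization tests for elevated relatedness.

#' Mean, variance, and skewness of a distribution of relatedness values
#'
#' Variance uses the n-1 denominator; skewness is the moment-based sample
#' skewness m3 / m2^(3/2) with central moments over n. With zero variance
#' the skewness is undefined and returned as `NA`.
#'
#' @param values numeric vector; at least 2 values for variance, 3 for
#'   skewness.
#' @return named numeric vector `c(mean, variance, skewness)`.
#' @examples
#' momentStats(c(1, 2, 3))   # mean 2, variance 1, skewness 0
#' @export
momentStats <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for the variance statistic")
  if (n < 3L) stop("need at least 3 values for the skewness statistic")
  m <- mean(values)
  v <- stats::var(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  sk <- if (m2 > 0) m3 / m2^1.5 else NA_real_
  c(mean = m, variance = v, skewness = sk)
}

## internal moment computation tolerant of degenerate permutation samples:
## zero-variance skewness counts as 0 rather than NA
.momentsForNull <- function(values) {
  m <- mean(values)
  v <- stats::var(values)
  m2 <- mean((values - m)^2)
  sk <- if (m2 > 0) mean((values - m)^3) / m2^1.5 else 0
  c(m, v, sk)
}

#' Randomization test for elevated relatedness between pairing partners
#'
#' Implements the season-stratified permutation null for three pairing
#' structures: paired male x paired female (`"WITHIN_PAIR"`, one partner
#' per focal) and focal adult x set of cuckolders (`"FOCAL_VS_SET"`). The
#' observed statistic is the mean, variance, and skewness of the per-focal
#' set means of relatedness (for within-pair data the set mean is the
#' single pair value). Each permutation reshuffles the season's pool of
#' partners without replacement, assigning every partner to exactly one
#' focal and preserving the observed per-focal set-size distribution within
#' season; new values are then looked up in the relatedness matrix and the
#' three statistics recomputed.
#'
#' @param obs data.frame with columns `focal_id`, `partner_id`, `season`:
#'   one row per observed (focal, partner) pair.
#' @param rmat relatedness lookup: a numeric matrix whose dimnames cover
#'   all focal and partner ids (e.g. from [relatednessMatrix()]).
#' @param scheme `"FOCAL_VS_SET"` (default) or `"WITHIN_PAIR"`; the latter
#'   requires exactly one partner per focal.
#' @param nPerm number of permutations (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @param alternative `"greater"` (one-sided toward elevation; default) or
#'   `"two.sided"`.
#' @param returnNull keep the per-permutation null statistics?
#' @param checkInvariants verify on every permutation that the partner
#'   multiset and per-focal set sizes are preserved within season (test
#'   mode; default FALSE).
#' @return data.frame with one row per statistic: `statistic`, `observed`,
#'   `null_mean`, `p`, `n_perm`; if `returnNull`, an attribute `"null"`
#'   holds the nPerm x 3 matrix of null statistics. p values use the
#'   add-one correction `(#{null >= observed} + 1) / (nPerm + 1)`, ties
#'   counting as extreme.
#' @export
randomizePairings <- function(obs, rmat,
                              scheme = c("FOCAL_VS_SET", "WITHIN_PAIR"),
                              nPerm = 10000L, seed = NULL,
                              alternative = c("greater", "two.sided"),
                              returnNull = FALSE, checkInvariants = FALSE) {
  scheme <- match.arg(scheme)
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  need <- c("focal_id", "partner_id", "season")
  if (length(setdiff(need, names(obs))))
    stop("obs needs columns focal_id, partner_id, season")
  ri <- match(obs$focal_id, rownames(rmat))
  ci <- match(obs$partner_id, colnames(rmat))
  if (anyNA(ri) || anyNA(ci))
    stop("pair not resolvable in relatedness matrix: ",
         paste(obs$focal_id[is.na(ri)], obs$partner_id[is.na(ci)])[1L])
  vals <- rmat[cbind(ri, ci)]
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("missing relatedness value for pair (%s, %s)",
                 obs$focal_id[bad], obs$partner_id[bad]))
  }
  focal <- factor(paste(obs$season, obs$focal_id, sep = "\r"))
  sizes <- as.vector(table(focal))
  if (scheme == "WITHIN_PAIR" && any(sizes != 1L))
    stop("WITHIN_PAIR scheme requires exactly one partner per focal")
  setMean <- function(v) rowsum(v, focal, reorder = TRUE)[, 1L] / sizes
  observed <- momentStats(setMean(vals))
  ## permutation machinery: shuffle partner columns within season
  strata <- split(seq_len(nrow(obs)), obs$season)
  null <- matrix(NA_real_, nPerm, 3L)
  for (b in seq_len(nPerm)) {
    ci_new <- ci
    for (s in strata) ci_new[s] <- ci[s][sample.int(length(s))]
    if (checkInvariants) {
      for (s in strata)
        if (!identical(sort(ci_new[s]), sort(ci[s])))
          stop("permutation failed to preserve the partner multiset")
    }
    null[b, ] <- .momentsForNull(setMean(rmat[cbind(ri, ci_new)]))
  }
  p <- vapply(1:3, function(j) {
    o <- observed[j]
    if (is.na(o)) return(NA_real_)
    if (alternative == "greater")
      (sum(null[, j] >= o) + 1) / (nPerm + 1)
    else
      (sum(abs(null[, j] - mean(null[, j])) >= abs(o - mean(null[, j]))) + 1) /
        (nPerm + 1)
  }, numeric(1))
  out <- data.frame(statistic = c("mean", "variance", "skewness"),
                    observed = unname(observed),
                    null_mean = colMeans(null),
                    p = p, n_perm = nPerm, stringsAsFactors = FALSE)
  if (returnNull) attr(out, "null") <- null
  out
}

#' Benjamini-Hochberg rejection flags
#'
#' Standard step-up control of the false discovery rate: sort the p values
#' ascending, find the largest i with p(i) <= i q / m, and reject hypotheses
#' 1..i.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @param q target false discovery rate (default 0.10).
#' @return logical vector of rejection flags, aligned with `p`; `NA` p
#'   values yield `NA` flags.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.2, 0.9), q = 0.10)  # TRUE TRUE FALSE FALSE
#' @export
bhAdjust <- function(p, q = 0.10) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

#' Build the pairing observations used by the randomization tests
#'
#' Assembles the three observation tables from a brood set: paired male x
#' cuckolder set, paired female x cuckolder set (both restricted to
#' well-reconstructed cuckolders and to broods where the paired male kept
#' some paternity), and paired male x paired female.
#'
#' @param broods a [BroodSet-class].
#' @param sires a [SireReconstruction-class] (already filtered); its sire
#'   ids name the cuckolder partners.
#' @param dropZeroPaternity apply [excludeZeroPaternity()] before building
#'   the cuckolder tables (default TRUE).
#' @return named list of data.frames (`male_cuckolder`, `female_cuckolder`,
#'   `within_pair`) with columns `focal_id`, `partner_id`, `season`.
#' @export
pairingObservations <- function(broods, sires, dropZeroPaternity = TRUE) {
  stopifnot(is(broods, "BroodSet"), is(sires, "SireReconstruction"))
  kept <- if (dropZeroPaternity) excludeZeroPaternity(broods) else broods
  info <- sireInfo(sires)
  tab <- unique(broodTable(kept)[c("brood_id", "season", "mother_id",
                                   "paired_male_id")])
  m <- merge(info, tab, by = "brood_id")
  male_cuck <- data.frame(focal_id = m$paired_male_id,
                          partner_id = m$sire_id, season = m$season,
                          stringsAsFactors = FALSE)
  female_cuck <- data.frame(focal_id = m$mother_id,
                            partner_id = m$sire_id, season = m$season,
                            stringsAsFactors = FALSE)
  all_pairs <- unique(broodTable(broods)[c("brood_id", "season", "mother_id",
                                           "paired_male_id")])
  within <- data.frame(focal_id = all_pairs$paired_male_id,
                       partner_id = all_pairs$mother_id,
                       season = all_pairs$season, stringsAsFactors = FALSE)
  within <- unique(within[c("focal_id", "partner_id", "season")])
  list(male_cuckolder = male_cuck, female_cuckolder = female_cuck,
       within_pair = within)
}
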