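## Inclusive-fitness game of cuckoldry tolerance.
##
## A paired male faces C ~ Poisson(muC) unrelated potential cuckolders and
## at most one related cuckolder (present with probability f). He can drive
## off D ~ Poisson(muD) of them; discriminating in favour of the relative
## costs defensive capability, reducing the mean to (1 - a) * muD. When
## more cuckolders arrive than can be driven off, paternity of the spawning
## is shared equally in expectation among the paired male and all
## successful cuckolders. Direct fitness is the focal's own expected egg
## share; indirect fitness is the relative's expected share weighted by the
## relatedness coefficient r (a phenotypic form of Hamilton's rule).

#' Construct game parameters
#'
#' @param r relatedness coefficient between the paired male and the related
#'   cuckolder, in \[0, 1\].
#' @param f probability the related cuckolder attempts to cuckold, \[0, 1\].
#' @param muC mean number of unrelated potential cuckolders (Poisson).
#' @param muD mean number of cuckolders the paired male can drive off
#'   (Poisson); reduced to (1 - a) muD under discriminate defense.
#' @param a cost of discriminate defense, 0 <= a < 1.
#' @return A [GameParams-class].
#' @export
GameParams <- function(r, f, muC, muD, a) {
  new("GameParams", r = as.numeric(r), f = as.numeric(f),
      muC = as.numeric(muC), muD = as.numeric(muD), a = as.numeric(a))
}

#' @export
setMethod("show", "GameParams", function(object) {
  cat(sprintf("GameParams: r = %g, f = %g, muC = %g, muD = %g, a = %g\n",
              object@r, object@f, object@muC, object@muD, object@a))
})

## truncation rule: Poisson quantile beyond which the excluded tail mass is
## below 1e-12 (a little margin past the 1e-13 quantile)
.poisTail <- function(mu) if (mu <= 0) 0L else stats::qpois(1 - 1e-13, mu) + 2L

#' Skellam probability mass function
#'
#' The difference C - D of two independent Poisson counts with means
#' `muC` and `muD` follows a Skellam distribution,
#' s_k = exp(-(muC + muD)) (muC/muD)^(k/2) I_k(2 sqrt(muC muD)),
#' where I_k is the modified Bessel function of the first kind. The
#' degenerate limits are handled as signed Poisson pmfs: at muD = 0 the
#' mass is Poisson(muC) on k >= 0, and at muC = 0 it is Poisson(muD) on
#' -k.
#'
#' @param k integer (vector) at which to evaluate the pmf.
#' @param muC,muD nonnegative Poisson means.
#' @return numeric vector of probabilities.
#' @export
skellamPmf <- function(k, muC, muD) {
  if (muC < 0 || muD < 0) stop("Poisson means must be nonnegative")
  if (any(k != round(k))) stop("k must be integer")
  if (muD == 0 && muC == 0) return(as.numeric(k == 0))
  if (muD == 0) return(ifelse(k >= 0, stats::dpois(k, muC), 0))
  if (muC == 0) return(ifelse(k <= 0, stats::dpois(-k, muD), 0))
  x <- 2 * sqrt(muC * muD)
  ## exponentially scaled Bessel keeps this stable for large means; at
  ## extreme orders (far outside the Poisson support, where the mass is
  ## negligible) besselI loses precision, so those entries are recomputed
  ## through the defining Poisson convolution series
  extreme <- abs(k) > .poisTail(muC) + .poisTail(muD)
  out <- rep(NA_real_, length(k))
  if (any(!extreme)) {
    kk <- k[!extreme]
    bi <- besselI(x, abs(kk), expon.scaled = TRUE)
    out[!extreme] <- exp(-(muC + muD) + x + (kk / 2) * log(muC / muD)) * bi
  }
  if (any(extreme)) {
    dmax <- .poisTail(muD)
    out[extreme] <- vapply(k[extreme], function(ki) {
      ds <- max(0L, -ki):(dmax + max(0L, -ki))
      sum(stats::dpois(ds, muD) * stats::dpois(ki + ds, muC))
    }, numeric(1))
  }
  out
}

## support over which the Skellam mass is complete to < 1e-12
.skellamSupport <- function(muC, muD) {
  seq.int(-.poisTail(muD), .poisTail(muC))
}

## shared direct-fitness kernel of the paired male (Eq. 2/3 bracket)
.pairedDirect <- function(f, muC, muDeff) {
  k <- .skellamSupport(muC, muDeff)
  s <- skellamPmf(k, muC, muDeff)
  if (abs(sum(s) - 1) > 1e-9)
    stop("Skellam truncation failed to converge")
  sum(s * ((1 - f) / (1 + pmax(k, 0)) + f / (1 + pmax(k + 1, 0))))
}

## double-Poisson kernel over c >= d (Eqs. 4-7): sum_c p_c(muC)
## sum_{d=0}^{c} p_d(muDeff) * term(c, d)
.doubleSum <- function(muC, muDeff, term) {
  cmax <- max(.poisTail(muC), 1L)
  dmax <- cmax
  cs <- 0:cmax
  ds <- 0:dmax
  pc <- stats::dpois(cs, muC)
  pd <- stats::dpois(ds, muDeff)
  M <- outer(cs, ds, term)
  M[outer(cs, ds, `<`)] <- 0     # only d <= c contributes
  as.numeric(pc %*% M %*% pd)
}

#' Inclusive fitness of the paired male
#'
#' Direct fitness is the paired male's expected share of the spawning's
#' eggs; indirect fitness is the related cuckolder's expected share times
#' r, times the probability f that he attends. Under `"DISCRIMINATE"`
#' defense the male's Poisson defense mean is reduced to (1 - a) muD and
#' the related cuckolder, when present, is always among the successful
#' cuckolders.
#'
#' @param p a [GameParams-class].
#' @param strategy `"INDISCRIMINATE"` or `"DISCRIMINATE"`.
#' @return list with `direct`, `indirect`, `total`.
#' @export
pairedMaleFitness <- function(p, strategy = c("INDISCRIMINATE",
                                              "DISCRIMINATE")) {
  stopifnot(is(p, "GameParams"))
  strategy <- match.arg(strategy)
  muDeff <- if (strategy == "DISCRIMINATE") (1 - p@a) * p@muD else p@muD
  direct <- .pairedDirect(p@f, p@muC, muDeff)
  indirect <- if (strategy == "DISCRIMINATE") {
    ## related male always among the successful subset
    p@f * p@r * .doubleSum(p@muC, muDeff,
                           function(c, d) 1 / (c + 2 - d))
  } else {
    ## related male succeeds with probability (c + 1 - d) / (c + 1)
    p@f * p@r * .doubleSum(p@muC, muDeff,
                           function(c, d) (c + 1 - d) / (c + 1) /
                             (c + 2 - d))
  }
  list(direct = direct, indirect = indirect, total = direct + indirect)
}

#' Inclusive fitness of a cuckolder
#'
#' Evaluated in a population where paired males discriminate in favour of
#' related cuckolders (defense mean (1 - a) muD throughout). Targeting the
#' related paired male guarantees the cuckolder a place among the
#' successful males whenever not all cuckolders can be driven off; his
#' indirect fitness is the related paired male's expected egg share times
#' r.
#'
#' @param p a [GameParams-class].
#' @param target `"RELATED"` or `"UNRELATED"`.
#' @return list with `direct`, `indirect`, `total`.
#' @export
cuckolderFitness <- function(p, target = c("RELATED", "UNRELATED")) {
  stopifnot(is(p, "GameParams"))
  target <- match.arg(target)
  muDeff <- (1 - p@a) * p@muD
  direct <- if (target == "RELATED") {
    .doubleSum(p@muC, muDeff, function(c, d) 1 / (c + 2 - d))
  } else {
    .doubleSum(p@muC, muDeff, function(c, d) (c + 1 - d) / (c + 1) /
                 (c + 2 - d))
  }
  k <- .skellamSupport(p@muC, muDeff)
  s <- skellamPmf(k, p@muC, muDeff)
  indirect <- if (target == "RELATED") {
    ## the relative's nest hosts the focal in addition to the C unrelated
    p@r * sum(s / (1 + pmax(k + 1, 0)))
  } else {
    p@r * sum(s / (1 + pmax(k, 0)))
  }
  list(direct = direct, indirect = indirect, total = direct + indirect)
}

#' Decision map over sperm-competition intensity and defense cost
#'
#' Evaluates, on a (muC, a) grid at fixed r, f, muD, the two adaptiveness
#' inequalities of the game: tolerance (discriminate defense) is adaptive
#' for the paired male when total fitness under `"DISCRIMINATE"` exceeds
#' `"INDISCRIMINATE"`; targeting the relative is adaptive for a cuckolder
#' when total fitness under `"RELATED"` exceeds `"UNRELATED"`.
#'
#' @param r,f,muD fixed game parameters.
#' @param muCGrid,aGrid grid values (defaults 200 points over \[0, 10\] and
#'   \[0, 0.99\]).
#' @return data.frame per grid cell: `muC`, `a`, `tolerate_margin`,
#'   `target_related_margin`, `tolerate_adaptive`, `target_related_adaptive`.
#'   The margins are the total-fitness differences whose sign changes trace
#'   the decision boundaries.
#' @export
decisionMap <- function(r, f = 0.5, muD = 1,
                        muCGrid = seq(0.05, 10, length.out = 200),
                        aGrid = seq(0, 0.99, length.out = 200)) {
  grid <- expand.grid(muC = muCGrid, a = aGrid)
  tol <- tar <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- GameParams(r = r, f = f, muC = grid$muC[i], muD = muD,
                    a = grid$a[i])
    wi <- pairedMaleFitness(p, "INDISCRIMINATE")
    wd <- pairedMaleFitness(p, "DISCRIMINATE")
    cr <- cuckolderFitness(p, "RELATED")
    cu <- cuckolderFitness(p, "UNRELATED")
    tol[i] <- wd$total - wi$total
    tar[i] <- cr$total - cu$total
  }
  data.frame(grid, tolerate_margin = tol, target_related_margin = tar,
             tolerate_adaptive = tol > 0, target_related_adaptive = tar > 0)
}

#' Monte-Carlo simulation of the cuckoldry game
#'
#' Simulates the game draw by draw as an independent oracle for the
#' analytic fitness expressions: C ~ Poisson(muC), D ~ Poisson of the
#' strategy-appropriate mean, related-male presence ~ Bernoulli(f), with
#' the defense and paternity-sharing rules applied verbatim. By default
#' egg shares are deterministic expected shares; `mode = "multinomial"`
#' instead allocates a finite clutch egg by egg, which has the same mean.
#'
#' @param p a [GameParams-class].
#' @param role `"paired"` or `"cuckolder"`.
#' @param strategy for `role = "paired"`: `"INDISCRIMINATE"` or
#'   `"DISCRIMINATE"`; for `role = "cuckolder"`: `"RELATED"` or
#'   `"UNRELATED"` (the target).
#' @param nDraws number of simulated spawning events.
#' @param seed optional integer seed.
#' @param mode `"expected"` (deterministic equal shares) or
#'   `"multinomial"` (per-egg allocation).
#' @param nEggs clutch size for `mode = "multinomial"`.
#' @return list with `direct`, `indirect`, `total` and standard errors
#'   `directSE`, `indirectSE`.
#' @export
monteCarloGame <- function(p, role = c("paired", "cuckolder"),
                           strategy = NULL, nDraws = 1e6, seed = NULL,
                           mode = c("expected", "multinomial"),
                           nEggs = 50L) {
  stopifnot(is(p, "GameParams"))
  role <- match.arg(role)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nDraws)
  if (n < 1L) stop("nDraws must be >= 1")
  eggFrac <- function(share) {
    ## realized egg fraction for one male with expected share `share`
    if (mode == "expected") share
    else stats::rbinom(n, nEggs, share) / nEggs
  }
  C <- stats::rpois(n, p@muC)
  if (role == "paired") {
    strategy <- match.arg(strategy, c("INDISCRIMINATE", "DISCRIMINATE"))
    disc <- strategy == "DISCRIMINATE"
    D <- stats::rpois(n, if (disc) (1 - p@a) * p@muD else p@muD)
    rel <- stats::rbinom(n, 1L, p@f) == 1L
    total_cuck <- C + rel
    n_succ <- pmax(total_cuck - D, 0L)          # successful cuckolders
    direct <- eggFrac(1 / (1 + n_succ))
    ## is the related male among the successful cuckolders?
    rel_succ <- rel & n_succ > 0L
    if (!disc) {
      ## indiscriminate defense removes a uniform subset of cuckolders:
      ## the relative survives with probability n_succ / total_cuck
      keep <- stats::runif(n) < ifelse(total_cuck > 0,
                                       n_succ / pmax(total_cuck, 1L), 0)
      rel_succ <- rel_succ & keep
    }
    rel_share <- ifelse(rel_succ, 1 / (1 + n_succ), 0)
    indirect <- p@r * eggFrac(rel_share)
  } else {
    strategy <- match.arg(strategy, c("RELATED", "UNRELATED"))
    D <- stats::rpois(n, (1 - p@a) * p@muD)     # discriminating population
    if (strategy == "RELATED") {
      ## the focal attends his relative's nest: C + 1 cuckolders in total,
      ## and the tolerant relative never drives the focal off when any
      ## cuckolder gets through (D <= C)
      succ <- pmax(C + 1L - D, 0L)
      direct <- eggFrac(ifelse(D <= C, 1 / (C + 2 - D), 0))
      indirect <- p@r * eggFrac(1 / (1 + succ))
    } else {
      ## focal attends an unrelated nest; his relative's own spawning is an
      ## independent event with no related cuckolder present
      succ <- pmax(C + 1L - D, 0L)
      focal_succ <- succ > 0L &
        stats::runif(n) < succ / (C + 1L)
      direct <- eggFrac(ifelse(focal_succ, 1 / (C + 2 - D), 0))
      C2 <- stats::rpois(n, p@muC)
      D2 <- stats::rpois(n, (1 - p@a) * p@muD)
      indirect <- p@r * eggFrac(1 / (1 + pmax(C2 - D2, 0L)))
    }
  }
  list(direct = mean(direct), indirect = mean(indirect),
       total = mean(direct) + mean(indirect),
       directSE = stats::sd(direct) / sqrt(n),
       indirectSE = stats::sd(indirect) / sqrt(n))
}

#' Fitness increase of a brood due to cuckoldry by relatives
#'
#' The allelic value of a brood with paternity loss `loss` to cuckolders of
#' mean relatedness `rBar` is V = (1 - loss) + loss * rBar; relative to
#' cuckoldry by non-relatives (rBar = 0) the percent increase is
#' 100 * loss * rBar / (1 - loss).
#'
#' @param rBar mean relatedness between the paired male and his cuckolders,
#'   in \[0, 1\].
#' @param paternityLoss fraction of the brood lost to cuckolders, in
#'   \[0, 1).
#' @return percent fitness increase (a single number).
#' @examples
#' broodValueIncrease(0.038, 0.449)  # about 3.1
#' @export
broodValueIncrease <- function(rBar, paternityLoss) {
  if (rBar < 0 || rBar > 1) stop("rBar must lie in [0, 1]")
  if (paternityLoss < 0 || paternityLoss >= 1)
    stop("paternityLoss must lie in [0, 1): a full loss has no baseline")
  100 * paternityLoss * rBar / (1 - paternityLoss)
}
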