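## Tests of whether parent-offspring relatedness deviates from pedigree
## expectation. Under random mating a parent's relatedness to its own
## offspring centres on 0.5; relatedness within the social pair shifts the
## expectation for within-pair fry, and relatedness between the paired male
## and his cuckolders shifts the paired male's relatedness to extra-pair
## fry above the half-pair-relatedness baseline R/2.

#' Build deviation observations for the parent-offspring tests
#'
#' Three kinds of deviation are supported:
#' * `"MALE_WP"`: r(paired male, within-pair fry) - 0.5, grouped by brood;
#' * `"FEMALE_EP"`: r(mother, extra-pair fry) - 0.5, grouped by sire group
#'   nested in brood;
#' * `"MALE_EP"`: r(paired male, extra-pair fry) - R/2, where R is the
#'   relatedness estimate between the paired male and female of that brood
#'   (R may be negative), grouped by sire group nested in brood.
#'
#' Zero-paternity broods are excluded throughout, as in the randomization
#' tests. Fry enter whenever the required pair estimate is computable.
#'
#' @param kind one of `"MALE_WP"`, `"FEMALE_EP"`, `"MALE_EP"`.
#' @param broods a [BroodSet-class].
#' @param x a [GenotypeSet-class] containing adults and offspring.
#' @param freqs an [AlleleFreqTable-class].
#' @param estimator `"QG"` or `"LR"`.
#' @return data.frame: `adult_id`, `offspring_id`, `brood_id`,
#'   `sire_group_id` (NA for `"MALE_WP"`), `estimator`, `expectation`,
#'   `deviation`. Pairs with undefined estimates are dropped with a message.
#' @export
buildDeviations <- function(kind = c("MALE_WP", "FEMALE_EP", "MALE_EP"),
                            broods, x, freqs, estimator = c("QG", "LR")) {
  kind <- match.arg(kind)
  estimator <- match.arg(estimator)
  kept <- excludeZeroPaternity(broods)
  tab <- broodTable(kept)
  if (kind == "MALE_WP") {
    tab <- tab[tab$sire_label == "WITHIN_PAIR", , drop = FALSE]
    adult <- tab$paired_male_id
  } else {
    tab <- tab[tab$sire_label != "WITHIN_PAIR", , drop = FALSE]
    adult <- if (kind == "FEMALE_EP") tab$mother_id else tab$paired_male_id
  }
  if (nrow(tab) == 0L) stop("no offspring of the requested kind")
  pr <- relatednessPairs(x, freqs, cbind(adult, tab$offspring_id), estimator)
  if (kind == "MALE_EP") {
    pairs <- unique(tab[c("brood_id", "paired_male_id", "mother_id")])
    Rp <- relatednessPairs(x, freqs,
                           cbind(pairs$paired_male_id, pairs$mother_id),
                           estimator)
    if (anyNA(Rp$value))
      stop("missing within-pair relatedness R for brood ",
           pairs$brood_id[is.na(Rp$value)][1L])
    expectation <- Rp$value[match(tab$brood_id, pairs$brood_id)] / 2
  } else {
    expectation <- rep(0.5, nrow(tab))
  }
  keep <- !is.na(pr$value)
  if (any(!keep))
    message(sum(!keep), " adult-offspring pairs dropped (undefined estimate)")
  data.frame(adult_id = adult[keep],
             offspring_id = tab$offspring_id[keep],
             brood_id = tab$brood_id[keep],
             sire_group_id = if (kind == "MALE_WP") NA_character_
                             else paste(tab$brood_id, tab$sire_label,
                                        sep = "_")[keep],
             estimator = estimator,
             expectation = expectation[keep],
             deviation = pr$value[keep] - expectation[keep],
             stringsAsFactors = FALSE)
}

#' Intercept-only mixed-model test on deviations
#'
#' Fits an intercept-only linear mixed model to the deviations by REML,
#' with a random intercept for brood (`grouping = "brood"`) or for sire
#' group nested in brood (`grouping = "sire-in-brood"`), and reports the
#' Wald t test of the intercept. The t degrees of freedom follow the
#' residual-style convention df = n - 1 (documented as approximate). When
#' the fit is singular (zero group variance), the function falls back to an
#' intercept-only model with cluster-robust standard errors over the
#' top-level grouping and flags the result.
#'
#' @param devs data.frame from [buildDeviations()].
#' @param grouping `"brood"` or `"sire-in-brood"`.
#' @return data.frame with `estimate`, `se`, `t`, `df`, `p` (two-sided),
#'   and `robust` (TRUE when the cluster-robust fallback was used).
#' @export
interceptTest <- function(devs, grouping = c("brood", "sire-in-brood")) {
  grouping <- match.arg(grouping)
  y <- devs$deviation
  n <- length(y)
  if (n < 3L || length(unique(devs$brood_id)) < 2L)
    stop("need at least 3 observations in at least 2 groups")
  dat <- data.frame(y = y, brood = devs$brood_id,
                    sire = if (grouping == "sire-in-brood")
                      devs$sire_group_id else devs$brood_id)
  form <- if (grouping == "brood") y ~ 1 + (1 | brood)
          else y ~ 1 + (1 | brood) + (1 | sire)
  fit <- suppressMessages(suppressWarnings(
    try(lme4::lmer(form, data = dat, REML = TRUE), silent = TRUE)))
  singular <- inherits(fit, "try-error") || lme4::isSingular(fit, tol = 1e-5)
  cf <- if (!singular)
    suppressWarnings(try(summary(fit)$coefficients, silent = TRUE)) else NULL
  if (!singular && !inherits(cf, "try-error") &&
      is.finite(cf[1L, "Std. Error"])) {
    est <- cf[1L, "Estimate"]; se <- cf[1L, "Std. Error"]
    robust <- FALSE
  } else {
    ## zero group variance: grand mean with cluster-robust (CR1) SE
    est <- mean(y)
    g <- factor(dat$brood)
    u <- tapply(y - est, g, sum)
    G <- nlevels(g)
    se <- sqrt(G / (G - 1) * sum(u^2)) / n
    robust <- TRUE
  }
  df <- n - 1L
  tval <- if (se > 0) est / se else 0
  p <- if (se > 0) 2 * stats::pt(-abs(tval), df) else as.numeric(est == 0)
  data.frame(estimate = est, se = se, t = tval, df = df, p = p,
             robust = robust)
}
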