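## Pairwise relatedness estimators.
##
## Both estimators are symmetrized by averaging the two directional
## (reference-choice) multilocus estimates, and both accumulate numerator
## and denominator across loci before dividing (ratio-of-sums), which keeps
## them close to unbiased at the marker polymorphism typical of
## microsatellite panels. Loci with an unknown allele in either individual
## are skipped; skipping never perturbs the contribution of other loci.

## Vectorized core over parallel index vectors ia (into ga) and ib (into gb).
## Returns value, n_loci_used and a failure reason per pair.
.relCore <- function(ga, gb, ia, ib, freqs, estimator) {
  loci <- intersect(intersect(lociIds(ga), lociIds(gb)), lociIds(freqs))
  if (length(loci) == 0L) stop("no loci shared by genotypes and frequency table")
  n <- length(ia)
  qg <- estimator == "QG"
  num_ab <- den_ab <- num_ba <- den_ba <- numeric(n) # QG accumulators
  swr_a <- sw_a <- swr_b <- sw_b <- numeric(n)       # LR accumulators
  n_used <- integer(n)
  for (l in loci) {
    ax <- ga@allele1[ia, l]; ay <- ga@allele2[ia, l]
    bx <- gb@allele1[ib, l]; by <- gb@allele2[ib, l]
    ok <- !(is.na(ax) | is.na(ay) | is.na(bx) | is.na(by))
    if (!any(ok)) next
    fl <- freqs@freqs[[l]]
    p_ax <- unname(fl[ax]); p_ay <- unname(fl[ay])
    p_bx <- unname(fl[bx]); p_by <- unname(fl[by])
    if (any(ok & (is.na(p_ax) | is.na(p_ay) | is.na(p_bx) | is.na(p_by))))
      stop("allele observed at locus ", l, " is absent from the frequency table")
    n_used <- n_used + ok
    if (qg) {
      ## within-individual allele frequencies P_i(x) in {0, 0.5, 1}
      Pb_ax <- ((bx == ax) + (by == ax)) / 2
      Pb_ay <- ((bx == ay) + (by == ay)) / 2
      Pa_bx <- ((ax == bx) + (ay == bx)) / 2
      Pa_by <- ((ax == by) + (ay == by)) / 2
      ## note P_a(ax) = P_a(ay) = (1 + [ax == ay]) / 2, likewise for b
      Pa_own <- (1 + (ax == ay)) / 2
      Pb_own <- (1 + (bx == by)) / 2
      add <- function(acc, contrib) {
        contrib[!ok] <- 0            # masked loci must not contribute
        acc + contrib
      }
      num_ab <- add(num_ab, Pb_ax - p_ax + Pb_ay - p_ay)
      den_ab <- add(den_ab, Pa_own - p_ax + Pa_own - p_ay)
      num_ba <- add(num_ba, Pa_bx - p_bx + Pa_by - p_by)
      den_ba <- add(den_ba, Pb_own - p_bx + Pb_own - p_by)
    } else {
      ## Lynch-Ritland, reference a then reference b
      acc <- function(px, py, x, y, u, v) {
        Sxy <- (x == y)
        num <- px * ((y == u) + (y == v)) + py * ((x == u) + (x == v)) -
          4 * px * py
        den <- (1 + Sxy) * (px + py) - 4 * px * py
        wt <- den / (2 * px * py)
        valid <- ok & is.finite(wt) & den > 1e-12
        list(swr = ifelse(valid, num / (2 * px * py), 0),
             sw = ifelse(valid, wt, 0))
      }
      ra <- acc(p_ax, p_ay, ax, ay, bx, by)
      rb <- acc(p_bx, p_by, bx, by, ax, ay)
      swr_a <- swr_a + ra$swr; sw_a <- sw_a + ra$sw
      swr_b <- swr_b + rb$swr; sw_b <- sw_b + rb$sw
    }
  }
  if (qg) {
    r_ab <- ifelse(den_ab != 0, num_ab / den_ab, NA_real_)
    r_ba <- ifelse(den_ba != 0, num_ba / den_ba, NA_real_)
  } else {
    r_ab <- ifelse(sw_a > 0, swr_a / sw_a, NA_real_)
    r_ba <- ifelse(sw_b > 0, swr_b / sw_b, NA_real_)
  }
  ## symmetric estimate: mean of the two directions; a direction with a
  ## degenerate denominator is dropped, both degenerate -> undefined
  both <- !is.na(r_ab) & !is.na(r_ba)
  value <- ifelse(both, (r_ab + r_ba) / 2, ifelse(is.na(r_ab), r_ba, r_ab))
  reason <- rep(NA_character_, n)
  reason[n_used == 0L] <- "no usable loci"
  reason[n_used > 0L & is.na(value)] <- "degenerate denominator"
  value[n_used == 0L] <- NA_real_
  data.frame(value = value, n_loci_used = n_used, reason = reason,
             stringsAsFactors = FALSE)
}

.relPairsIdx <- function(ga, gb, ia, ib, freqs, estimator) {
  estimator <- match.arg(estimator, c("QG", "LR"))
  .relCore(ga, gb, ia, ib, freqs, estimator)
}

#' Pairwise relatedness for a list of pairs
#'
#' Computes the symmetric Queller-Goodnight (`"QG"`) or Lynch-Ritland
#' (`"LR"`) relatedness estimate for each requested pair of individuals.
#' Estimates are dimensionless; they centre on 0 for unrelated pairs, 0.25
#' for half sibs and 0.5 for parent-offspring or full-sib pairs, and can be
#' negative in finite samples. Loci with an unknown allele in either member
#' are skipped. Pairs whose estimate is undefined (no usable loci, or
#' degenerate denominators in both directions) get `NA` with a reason.
#'
#' @param x a [GenotypeSet-class] containing all individuals referenced.
#' @param freqs an [AlleleFreqTable-class]; every observed allele must be
#'   present (frequencies are fixed inputs, no leave-pair-out re-estimation).
#' @param pairs two-column matrix or data.frame of individual ids.
#' @param estimator `"QG"` or `"LR"`.
#' @param minLoci minimum usable loci required per pair (default 1); pairs
#'   below it get `NA` with reason `"below minLoci"`.
#' @return data.frame: `id_a`, `id_b`, `estimator`, `value`, `n_loci_used`,
#'   `reason` (NA when the estimate is defined).
#' @export
relatednessPairs <- function(x, freqs, pairs, estimator = c("QG", "LR"),
                             minLoci = 1L) {
  estimator <- match.arg(estimator)
  pairs <- as.matrix(pairs)
  ids <- individualIds(x)
  ia <- match(pairs[, 1L], ids)
  ib <- match(pairs[, 2L], ids)
  if (anyNA(ia) || anyNA(ib))
    stop("unknown individual id: ",
         c(pairs[, 1L][is.na(ia)], pairs[, 2L][is.na(ib)])[1L])
  res <- .relCore(x, x, ia, ib, freqs, estimator)
  low <- !is.na(res$value) & res$n_loci_used < minLoci
  res$value[low] <- NA_real_
  res$reason[low] <- "below minLoci"
  data.frame(id_a = pairs[, 1L], id_b = pairs[, 2L], estimator = estimator,
             res, stringsAsFactors = FALSE)
}

#' Single-pair relatedness estimates
#'
#' Thin wrappers over [relatednessPairs()] for one pair; they raise an error
#' when the estimate is undefined.
#'
#' @inheritParams relatednessPairs
#' @param idA,idB individual ids.
#' @return list with `value` and `nLociUsed`.
#' @export
rQG <- function(x, freqs, idA, idB) {
  res <- relatednessPairs(x, freqs, cbind(idA, idB), "QG")
  if (is.na(res$value)) stop("undefined QG estimate: ", res$reason)
  list(value = res$value, nLociUsed = res$n_loci_used)
}

#' @rdname rQG
#' @export
rLR <- function(x, freqs, idA, idB) {
  res <- relatednessPairs(x, freqs, cbind(idA, idB), "LR")
  if (is.na(res$value)) stop("undefined LR estimate: ", res$reason)
  list(value = res$value, nLociUsed = res$n_loci_used)
}

#' Relatedness matrix
#'
#' Computes all pairwise estimates among `rows` x `cols` individuals. When
#' `rows` and `cols` coincide the result is symmetric with an undefined
#' (`NA`) diagonal: self-relatedness is not a meaningful estimate here.
#' Failed pairs are recorded, not raised.
#'
#' @inheritParams relatednessPairs
#' @param rows,cols individual ids; default all individuals of `x`.
#' @return numeric matrix with `dimnames = list(rows, cols)`; attribute
#'   `"failed"` holds a data.frame of undefined pairs and reasons.
#' @export
relatednessMatrix <- function(x, freqs, estimator = c("QG", "LR"),
                              rows = individualIds(x), cols = rows,
                              minLoci = 1L) {
  estimator <- match.arg(estimator)
  if (length(rows) < 2L && identical(rows, cols))
    stop("need at least 2 individuals")
  symmetric <- identical(rows, cols)
  if (symmetric) {
    idx <- which(upper.tri(matrix(0, length(rows), length(cols))), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(seq_along(rows), seq_along(cols)))
  }
  pr <- relatednessPairs(x, freqs, cbind(rows[idx[, 1L]], cols[idx[, 2L]]),
                         estimator, minLoci = minLoci)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[idx] <- pr$value
  if (symmetric) m[idx[, c(2L, 1L)]] <- pr$value
  failed <- pr[!is.na(pr$reason), c("id_a", "id_b", "reason")]
  rownames(failed) <- NULL
  attr(m, "failed") <- failed
  m
}
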