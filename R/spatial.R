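## Spatial kin-structure analyses: the delta-r radius-sweep permutation
## test for unpaired males versus paired males, and Mantel tests of
## distance versus relatedness among paired males.

## Euclidean distances between territory centres (2-D, metres)
.territoryDist <- function(tt) {
  d <- as.matrix(stats::dist(cbind(tt$x_m, tt$y_m)))
  dimnames(d) <- list(tt$territory_id, tt$territory_id)
  d
}

## internal: delta-r per unpaired male given an anchor assignment
## anchor: named character vector unpaired_male_id -> territory_id
.deltaRDetail <- function(anchor, tdist, tt, rmat, radius) {
  paired <- tt$paired_male_id[!is.na(tt$paired_male_id) &
                              tt$paired_male_id != ""]
  ter_of <- stats::setNames(tt$territory_id,
                            tt$paired_male_id)[paired]
  males <- names(anchor)
  out <- data.frame(unpaired_male_id = males, delta_r = NA_real_,
                    n_within = 0L, n_beyond = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(males)) {
    d <- tdist[anchor[males[i]], ter_of]
    r <- rmat[males[i], paired]
    within <- d <= radius
    ok <- !is.na(r)
    nw <- sum(within & ok); nb <- sum(!within & ok)
    out$n_within[i] <- nw; out$n_beyond[i] <- nb
    if (nw > 0L && nb > 0L)
      out$delta_r[i] <- max(r[within & ok]) - max(r[!within & ok])
  }
  out
}

#' The delta-r statistic at one radius
#'
#' For each unpaired male, delta-r is the maximum relatedness estimate to
#' the paired males whose territories lie within the given radius of his
#' anchor territory, minus the maximum relatedness to the paired males
#' beyond it. Distances are 2-D Euclidean between territory centres;
#' "within" is a closed ball (distance <= radius). The test statistic is
#' the mean of delta-r over the unpaired males for which both sides are
#' non-empty; males with an empty side are excluded and counted.
#'
#' @param map a [TerritoryMap-class]; every unpaired male must be anchored.
#' @param rmat relatedness lookup matrix with unpaired males in rows and
#'   paired males in columns (dimnames used; a full symmetric matrix works).
#' @param radius radius in metres.
#' @return list with `statistic` (mean delta-r), `nUsed`, and `detail`
#'   (per-male data.frame).
#' @export
deltaR <- function(map, rmat, radius) {
  stopifnot(is(map, "TerritoryMap"))
  tt <- territories(map)
  an <- anchors(map)
  if (nrow(an) == 0L) stop("no unpaired males anchored")
  tdist <- .territoryDist(tt)
  anchor <- stats::setNames(an$territory_id, an$unpaired_male_id)
  detail <- .deltaRDetail(anchor, tdist, tt, rmat, radius)
  used <- !is.na(detail$delta_r)
  if (!any(used))
    stop("all unpaired males have an empty within- or beyond-set at radius ",
         radius, " m; try another radius")
  list(statistic = mean(detail$delta_r[used]), nUsed = sum(used),
       detail = detail)
}

#' Radius sweep of the delta-r permutation test
#'
#' Computes the observed delta-r statistic at each radius, then builds its
#' permutation null by randomly re-anchoring the unpaired males to
#' territories under the capacity rule: a territory can receive up to one
#' unpaired male if none was originally captured next to it, or up to the
#' number originally captured there. p values are one-sided toward large
#' delta-r with the add-one correction, and Benjamini-Hochberg flags are
#' attached across radii.
#'
#' @inheritParams deltaR
#' @param radii radii in metres (default 1..10).
#' @param nPerm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @param q false discovery rate for the radius-wise flags (default 0.10).
#' @param checkCapacity verify the capacity rule on every permutation
#'   (test mode; default FALSE).
#' @return data.frame: `radius`, `observed_delta_r`, `n_unpaired_used`,
#'   `p`, `bh_reject`.
#' @export
deltaRSweep <- function(map, rmat, radii = 1:10, nPerm = 10000L,
                        seed = NULL, q = 0.10, checkCapacity = FALSE) {
  stopifnot(is(map, "TerritoryMap"))
  if (!is.null(seed)) set.seed(seed)
  tt <- territories(map)
  an <- anchors(map)
  tdist <- .territoryDist(tt)
  males <- an$unpaired_male_id
  obs_anchor <- stats::setNames(an$territory_id, males)
  counts <- anchorCounts(map)
  capacity <- stats::setNames(pmax(1L, counts), names(counts))
  if (sum(capacity) < length(males)) stop("infeasible capacity assignment")
  slots <- rep(names(capacity), capacity)
  observed <- vapply(radii, function(rr)
    deltaR(map, rmat, rr)$statistic, numeric(1))
  n_used <- vapply(radii, function(rr)
    deltaR(map, rmat, rr)$nUsed, numeric(1))
  ## precomputations for the permutation loop: relatedness rows per male,
  ## and per-territory within-radius masks over the paired males
  paired <- tt$paired_male_id[!is.na(tt$paired_male_id) &
                              tt$paired_male_id != ""]
  ter_of <- stats::setNames(tt$territory_id, tt$paired_male_id)[paired]
  R <- rmat[males, paired, drop = FALSE]
  masks <- lapply(tt$territory_id, function(t)
    outer(tdist[t, ter_of], radii, `<=`))
  names(masks) <- tt$territory_id
  exceed <- integer(length(radii))
  nm <- length(males)
  for (b in seq_len(nPerm)) {
    anchor <- sample(slots, nm)
    if (checkCapacity) {
      got <- table(anchor)
      if (any(got > capacity[names(got)]))
        stop("permutation violated the capacity rule")
    }
    acc <- matrix(0, 2L, length(radii))  # row 1: sum of delta-r, row 2: n used
    for (i in seq_len(nm)) {
      v <- R[i, ]
      M <- masks[[anchor[i]]]
      ok <- !is.na(v)
      for (j in seq_along(radii)) {
        w <- M[, j] & ok
        bset <- !M[, j] & ok
        if (any(w) && any(bset)) {
          acc[1L, j] <- acc[1L, j] + (max(v[w]) - max(v[bset]))
          acc[2L, j] <- acc[2L, j] + 1
        }
      }
    }
    stat <- acc[1L, ] / acc[2L, ]
    exceed <- exceed + (!is.na(stat) & stat >= observed)
  }
  p <- (exceed + 1) / (nPerm + 1)
  data.frame(radius = radii, observed_delta_r = observed,
             n_unpaired_used = as.integer(n_used), p = p,
             bh_reject = bhAdjust(p, q))
}

#' Mantel test of distance against relatedness
#'
#' Pearson correlation of the off-diagonal upper triangles of two square
#' symmetric matrices, with significance from simultaneous row/column
#' permutations of one matrix (delegated to \pkg{vegan}). The p value is
#' one-sided toward positive association with the add-one correction.
#'
#' @param distMat square symmetric distance matrix.
#' @param relMat square symmetric relatedness matrix with the same ordering.
#' @param nPerm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @return list with `mantelR` and `p`.
#' @export
mantelTest <- function(distMat, relMat, nPerm = 10000L, seed = NULL) {
  distMat <- as.matrix(distMat); relMat <- as.matrix(relMat)
  if (!identical(dim(distMat), dim(relMat)))
    stop("matrix shape mismatch")
  if (nrow(distMat) < 4L) stop("need at least 4 individuals")
  if (!is.null(seed)) set.seed(seed)
  diag(relMat) <- 0     # vegan requires a complete dissimilarity structure
  fit <- vegan::mantel(stats::as.dist(distMat), stats::as.dist(relMat),
                       method = "pearson", permutations = nPerm)
  list(mantelR = unname(fit$statistic), p = fit$signif)
}
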