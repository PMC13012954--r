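# Post-classification dynamics statistics: IQR outlier filtering,
# stage-percentage time courses, temporal integrals and timing metrics,
# compositional CLR / PERMANOVA analysis, and method-agreement statistics.

#' IQR outlier filter
#'
#' Removes values outside the Tukey fences [Q1 - k*IQR, Q3 + k*IQR],
#' computed per group. Groups with fewer than 4 values are passed through
#' unfiltered with a warning. Quartiles are the default (type 7) sample
#' quantiles.
#'
#' @param values numeric vector
#' @param groups optional grouping vector (e.g. interaction of treatment,
#'   timepoint and class); NULL treats all values as one group
#' @param k fence multiplier (default 1.5)
#' @param wells optional well id per value, to report removal fractions per
#'   well
#' @return list: \code{keep} (logical per value), \code{log} (per-group
#'   data.frame: group, n, n_removed, lower, upper),
#'   \code{removalByWell} (data.frame or NULL)
#' @export
iqrFilter <- function(values, groups = NULL, k = 1.5, wells = NULL) {
  stopifnot(is.numeric(values), k >= 0)
  g <- if (is.null(groups)) rep("all", length(values)) else as.character(groups)
  stopifnot(length(g) == length(values))
  keep <- rep(TRUE, length(values))
  logRows <- list()
  for (gr in unique(g)) {
    ix <- which(g == gr)
    v <- values[ix]
    ok <- is.finite(v)
    if (sum(ok) < 4L) {
      warning("group '", gr, "' has fewer than 4 values; passed unfiltered")
      logRows[[gr]] <- data.frame(group = gr, n = length(ix), n_removed = 0L,
                                  lower = NA_real_, upper = NA_real_)
      next
    }
    q <- stats::quantile(v[ok], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - k * iqr
    hi <- q[2] + k * iqr
    bad <- ok & (v < lo | v > hi)
    keep[ix[bad]] <- FALSE
    logRows[[gr]] <- data.frame(group = gr, n = length(ix),
                                n_removed = sum(bad), lower = lo, upper = hi)
  }
  log <- do.call(rbind, logRows)
  rownames(log) <- NULL
  removalByWell <- NULL
  if (!is.null(wells)) {
    removalByWell <- do.call(rbind, lapply(split(seq_along(keep), wells),
      function(ix) data.frame(well = wells[ix[1]], n = length(ix),
                              n_removed = sum(!keep[ix]),
                              fraction_removed = mean(!keep[ix]))))
    rownames(removalByWell) <- NULL
  }
  list(keep = keep, log = log, removalByWell = removalByWell)
}

#' Temporal integral (trapezoidal area under a stage time course)
#'
#' @param t timepoints (hours), strictly increasing
#' @param y stage percentage at each timepoint
#' @return TI in percent x hour
#' @export
temporalIntegral <- function(t, y) {
  stopifnot(length(t) == length(y))
  if (length(t) < 2L)
    stop("temporal integral needs at least two timepoints", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("timepoints must be strictly increasing", call. = FALSE)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Timing metrics of a stage time course
#'
#' onset10 / t50 are the earliest linearly interpolated times the trace
#' first reaches 10% / 50% of its own maximum; the centroid is the
#' intensity-weighted mean time sum(t*y)/sum(y). An all-zero (or
#' non-positive-maximum) trace has no defined timing: all three are NA.
#'
#' @param t timepoints (hours), strictly increasing
#' @param y trace values
#' @return list: onset10, t50, centroid (hours)
#' @export
timingMetrics <- function(t, y) {
  stopifnot(length(t) == length(y))
  if (any(diff(t) <= 0))
    stop("timepoints must be strictly increasing", call. = FALSE)
  m <- max(y)
  if (!is.finite(m) || m <= 0)
    return(list(onset10 = NA_real_, t50 = NA_real_, centroid = NA_real_))
  list(onset10 = firstCrossing(t, y, 0.10 * m),
       t50 = firstCrossing(t, y, 0.50 * m),
       centroid = sum(t * y) / sum(y))
}

firstCrossing <- function(t, y, th) {
  i <- which(y >= th)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t[1])
  t[i - 1] + (th - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' Centered log-ratio composition vector
#'
#' Adds the pseudocount to the per-stage temporal integrals (spread,
#' disintegrated, netosis) and applies the CLR transform
#' ln(x) - mean(ln(x)); components sum to zero.
#'
#' @param ti nonnegative numeric vector (named or not)
#' @param pseudocount positive constant added before the log (default 0.5)
#' @return CLR vector (sum 0)
#' @export
clrCompose <- function(ti, pseudocount = 0.5) {
  stopifnot(all(ti >= 0), pseudocount > 0)
  lx <- log(ti + pseudocount)
  lx - mean(lx)
}

#' PERMANOVA on Euclidean distances
#'
#' Permutation multivariate ANOVA of the rows of \code{x} (e.g. CLR
#' composition vectors) against a grouping factor, using the pseudo-F from
#' the Euclidean distance-matrix partition. The p-value uses the
#' add-one convention p = (1 + #\{F* >= F\}) / (1 + nPerm), so the minimum
#' attainable p is 1/(nPerm+1). With \code{pairwise = TRUE} every pair of
#' groups is also tested and the pairwise p-values adjusted.
#'
#' @param x numeric matrix, one row per replicate
#' @param groups group label per row
#' @param nPerm number of permutations (default 999)
#' @param seed integer seed
#' @param pairwise also run all pairwise two-group tests
#' @param adjust p-adjustment method for the pairwise table
#' @return list: F, p, nPerm, df (degrees of freedom), and optionally
#'   \code{pairwise} (data.frame)
#' @export
permanova <- function(x, groups, nPerm = 999L, seed = 1L,
                      pairwise = FALSE, adjust = "holm") {
  x <- as.matrix(x)
  g <- factor(groups)
  stopifnot(nrow(x) == length(g))
  tab <- table(g)
  if (nlevels(g) < 2L || any(tab < 2L))
    stop("PERMANOVA needs >= 2 groups with >= 2 members each", call. = FALSE)
  set.seed(seed)
  res <- permanovaCore(x, g, nPerm)
  out <- list(F = res$F, p = res$p, nPerm = nPerm,
              df = c(among = nlevels(g) - 1L, within = nrow(x) - nlevels(g)))
  if (pairwise) {
    prs <- utils::combn(levels(g), 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(prs, function(pr) {
      sel <- g %in% pr
      r <- permanovaCore(x[sel, , drop = FALSE], droplevels(g[sel]), nPerm)
      data.frame(group_a = pr[1], group_b = pr[2], F = r$F, p = r$p)
    }))
    pw$p_adjusted <- stats::p.adjust(pw$p, adjust)
    out$pairwise <- pw
  }
  out
}

# Pseudo-F and permutation p from squared Euclidean distances.
# SST = sum of all squared pairwise distances / n; SSW = the analogous
# within-group sums; F = (SSA/(a-1)) / (SSW/(n-a)). Permuting group labels
# only re-partitions the fixed distance matrix.
permanovaCore <- function(x, g, nPerm) {
  n <- nrow(x)
  a <- nlevels(g)
  D2 <- as.matrix(stats::dist(x))^2
  sst <- sum(D2) / (2 * n)
  ssw <- function(idx) {
    s <- 0
    for (ix in split(seq_len(n), idx))
      s <- s + sum(D2[ix, ix]) / (2 * length(ix))
    s
  }
  statF <- function(idx) {
    w <- ssw(idx)
    ((sst - w) / (a - 1)) / (w / (n - a))
  }
  f0 <- statF(g)
  ge <- sum(vapply(seq_len(nPerm),
                   function(i) statF(g[sample.int(n)]) >= f0 - 1e-12,
                   logical(1)))
  list(F = f0, p = (1 + ge) / (1 + nPerm))
}

#' Per-component contribution to a compositional difference
#'
#' Contribution_i = (dCLR_i)^2 / sum_j (dCLR_j)^2 x 100, where dCLR is the
#' difference between the group centroids; contributions sum to 100.
#' A zero centroid difference leaves the decomposition undefined (all NA).
#'
#' @param a matrix of CLR vectors for group A (rows = replicates)
#' @param b matrix of CLR vectors for group B
#' @return named numeric vector of percentages
#' @export
clrContribution <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  d <- colMeans(a) - colMeans(b)
  s <- sum(d^2)
  if (s == 0) return(stats::setNames(rep(NA_real_, length(d)), colnames(a)))
  stats::setNames(100 * d^2 / s, colnames(a))
}

#' Agreement statistics between two quantification methods
#'
#' For paired count vectors: ICC(2,1) absolute agreement and ICC(3,1)
#' consistency from the two-way ANOVA decomposition of the n x 2 rating
#' matrix, Lin's concordance correlation coefficient, Bland-Altman bias and
#' 95% limits of agreement, Spearman correlation, MAE/RMSE and the
#' rank-biserial correlation from the paired signed-rank statistic.
#'
#' @param x counts by method 1
#' @param y counts by method 2 (paired)
#' @return list of statistics
#' @export
agreementStats <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  M <- cbind(x, y)
  k <- 2L
  rowM <- rowMeans(M); colM <- colMeans(M); grand <- mean(M)
  msr <- k * sum((rowM - grand)^2) / (n - 1)
  msc <- n * sum((colM - grand)^2) / (k - 1)
  sse <- sum((M - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0 && msc == 0 && mse == 0) {
    icc2 <- icc3 <- NA_real_
  } else {
    icc2 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    icc3 <- (msr - mse) / (msr + (k - 1) * mse)
  }
  sx2 <- stats::var(x); sy2 <- stats::var(y)
  sxy <- stats::cov(x, y)
  ccc <- 2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
  d <- x - y
  bias <- mean(d)
  loa <- bias + c(-1, 1) * 1.96 * stats::sd(d)
  nz <- d[d != 0]
  rb <- if (length(nz) == 0L) NA_real_ else {
    r <- rank(abs(nz))
    (sum(r[nz > 0]) - sum(r[nz < 0])) / sum(r)
  }
  list(icc2 = icc2, icc3 = icc3, lin_ccc = ccc,
       bias = bias, loa_lower = loa[1], loa_upper = loa[2],
       spearman_r = suppressWarnings(
         stats::cor(x, y, method = "spearman")),
       mae = mean(abs(d)), rmse = sqrt(mean(d^2)), rank_biserial = rb)
}

#' Build stage time courses and temporal-integral summaries from HitTables
#'
#' Per-image stage counts are normalised to percentages of the image's total
#' cell count, IQR-filtered per (treatment, timepoint, stage), averaged
#' across fields of view per well, then summarised as the median across
#' wells per treatment. Temporal integrals are computed per well (replicate)
#' and per stage, and summarised by the treatment median. Wells missing
#' timepoints of the common grid keep their trace with gaps; their TI uses
#' the available points, with a warning.
#'
#' @param hits HitTable data.frame with columns plate, well, field,
#'   hours_elapsed, treatment, the five stage counts and total
#' @param k IQR fence multiplier
#' @return list: \code{perImage} (percentages), \code{perWell} (FOV means),
#'   \code{perTreatment} (median traces), \code{tiPerWell},
#'   \code{tiMedian}, \code{removalByWell}
#' @export
buildTimecourses <- function(hits, k = 1.5) {
  lv <- stageLevels()
  need <- c("well", "field", "hours_elapsed", "treatment", lv, "total")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("HitTable is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  long <- do.call(rbind, lapply(lv, function(st) {
    data.frame(well = hits$well, field = hits$field,
               hours_elapsed = hits$hours_elapsed,
               treatment = hits$treatment, stage = st,
               pct = ifelse(hits$total > 0, 100 * hits[[st]] / hits$total, 0))
  }))
  grp <- interaction(long$treatment, long$hours_elapsed, long$stage,
                     drop = TRUE)
  filt <- suppressWarnings(
    iqrFilter(long$pct, groups = grp, k = k, wells = long$well))
  long$kept <- filt$keep
  keptLong <- long[long$kept, , drop = FALSE]
  perWell <- stats::aggregate(
    pct ~ treatment + well + hours_elapsed + stage, data = keptLong,
    FUN = mean)
  perTreatment <- stats::aggregate(
    pct ~ treatment + hours_elapsed + stage, data = perWell,
    FUN = stats::median)
  names(perTreatment)[names(perTreatment) == "pct"] <- "median_pct"
  fullGrid <- sort(unique(perWell$hours_elapsed))
  tiPerWell <- do.call(rbind, lapply(
    split(perWell, list(perWell$treatment, perWell$well, perWell$stage),
          drop = TRUE),
    function(d) {
      d <- d[order(d$hours_elapsed), , drop = FALSE]
      if (nrow(d) < 2L) return(NULL)
      if (nrow(d) < length(fullGrid))
        warning("well ", d$well[1], " stage ", d$stage[1],
                ": TI computed on ", nrow(d), "/", length(fullGrid),
                " timepoints")
      tm <- timingMetrics(d$hours_elapsed, d$pct)
      data.frame(treatment = d$treatment[1], well = d$well[1],
                 stage = d$stage[1],
                 ti = temporalIntegral(d$hours_elapsed, d$pct),
                 onset10 = tm$onset10, t50 = tm$t50, centroid = tm$centroid)
    }))
  rownames(tiPerWell) <- NULL
  tiMedian <- stats::aggregate(ti ~ treatment + stage, data = tiPerWell,
                               FUN = stats::median)
  names(tiMedian)[names(tiMedian) == "ti"] <- "median_ti"
  list(perImage = long, perWell = perWell, perTreatment = perTreatment,
       tiPerWell = tiPerWell, tiMedian = tiMedian,
       removalByWell = filt$removalByWell)
}

#' CLR composition matrix per replicate well
#'
#' Builds the 3-component (spread, disintegrated, netosis) CLR composition
#' vector of each well from its per-stage temporal integrals.
#'
#' @param tiPerWell the \code{tiPerWell} table from
#'   \code{\link{buildTimecourses}}
#' @param pseudocount pseudocount for \code{\link{clrCompose}}
#' @return matrix (rows = wells, cols = the three stages) with a
#'   \code{groups} attribute carrying each well's treatment
#' @export
composeReplicates <- function(tiPerWell, pseudocount = 0.5) {
  stages <- c("spread", "disintegrated", "netosis")
  ws <- split(tiPerWell, tiPerWell$well)
  rows <- lapply(ws, function(d) {
    ti <- stats::setNames(rep(0, 3), stages)
    hit <- d$stage %in% stages
    ti[d$stage[hit]] <- d$ti[hit]
    clrCompose(ti, pseudocount)
  })
  m <- do.call(rbind, rows)
  attr(m, "groups") <- vapply(ws, function(d) as.character(d$treatment[1]),
                              character(1))
  m
}
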