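# Nonparametric cohort-statistics protocol: mean/SD, Q1-Q3 (linear
# interpolation between order statistics), CV%, single-pass 3xIQR outlier
# screening on the three core parameters, Wilcoxon rank-sum with midranks,
# tie-corrected variance, continuity correction and effect size r = Z/sqrt(n),
# and Spearman correlations with a t-approximation p value.

#' Summary statistics of a parameter
#'
#' Mean, sample SD, first and third quartile (linear interpolation between
#' order statistics), and coefficient of variation CV% = SD/mean * 100.
#'
#' @param values numeric vector, n >= 2
#' @return list with \code{mean}, \code{sd}, \code{q1}, \code{q3},
#'   \code{cvPct} (NA when the mean is not positive), \code{n}
#' @export
summarizeStats <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 2)
  q <- unname(quantile(values, c(0.25, 0.75), type = 7))
  m <- mean(values)
  s <- sd(values)
  list(mean = m, sd = s, q1 = q[1], q3 = q[2],
       cvPct = if (m > 0) s / m * 100 else NA_real_,
       n = length(values))
}

#' Coefficient-of-variation helper
#'
#' @param mean,sd summary values
#' @return CV in percent (NA for non-positive mean)
#' @export
cvPercent <- function(mean, sd) {
  if (is.na(mean) || mean <= 0) return(NA_real_)
  sd / mean * 100
}

#' Effect size r from a Z value
#'
#' r = Z / sqrt(n), with n the number of analyzed subjects.
#'
#' @param z Wilcoxon Z value
#' @param nTotal total analyzed sample size
#' @return effect size r
#' @export
effectSizeR <- function(z, nTotal) z / sqrt(nTotal)

#' Single-pass 3xIQR outlier exclusion
#'
#' A subject is excluded if any screened parameter lies below
#' \code{Q1 - k*IQR} or above \code{Q3 + k*IQR}, with the quartiles
#' computed on all rows before any exclusion (one screening pass). When
#' IQR = 0 the bounds collapse to [Q1, Q3], so any value off the common
#' value is excluded.
#'
#' @param table cohort data.frame with an \code{id} column
#' @param columns parameters screened (default the three core parameters)
#' @param k IQR multiplier (default 3)
#' @return list with \code{kept} (data.frame), \code{excluded} (data.frame
#'   id/column/value/lower/upper, one row per violation)
#' @export
excludeOutliers <- function(table,
                            columns = c("ratio_area", "ratio_sv",
                                        "resistance"),
                            k = 3) {
  stopifnot(k > 0, all(columns %in% names(table)))
  excl <- data.frame(id = character(), column = character(),
                     value = numeric(), lower = numeric(),
                     upper = numeric())
  drop <- rep(FALSE, nrow(table))
  for (col in columns) {
    x <- table[[col]]
    q <- unname(quantile(x, c(0.25, 0.75), type = 7, na.rm = TRUE))
    iqr <- q[2] - q[1]
    lo <- q[1] - k * iqr; hi <- q[2] + k * iqr
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad)) {
      excl <- rbind(excl, data.frame(id = as.character(table$id[bad]),
                                     column = col, value = x[bad],
                                     lower = lo, upper = hi))
      drop <- drop | bad
    }
  }
  list(kept = table[!drop, , drop = FALSE], excluded = excl)
}

#' Wilcoxon rank-sum test with effect size
#'
#' Two-sided rank-sum test on two independent groups using midranks for
#' ties, the tie-corrected normal approximation with continuity
#' correction. Z is the standardized deviation of group A's rank sum from
#' its null expectation; the effect size is r = Z/sqrt(nA + nB).
#'
#' @param groupA,groupB numeric vectors (each n >= 3)
#' @return list with \code{zValue}, \code{pValue}, \code{effectR},
#'   \code{nTotal}, \code{rankSumA}
#' @export
wilcoxonRankSum <- function(groupA, groupB) {
  groupA <- groupA[!is.na(groupA)]; groupB <- groupB[!is.na(groupB)]
  nA <- length(groupA); nB <- length(groupB)
  stopifnot(nA >= 3, nB >= 3)
  N <- nA + nB
  r <- rank(c(groupA, groupB))        # midranks
  W <- sum(r[seq_len(nA)])
  E <- nA * (N + 1) / 2
  ties <- table(r)
  tieTerm <- sum(ties^3 - ties) / (N * (N - 1))
  V <- nA * nB / 12 * ((N + 1) - tieTerm)
  if (V <= 0) {
    z <- 0; p <- 1
  } else {
    dev <- W - E
    z <- (dev - 0.5 * sign(dev)) / sqrt(V)
    if (dev == 0) z <- 0
    p <- 2 * pnorm(-abs(z))
  }
  list(zValue = z, pValue = min(p, 1), effectR = effectSizeR(z, N),
       nTotal = N, rankSumA = W)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; two-sided p value from the
#' t-approximation with n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors (n >= 4 complete pairs)
#' @return list with \code{rho}, \code{pValue}, \code{n} (rho and p are NA
#'   when either vector has zero rank variance)
#' @export
spearmanCor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 4)
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    return(list(rho = NA_real_, pValue = NA_real_, n = n))
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, pValue = p, n = n)
}

#' Spearman correlation matrix
#'
#' Pairwise-complete Spearman correlations over the requested columns with
#' significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param table data.frame
#' @param columns numeric columns to correlate
#' @return list of matrices \code{rho}, \code{p}, \code{n}, and character
#'   matrix \code{stars}
#' @export
correlationMatrix <- function(table, columns) {
  stopifnot(all(columns %in% names(table)))
  p <- length(columns)
  rho <- matrix(NA_real_, p, p, dimnames = list(columns, columns))
  pv <- rho
  nM <- matrix(NA_integer_, p, p, dimnames = list(columns, columns))
  diag(rho) <- 1; diag(pv) <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i >= j) next
    x <- table[[columns[i]]]; y <- table[[columns[j]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4) next
    r <- spearmanCor(x, y)
    rho[i, j] <- rho[j, i] <- r$rho
    pv[i, j] <- pv[j, i] <- r$pValue
    nM[i, j] <- nM[j, i] <- r$n
  }
  stars <- matrix("", p, p, dimnames = list(columns, columns))
  stars[!is.na(pv) & pv < 0.05] <- "*"
  stars[!is.na(pv) & pv < 0.01] <- "**"
  stars[!is.na(pv) & pv < 0.001] <- "***"
  diag(stars) <- ""
  list(rho = rho, p = pv, n = nM, stars = stars)
}
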