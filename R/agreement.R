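#' Round half away from zero
#'
#' Reporting rounding used throughout (percentages to 2 decimals,
#' kappa/CCC to 3): ties go up, not to even as in base [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Square contingency table
#'
#' Integer cross-classification counts of two raters/methods over the
#' same ordered class set.
#'
#' @param counts Square numeric matrix of nonnegative integers with a
#'   positive total.
#' @param labels Ordered class names (default: dimnames or 1..k).
#' @return An object of class `"hepiron_contingency"` (a matrix).
#' @export
contingency_table <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (sum(counts) <= 0) stop("table total must be positive")
  if (is.null(labels)) {
    labels <- rownames(counts)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(counts)))
  }
  dimnames(counts) <- list(labels, labels)
  structure(counts, class = c("hepiron_contingency", "matrix"))
}

#' Cross-classify two label vectors
#'
#' @param class_a,class_b Equal-length vectors of class labels (method A
#'   indexes rows, method B columns).
#' @param labels Ordered class set; defaults to the union of observed
#'   labels (sorted).
#' @return A [contingency_table()]; cell (i, j) counts subjects with
#'   `class_a == labels[i]` and `class_b == labels[j]`.
#' @export
build_contingency <- function(class_a, class_b, labels = NULL) {
  if (length(class_a) != length(class_b)) {
    stop("'class_a' and 'class_b' must have the same length")
  }
  if (is.null(labels)) {
    labels <- sort(unique(c(as.character(class_a), as.character(class_b))))
  }
  a <- factor(as.character(class_a), levels = labels)
  b <- factor(as.character(class_b), levels = labels)
  if (anyNA(a) || anyNA(b)) stop("labels outside the declared class set")
  contingency_table(unclass(table(a, b)), labels)
}

#' Read / write a contingency table as CSV
#'
#' The CSV carries class labels as header row and first column.
#'
#' @param path File path.
#' @return `read_contingency()` returns a [contingency_table()].
#' @export
read_contingency <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  contingency_table(as.matrix(df), rownames(df))
}

#' @rdname read_contingency
#' @param t A [contingency_table()].
#' @export
write_contingency <- function(t, path) {
  utils::write.csv(as.data.frame(unclass(t)), path, row.names = TRUE)
  invisible(path)
}

#' Overall percent agreement
#'
#' `100 * trace / total` of a square contingency table.
#'
#' @param t A [contingency_table()].
#' @return Percent in \[0, 100\] (unrounded; report with
#'   [round_half_up()] to 2 decimals).
#' @export
overall_agreement <- function(t) {
  stopifnot(inherits(t, "hepiron_contingency"))
  100 * sum(diag(t)) / sum(t)
}

#' Cohen's kappa (identity weights)
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o` the observed diagonal proportion and `p_e` the chance
#' proportion from the marginal products.  "Equal weights" here means
#' identity (unweighted) agreement weights: every disagreement counts
#' the same.  The standard error is the large-sample (Fleiss-Cohen-
#' Everitt) asymptotic formula without continuity correction.
#'
#' @param t A [contingency_table()].
#' @param weighting Only `"identity"` is implemented.
#' @return List with `kappa`, `se`, `p_o`, `p_e`, `n`.  Degenerate
#'   marginals (`p_e == 1`) give `kappa = NA`.
#' @export
cohens_kappa <- function(t, weighting = c("identity")) {
  stopifnot(inherits(t, "hepiron_contingency"))
  weighting <- match.arg(weighting)
  n <- sum(t)
  p <- t / n
  po <- sum(diag(p))
  rs <- rowSums(p)
  cs <- colSums(p)
  pe <- sum(rs * cs)
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    return(list(kappa = NA_real_, se = NA_real_, p_o = po, p_e = pe, n = n))
  }
  k <- (po - pe) / (1 - pe)
  # asymptotic SE (Fleiss, Cohen & Everitt 1969)
  a <- sum(diag(p) * (1 - (rs + cs) * (1 - k))^2)
  b_mat <- p * outer(cs, rs, "+")^2
  diag(b_mat) <- 0
  b <- (1 - k)^2 * sum(b_mat)
  cc <- (k - pe * (1 - k))^2
  se <- sqrt(max(a + b - cc, 0) / (n * (1 - pe)^2))
  list(kappa = k, se = se, p_o = po, p_e = pe, n = n)
}

#' Ordinary least-squares line
#'
#' @param x,y Equal-length numeric vectors (n >= 3, `x` not constant).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("'x' must not be constant")
  fit <- stats::lm(y ~ x)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (sst > 0) 1 - ssr / sst else 0)
}

#' Bland-Altman agreement summary
#'
#' Differences `y - x`, their mean and SD (n - 1 denominator) and the
#' 95 percent limits of agreement at mean +/- 1.96 SD.
#'
#' @param x,y Equal-length numeric vectors (n >= 2).
#' @return List with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 2L) stop("need at least 2 points")
  d <- y - x
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       n = length(d))
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' n-denominator moments, penalizing both decorrelation and
#' location/scale shift.  The 95 percent confidence interval uses the
#' Fisher z-transform with Lin's asymptotic variance.  The qualitative
#' rating follows the study's bins: < 0.9 poor, 0.9-0.95 moderate,
#' 0.95-0.99 substantial, > 0.99 almost perfect.
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return List with `ccc`, `ci_low`, `ci_high`, `rating`, `n`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 points")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / (sx2 * sy2)^0.25
  ci <- c(NA_real_, NA_real_)
  if (abs(ccc) < 1 && is.finite(r) && r != 0) {
    z <- atanh(ccc)
    sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    if (is.finite(sz2) && sz2 >= 0) {
      hw <- stats::qnorm(0.975) * sqrt(sz2)
      ci <- tanh(c(z - hw, z + hw))
    }
  }
  rating <- if (ccc < 0.9) "poor" else if (ccc < 0.95) "moderate"
            else if (ccc <= 0.99) "substantial" else "almost perfect"
  list(ccc = ccc, ci_low = ci[1], ci_high = ci[2], rating = rating, n = n)
}
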