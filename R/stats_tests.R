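#' Association of expression with a binary sample grouping
#'
#' Classical unpaired two-tailed t-test (pooled variance) of per-sample
#' values between two groups — e.g. testing whether a gene's expression
#' differs between tumor subtypes.
#'
#' @param values Numeric vector, one value per sample.
#' @param groups Two-level factor or character vector, same length.
#' @return List with `t` statistic, `p` (two-tailed), `df`.
#' @export
group_association <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required",
                                  call. = FALSE)
  if (min(table(groups)) < 2L) stop("each group needs >= 2 samples",
                                    call. = FALSE)
  ht <- stats::t.test(values ~ groups, var.equal = TRUE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Pearson product-moment correlation
#'
#' @param x,y Paired numeric vectors, >= 3 values, each with nonzero
#'   variance.
#' @return List with `r` and two-tailed `p`.
#' @export
pearson_association <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need >= 3 paired values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in correlation input", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' Significance tier of a two-group comparison
#'
#' Runs a classical unpaired two-tailed t-test and maps the p-value onto
#' the lettered tiers used to annotate growth-curve figures:
#' A (p <= 0.01), B (p <= 0.005), C (p <= 0.001), D (p <= 0.0005); the
#' most stringent satisfied tier is reported, `"none"` otherwise.
#'
#' @param a,b Numeric vectors, >= 2 values each.
#' @return List with `tier` and `p`.
#' @export
#' @examples
#' significance_tiers(c(1, 2, 1.5, 1.8), c(5, 6, 5.5, 5.8))
significance_tiers <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  p <- stats::t.test(a, b, var.equal = TRUE,
                     alternative = "two.sided")$p.value
  cuts <- c(D = 0.0005, C = 0.001, B = 0.005, A = 0.01)
  tier <- names(cuts)[p <= cuts]
  list(tier = if (length(tier)) tier[1] else "none", p = p)
}

#' Caliper tumor volume
#'
#' Standard xenograft volume estimate from caliper length and width:
#' `V = length * width^2 / 2` (mm^3).
#'
#' @param length,width Caliper measurements in mm, > 0; vectorized.
#' @return Volume in mm^3.
#' @export
#' @examples
#' tumor_volume(10, 5)  # 125
tumor_volume <- function(length, width) {
  if (any(!is.finite(c(length, width))) || any(c(length, width) <= 0)) {
    stop("length and width must be > 0", call. = FALSE)
  }
  length * width^2 / 2
}
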