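#' @importFrom rlang abort warn inform %||%
#' @importFrom stats cor sd setNames pchisq pnorm pt qnorm phyper rnorm runif
#'   rbinom rexp hclust cutree as.dist quantile uniroot complete.cases
#' @importFrom utils head
NULL

# round half away from zero for positive x; used where an integer count is
# derived from a fractional formula and ties must not bank
round_half_up <- function(x) floor(x + 0.5)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "sigforge_validation_error")
}

parse_error <- function(msg) abort(msg, class = "sigforge_parse_error")

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' by the recovery checks that compare inferred gene groups or sample
#' subtypes against planted ground truth. 1 means identical partitions, 0 is
#' the expected value for independent random partitions.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single numeric value, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  assert_that(length(a) == length(b), "partitions must label the same items")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# rank -> fraction in (0, 1]; average ties so the map is permutation-stable
rank_fraction <- function(x) rank(x, ties.method = "average") / length(x)

# min-max rescale to [0, 1]; degenerate (constant) input maps to `constant`
rescale01 <- function(x, constant = 1) {
  rng <- range(x)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) return(rep(constant, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}
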