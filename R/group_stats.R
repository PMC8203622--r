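#' Compare two measurement groups
#'
#' The two tests used for thickness comparisons: a one-tailed unpaired
#' Student t-test (independent interface classes) and the one-tailed
#' Wilcoxon matched-pairs signed-ranks test (interface vs free thickness of
#' the same membranes). The direction of the alternative is explicit.
#'
#' For the paired Wilcoxon test with `n <= 16` informative (non-zero)
#' differences, the p-value comes from exact enumeration of all `2^n` sign
#' assignments over midranks, which stays exact under ties; larger samples
#' use the normal approximation with continuity correction. Zero differences
#' are dropped (Wilcoxon convention); if all differences are zero the result
#' is flagged and `p = 1` by convention.
#'
#' @param a,b numeric vectors. For `alternative = "greater"` the alternative
#'   hypothesis is that `a` tends to exceed `b`.
#' @param test `"t"` (unpaired Student, equal variances) or `"wilcoxon"`
#'   (matched pairs, requires `paired = TRUE`).
#' @param alternative `"greater"` or `"less"` (one-tailed).
#' @param paired must be `TRUE` for the Wilcoxon matched-pairs test and
#'   `FALSE` for the unpaired t-test.
#' @return A `group_test_result` list: `test`, `statistic`, `p_value`,
#'   `alternative`, `alpha`, `n` (per group), `flag` (NA or a note).
#' @export
compare_groups <- function(a, b, test = c("t", "wilcoxon"),
                           alternative = c("greater", "less"),
                           paired = (test == "wilcoxon")) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 observations per group", call. = FALSE)
  flag <- NA_character_

  if (test == "t") {
    if (isTRUE(paired)) stop("the t comparison here is unpaired", call. = FALSE)
    if (sd(a) == 0 && sd(b) == 0)
      stop("zero variance in both groups; t statistic undefined", call. = FALSE)
    ht <- t.test(a, b, alternative = alternative, var.equal = TRUE)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    if (!isTRUE(paired)) stop("the Wilcoxon comparison here is paired", call. = FALSE)
    if (length(a) != length(b)) stop("paired groups must have equal length", call. = FALSE)
    d <- a - b
    if (alternative == "less") d <- -d      # test now one-sided 'greater'
    nz <- d != 0
    if (!any(nz)) {
      res <- list(statistic = 0, p = 1)
      flag <- "all paired differences zero"
    } else {
      if (sum(!nz) > 0) flag <- sprintf("%d zero difference(s) dropped", sum(!nz))
      res <- signed_rank_one_sided(d[nz])
    }
    stat <- res$statistic; p <- res$p
  }

  structure(list(test = if (test == "t") "one-tailed unpaired t" else
                   "Wilcoxon matched-pairs signed-ranks",
                 statistic = stat, p_value = p, alternative = alternative,
                 alpha = 0.05, n = c(n_a = length(a), n_b = length(b)),
                 flag = flag),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> %s: statistic %.4g, one-tailed p %.4g (n = %d, %d)%s\n",
              x$test, x$statistic, x$p_value, x$n[1], x$n[2],
              if (is.na(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

# One-sided (greater) signed-rank test on non-zero differences d.
# V = sum of midranks of positive differences; exact p by enumerating the
# null distribution of V over all sign assignments when n <= 16.
signed_rank_one_sided <- function(d, exact_max_n = 16L) {
  n <- length(d)
  r <- rank(abs(d))                       # midranks; ties allowed
  v_obs <- sum(r[d > 0])
  if (n <= exact_max_n) {
    # work on doubled ranks so midranks (.5) become integers
    r2 <- as.integer(round(2 * r))
    # distribution of sum of a random subset of r2: polynomial product
    dist <- numeric(sum(r2) + 1L)         # index = value + 1
    dist[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), dist[seq_len(length(dist) - rk)])
      dist <- (dist + shifted) / 2
    }
    p <- sum(dist[seq.int(round(2 * v_obs) + 1L, length(dist))])
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- stats::pnorm((v_obs - 0.5 - mu) / sqrt(sig2), lower.tail = FALSE)
  }
  list(statistic = v_obs, p = min(1, p))
}
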