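#' Kendall rank correlation (tau-a or tau-b)
#'
#' Computes Kendall's tau with an O(n log n) merge-sort algorithm. The
#' tau-a variant divides the concordant-minus-discordant pair count by the
#' total number of pairs n(n-1)/2 and is the recommended statistic for
#' comparing RDMs when the candidate matrices contain many tied entries
#' (tied pairs simply dilute tau-a toward zero). The tau-b variant applies
#' the usual tie correction, dividing by the geometric mean of the numbers
#' of untied pairs in each input, and is undefined when either input is
#' completely tied.
#'
#' @param x,y Numeric vectors of equal length (>= 2), no missing values.
#' @param variant `"tau_a"` (default) or `"tau_b"`.
#' @return Rank correlation in \[-1, 1\].
#' @export
#' @examples
#' kendall_tau(1:5, c(2, 1, 4, 3, 5))            # tau-a
#' kendall_tau(1:5, c(2, 1, 4, 3, 5), "tau_b")
kendall_tau <- function(x, y, variant = c("tau_a", "tau_b")) {
  variant <- match_variant(variant)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  tau_from_stats(kendall_stats_cpp(as.numeric(x), as.numeric(y)), variant)
}

# cheap stand-in for match.arg in hot loops
match_variant <- function(variant) {
  v <- variant[1L]
  if (!v %in% c("tau_a", "tau_b")) {
    stop("variant must be \"tau_a\" or \"tau_b\"")
  }
  v
}

tau_from_stats <- function(st, variant) {
  s <- st[1]; n0 <- st[2]; n1 <- st[3]; n2 <- st[4]
  if (variant == "tau_a") return(s / n0)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) {
    stop("tau-b is undefined: ",
         if (n1 == n0) "x is completely tied" else "y is completely tied")
  }
  s / den
}
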