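# Exact big-integer products for design-space counts.
#
# Synonymous design spaces routinely exceed 10^600, far beyond double
# precision, so counts are carried as exact arbitrary-precision integers
# (base-1e4 limbs, little-endian) alongside their base-10 logarithm. Only
# multiplication by small positive integers is needed (codon multiplicities
# are at most 6), so the arithmetic is deliberately minimal.

#' Exact product of small positive integers, with its log10
#'
#' @param factors Integer vector of positive factors.
#' @return An object of class `bigcount` with the exact decimal value
#'   (via [as.character()]) and a `log10` field.
#' @examples
#' big_product(rep(6, 400)) # 6^400, about 3.2e311
#' @export
big_product <- function(factors) {
  factors <- as.integer(factors)
  if (length(factors) == 0L || any(is.na(factors)) || any(factors < 1L))
    stop("factors must be positive integers")
  base <- 10000L
  digits <- 1L # little-endian base-1e4 limbs
  for (f in factors) {
    carry <- 0
    prod <- digits * as.double(f) + 0 # vectorized limb multiply
    for (i in seq_along(prod)) {
      v <- prod[i] + carry
      prod[i] <- v %% base
      carry <- v %/% base
    }
    digits <- prod
    while (carry > 0) {
      digits <- c(digits, carry %% base)
      carry <- carry %/% base
    }
  }
  structure(list(digits = as.integer(digits),
                 log10 = sum(log10(as.double(factors)))),
            class = "bigcount")
}

#' @export
as.character.bigcount <- function(x, ...) {
  limbs <- rev(x$digits)
  paste0(limbs[1], paste(sprintf("%04d", limbs[-1]), collapse = ""))
}

#' @export
print.bigcount <- function(x, ...) {
  mant <- 10^(x$log10 - floor(x$log10))
  cat(sprintf("<bigcount> %.4f x 10^%d (log10 = %.4f)\n",
              mant, as.integer(floor(x$log10)), x$log10))
  s <- as.character(x)
  if (nchar(s) <= 40) cat("  exact:", s, "\n")
  else cat("  exact:", substr(s, 1, 30), "...", sprintf("(%d digits)\n", nchar(s)))
  invisible(x)
}
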