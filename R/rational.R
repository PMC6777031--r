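# Minimal exact rational arithmetic on machine integers (stored as doubles;
# exact while |num|, |den| < 2^53). Only what the Adler-interval machinery
# needs: construction in lowest terms and exact comparison by cross
# multiplication. Internal.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

# rational num/den in lowest terms, den > 0
.rat <- function(num, den) {
  stopifnot(den != 0)
  if (den < 0) { num <- -num; den <- -den }
  g <- .gcd(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  c(num = num, den = den)
}

# sign of a/b - c/d, exactly
.ratCmp <- function(x, y) sign(x[["num"]] * y[["den"]] - y[["num"]] * x[["den"]])

.ratLe <- function(x, y) .ratCmp(x, y) <= 0

.ratValue <- function(x) x[["num"]] / x[["den"]]

# decimal -> exact rational at the stated precision (digits after the point)
.ratFromDecimal <- function(x, digits = 9L) {
  .rat(round(x * 10^digits), 10^digits)
}
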