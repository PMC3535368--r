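#' Parse a concentration string with an explicit unit suffix
#'
#' Configuration files and command-line options give concentrations as
#' strings such as `"500 uM"`, `"2mM"` or `"1e-4 M"`.  The internal
#' canonical unit is molar; conversion happens only at I/O boundaries.
#'
#' @param x Character vector of concentration strings.  Each element must
#'   end in `"uM"`, `"mM"` or `"M"` (case-sensitive), optionally separated
#'   from the number by whitespace.
#' @return Numeric vector of concentrations in molar.
#' @examples
#' parse_conc(c("500 uM", "2mM", "1e-4 M"))
#' @export
parse_conc <- function(x) {
  stopifnot(is.character(x))
  m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*(uM|mM|M)\\s*$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("cannot parse concentration(s): ",
         paste(x[bad], collapse = ", "),
         " (expected e.g. \"500 uM\", \"2 mM\", \"1e-4 M\")")
  }
  val <- vapply(m, function(g) as.numeric(g[2]), numeric(1))
  scale <- c(uM = 1e-6, mM = 1e-3, M = 1)[vapply(m, `[`, character(1), 3)]
  unname(val * scale)
}

#' Format a molar concentration with a unit suffix
#'
#' Inverse of [parse_conc()]: picks the largest of M/mM/uM that keeps the
#' mantissa >= 1 and round-trips bit-exactly through [parse_conc()]
#' (the mantissa is printed at full double precision).
#'
#' @param conc_M Numeric vector, molar.
#' @return Character vector such as `"500 uM"`.
#' @export
format_conc <- function(conc_M) {
  vapply(conc_M, function(c0) {
    if (!is.finite(c0)) return(NA_character_)
    if (c0 == 0) return("0 M")
    a <- abs(c0)
    pref <- if (a >= 0.9999) {
      character(0)
    } else if (a >= 1e-3 * 0.9999) {
      c(sprintf("%.17g mM", c0 * 1e3))
    } else {
      c(sprintf("%.17g uM", c0 * 1e6), sprintf("%.17g mM", c0 * 1e3))
    }
    # prefer the natural prefix, but only if it survives the round trip
    for (s in pref) {
      if (identical(parse_conc(s), c0)) return(s)
    }
    sprintf("%.17g M", c0)
  }, character(1))
}

# time unit helpers: all model internals are seconds, all user-facing
# times (schedules, fitted time constants) are minutes
min_to_sec <- function(t_min) t_min * 60
sec_to_min <- function(t_sec) t_sec / 60
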