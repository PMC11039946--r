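#' @keywords internal
"_PACKAGE"

# two-sided normal 97.5% quantile used for every 95% CI in the package
Z975 <- stats::qnorm(0.975)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed pipeline error
#'
#' All recoverable pipeline failures (no instruments survive selection,
#' harmonization leaves no usable SNP, ...) are signalled as classed
#' conditions so batch drivers can trap them without string matching.
#'
#' @noRd
mr_abort <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mr_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Two-sided normal p-value for a z statistic
#' @noRd
z_pvalue <- function(z) 2 * stats::pnorm(-abs(z))

#' Check whether an allele pair is palindromic
#'
#' A variant is palindromic when its two alleles are reverse complements of
#' each other (A/T or C/G), so strand orientation cannot be resolved from the
#' alleles alone.
#'
#' @param a1,a2 Character vectors of single-base alleles (A, C, G or T).
#' @return Logical vector.
#' @examples
#' is_palindromic(c("A", "A"), c("T", "G"))
#' @export
is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  toupper(a2) == unname(comp[toupper(a1)])
}
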