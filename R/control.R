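#' Method variant switches
#'
#' Several of the interval constructions admit more than one defensible
#' reading of their defining formulas; this object collects the switches.
#'
#' @param t5_df Degrees of freedom for the pooled-variance Welch-type
#'   interval `t5`: `"printed"` uses
#'   \eqn{(R_1+R_2)^2 / \{R_1^2/(n+1) + R_2^2/(n_1+n_2)\} - 2};
#'   `"nminus1"` replaces the `n + 1` divisor by the conventional `n - 1`.
#' @param t4_weights Unpaired-block weights of the Ekbohm weighted estimator:
#'   `"symmetric"` (default) uses the label-symmetric maximum-likelihood form
#'   in which both unpaired weights carry \eqn{(1-\lambda^2)} — equivalently
#'   the `tw1` weights with \eqn{\lambda} in place of \eqn{\rho} — so the
#'   `x1` coefficients sum to 1 and the `x2` coefficients to -1;
#'   `"asymmetric"` keeps \eqn{(1-\lambda)^2} in the `x2` weight.
#' @param corr_variant Correlation recovery for the hybrid (MOVER) intervals:
#'   `"printed"` uses \eqn{nr/\{(n+n_1)(n+n_2)-n_1n_2r^2\}} (clamped);
#'   `"derived"` uses \eqn{nr/\sqrt{(n+n_1)(n+n_2)-n_1n_2r^2}}, the form with
#'   the dimensionally natural square root.
#' @param hybrid_center Whether the MOVER combination is anchored at the
#'   pooled means (`"pooled"`, default) or the shrunken centers of the
#'   marginal limits (`"shrunken"`).
#' @param marginal_ss Whether the marginal limits' sum of squares runs over
#'   the complete-pair block only (`"paired"`, default) or over all
#'   observations of the variable (`"all"`).
#' @param gee_working Working correlation structure of the GEE fit:
#'   `"exchangeable"` (default, fixed at the paired Pearson correlation) or
#'   `"independence"`.
#' @param gee_tol,gee_maxit Convergence tolerance and iteration cap of the
#'   GEE fit.
#' @return A list of class `"mdiff_control"`.
#' @export
mdiff_control <- function(t5_df = c("printed", "nminus1"),
                          t4_weights = c("symmetric", "asymmetric"),
                          corr_variant = c("printed", "derived"),
                          hybrid_center = c("pooled", "shrunken"),
                          marginal_ss = c("paired", "all"),
                          gee_working = c("exchangeable", "independence"),
                          gee_tol = 1e-10, gee_maxit = 100L) {
  structure(list(
    t5_df = match.arg(t5_df),
    t4_weights = match.arg(t4_weights),
    corr_variant = match.arg(corr_variant),
    hybrid_center = match.arg(hybrid_center),
    marginal_ss = match.arg(marginal_ss),
    gee_working = match.arg(gee_working),
    gee_tol = gee_tol, gee_maxit = as.integer(gee_maxit)
  ), class = "mdiff_control")
}
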