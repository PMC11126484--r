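#' Buoyant density of unlabeled DNA from GC content
#'
#' Equilibrium CsCl buoyant density of native (14N) DNA as a linear function
#' of GC fraction: `rho0 = 1.660 + 0.098 * gc` g/mL. GC-rich DNA is denser
#' because the G:C pair is heavier and more compact in CsCl.
#'
#' @param gc GC fraction in \[0, 1\] (numeric, vectorized).
#' @return Buoyant density in g/mL.
#' @examples
#' unlabeled_density(0.5) # 1.709
#' @export
unlabeled_density <- function(gc) {
  check_fraction(gc, "gc")
  1.660 + 0.098 * gc
}

# free-acid molar masses of the two base pairs, g/mol
.MASS_AT <- 617.4
.MASS_GC <- 618.4
# mass increment per 14N -> 15N substitution, g/mol
.DELTA_M_N <- 0.9970

#' Buoyant-density shift from 15N labeling
#'
#' Predicts the increase in CsCl buoyant density of DNA in which a fraction
#' `atom15n` of nitrogen atoms are 15N. The shift is mass-proportional:
#' `delta_rho = atom15n * rho0(gc) * n_N(gc) * delta_m / m_bp(gc)`, with
#' `n_N(gc) = 7 + gc` nitrogen atoms per base pair (A:T has 7, G:C has 8),
#' `delta_m = 0.9970` g/mol per substituted atom and the base-pair molar
#' mass interpolated between the free-acid values 617.4 (A:T) and 618.4
#' (G:C) g/mol. At full labeling and 50% GC this gives ~0.021 g/mL, the
#' characteristic small shift that makes 15N-SIP harder than 13C-SIP.
#'
#' @param atom15n 15N atom fraction in \[0, 1\].
#' @param gc GC fraction in \[0, 1\].
#' @return Density shift in g/mL; linear in `atom15n`.
#' @examples
#' label_shift(1, 0.5)   # ~0.021 g/mL, full labeling
#' label_shift(0.5, 0.5) # exactly half of that
#' @export
label_shift <- function(atom15n, gc) {
  check_fraction(atom15n, "atom15n")
  check_fraction(gc, "gc")
  n_nitrogen <- 7 + gc
  m_bp <- .MASS_AT + gc * (.MASS_GC - .MASS_AT)
  atom15n * unlabeled_density(gc) * n_nitrogen * .DELTA_M_N / m_bp
}

#' Convert CsCl refractive index to buoyant density
#'
#' Standard refractometric calibration for CsCl solutions:
#' `rho = 10.8601 * RI - 13.4974` g/mL. Gradient fractions are routinely
#' characterized by refractive index of a small aliquot; this converts the
#' reading to the density scale on which DNA banding is interpreted.
#'
#' @param refractive_index refractive index reading(s), in \[1.37, 1.42\]
#'   (the plausible CsCl working range).
#' @return Buoyant density in g/mL.
#' @examples
#' ri_to_bd(1.4015) # 1.7230, a typical mean gradient density
#' @export
ri_to_bd <- function(refractive_index) {
  if (!is.numeric(refractive_index) ||
      any(!is.finite(refractive_index)) ||
      any(refractive_index < 1.37 | refractive_index > 1.42)) {
    stop("refractive_index must be within [1.37, 1.42] (CsCl working range)",
         call. = FALSE)
  }
  10.8601 * refractive_index - 13.4974
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1)) {
    stop(sprintf("%s must be numeric in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
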