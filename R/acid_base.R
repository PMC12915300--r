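# Henderson-Hasselbalch, buffer capacity and a charge-balance pH solver
# for mixtures of monoprotic weak acids (the volatile fatty acids that
# accumulate during substrate fermentation: acetate pKa 4.76, butyrate
# pKa 4.82).

.vfa_pka <- c(acetate = 4.76, butyrate = 4.82)

#' Construct a monoprotic weak acid
#'
#' @param name Acid name. `"acetate"` and `"butyrate"` are presets whose
#'   pKa may be omitted.
#' @param C_M Total (analytical) concentration in mol/L.
#' @param pKa Acid dissociation constant exponent; must lie in (0, 14).
#' @return An object of class `weak_acid`.
#' @export
#' @examples
#' weak_acid("acetate", C_M = 1.8e-3)
weak_acid <- function(name, C_M, pKa = NULL) {
  if (is.null(pKa)) {
    if (!name %in% names(.vfa_pka)) {
      stop_sulfidogen(sprintf("no preset pKa for '%s'; supply pKa", name),
                      "sulfidogen_lookup_error")
    }
    pKa <- .vfa_pka[[name]]
  }
  if (!(pKa > 0 && pKa < 14)) {
    stop_sulfidogen("pKa must lie in (0, 14)", "sulfidogen_domain_error")
  }
  if (C_M < 0) {
    stop_sulfidogen("concentration must be non-negative", "sulfidogen_domain_error")
  }
  structure(list(name = name, pKa = pKa, C_M = C_M), class = "weak_acid")
}

#' Henderson-Hasselbalch pH of a conjugate pair
#'
#' `pH = pKa + log10(base / acid)`.
#'
#' @param pKa Acid dissociation exponent.
#' @param base_conc Conjugate-base concentration (any unit, ratio is used).
#' @param acid_conc Protonated-acid concentration (same unit).
#' @return pH.
#' @export
#' @examples
#' henderson_hasselbalch(4.76, 10, 1)  # 5.76
henderson_hasselbalch <- function(pKa, base_conc, acid_conc) {
  if (any(base_conc <= 0) || any(acid_conc <= 0)) {
    stop_sulfidogen("concentrations must be positive", "sulfidogen_domain_error")
  }
  pKa + log10(base_conc / acid_conc)
}

#' Buffer capacity of a monoprotic weak acid solution
#'
#' `beta = 2.303 (Kw/[H+] + [H+] + C Ka [H+] / ([H+] + Ka)^2)`, the amount
#' of strong base required to raise the pH by one unit. At `pH = pKa` the
#' weak-acid term reduces to `C/4`, its maximum.
#'
#' @param acid A [weak_acid] (its `C_M` may be zero for water-only
#'   buffering).
#' @param pH Evaluation pH, in (0, 14).
#' @param Kw Water autoionisation constant (default 1e-14).
#' @return Buffer capacity in mol/L per pH unit.
#' @export
buffer_capacity <- function(acid, pH, Kw = 1e-14) {
  stopifnot(inherits(acid, "weak_acid"))
  if (!(pH > 0 && pH < 14)) {
    stop_sulfidogen("pH must lie in (0, 14)", "sulfidogen_domain_error")
  }
  h <- 10^(-pH)
  Ka <- 10^(-acid$pKa)
  2.303 * (Kw / h + h + acid$C_M * Ka * h / (h + Ka)^2)
}

#' Solution specification for the pH solver
#'
#' @param acids A [weak_acid] or list of them (superposition of monoprotic
#'   weak-acid terms).
#' @param strong_base Strong base added, equivalents/L (non-negative).
#' @param Kw Water autoionisation constant.
#' @return An object of class `solution_spec`.
#' @export
solution_spec <- function(acids = list(), strong_base = 0, Kw = 1e-14) {
  if (inherits(acids, "weak_acid")) acids <- list(acids)
  stopifnot(all(vapply(acids, inherits, logical(1), "weak_acid")))
  if (strong_base < 0) {
    stop_sulfidogen("strong base must be non-negative", "sulfidogen_domain_error")
  }
  structure(list(acids = acids, strong_base = strong_base, Kw = Kw),
            class = "solution_spec")
}

#' Equilibrium pH of a weak-acid mixture by charge balance
#'
#' Solves `[H+] + B - Kw/[H+] - sum(C_i Ka_i / ([H+] + Ka_i)) = 0` (B the
#' strong-base equivalents, the sum over dissociated acid anions) by
#' bracketed root search on log10[H+] over \[1e-14, 10\] M, then polishes to
#' a charge-balance residual below 1e-12 eq/L.
#'
#' @param spec A [solution_spec], or a [weak_acid]/list of them (in which
#'   case `strong_base` and `Kw` apply).
#' @param strong_base,Kw Used only when `spec` is not a `solution_spec`.
#' @return pH.
#' @export
#' @examples
#' mixture_ph(solution_spec())  # pure water: 7
mixture_ph <- function(spec, strong_base = 0, Kw = 1e-14) {
  if (!inherits(spec, "solution_spec")) {
    spec <- solution_spec(spec, strong_base = strong_base, Kw = Kw)
  }
  C <- vapply(spec$acids, function(a) a$C_M, numeric(1))
  Ka <- vapply(spec$acids, function(a) 10^(-a$pKa), numeric(1))
  resid <- function(lh) {
    h <- 10^lh
    h + spec$strong_base - spec$Kw / h - sum(C * Ka / (h + Ka))
  }
  lo <- -14; hi <- 1
  if (resid(lo) > 0 || resid(hi) < 0) {
    stop_sulfidogen("no sign change in [H+] bracket", "sulfidogen_solver_error")
  }
  root <- uniroot(resid, c(lo, hi), tol = .Machine$double.eps^0.75,
                  maxiter = 2000)
  if (abs(resid(root$root)) > 1e-12) {
    # one more bisection sweep at full precision around the root
    root <- uniroot(resid, c(root$root - 1e-6, root$root + 1e-6),
                    tol = .Machine$double.eps, maxiter = 5000,
                    extendInt = "yes")
  }
  -root$root
}
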