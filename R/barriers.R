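#' Physical constants (CODATA 2018)
#'
#' @return named list: `kB` (J/K), `h` (J s), `R` (kcal/(mol K)).
#' @export
physicalConstants <- function() {
    list(kB = 1.380649e-23, h = 6.62607015e-34, R = 1.98720425864e-3)
}

#' Extract the activation barrier from a reaction profile
#'
#' The barrier is the highest energy minus the lowest energy occurring
#' before the highest point. The profile is rejected (no barrier
#' evaluated) when the last frame is the highest (`LAST_FRAME_MAX`), when
#' the maximum sits on the first frame (`NO_PRE_MAX`), or when any frame
#' before the maximum failed to converge (`INCOMPLETE`). Ties in the
#' maximum resolve to the first occurrence.
#'
#' @param p a [ReactionProfile-class], or a plain numeric energy vector
#'   (all frames then count as converged).
#' @return A [BarrierResult-class].
#' @examples
#' barrierValue(extractBarrier(c(2, 5, 9, 4)))  # 7
#' extractBarrier(c(0, 1, 2, 3))                # invalid: LAST_FRAME_MAX
#' @export
extractBarrier <- function(p) {
    if (is.numeric(p)) p <- reactionProfile("profile", seq_along(p), p)
    e <- p@energies
    conv <- p@statuses == "CONVERGED"
    if (sum(conv) < 2L)
        stop("need at least two converged frames")
    invalid <- function(reason)
        new("BarrierResult", barrier = NA_real_, argmax = NA_integer_,
            argmin = NA_integer_, valid = FALSE, reason = reason)
    emax <- max(e[conv])
    argmax <- which(conv & e == emax)[1L]
    if (any(!conv[seq_len(argmax)])) return(invalid("INCOMPLETE"))
    if (argmax == length(e)) return(invalid("LAST_FRAME_MAX"))
    if (argmax == 1L) return(invalid("NO_PRE_MAX"))
    pre <- seq_len(argmax - 1L)
    argmin <- pre[which.min(e[pre])]
    new("BarrierResult", barrier = emax - e[argmin],
        argmax = as.integer(argmax), argmin = as.integer(argmin),
        valid = TRUE, reason = "")
}

#' Barrier change of a mutant relative to a reference
#'
#' @param mut,ref [BarrierResult-class] objects (or numeric barriers);
#'   both must be valid.
#' @return mutant barrier minus reference barrier, kcal/mol.
#' @export
deltaBarrier <- function(mut, ref) {
    val <- function(x) {
        if (is.numeric(x)) return(x)
        if (!x@valid) stop("delta-barrier undefined: invalid barrier (",
                           x@reason, ")")
        x@barrier
    }
    val(mut) - val(ref)
}

#' Activation free energy from a turnover number (Eyring equation)
#'
#' `dG = R T ln(kB T / (h kcat))`, the transition-state-theory conversion
#' used to compare computed barriers against an experimental kcat.
#'
#' @param kcat turnover number, 1/s (> 0).
#' @param temperature Kelvin (> 0); 313.15 K is the assay temperature of
#'   the reference kinetics.
#' @return activation free energy, kcal/mol.
#' @examples
#' round(eyringDG(9.6, 313.15), 1)  # 17.0
#' @export
eyringDG <- function(kcat, temperature = 313.15) {
    if (any(kcat <= 0) || any(temperature <= 0))
        stop("kcat and temperature must be positive")
    cst <- physicalConstants()
    cst$R * temperature * log(cst$kB * temperature / (cst$h * kcat))
}

#' Turnover number from an activation free energy (inverse Eyring)
#'
#' Exact inverse of [eyringDG()].
#'
#' @param deltaG activation free energy, kcal/mol.
#' @param temperature Kelvin (> 0).
#' @return kcat in 1/s.
#' @export
eyringK <- function(deltaG, temperature = 313.15) {
    if (any(temperature <= 0)) stop("temperature must be positive")
    cst <- physicalConstants()
    cst$kB * temperature / cst$h *
        exp(-deltaG / (cst$R * temperature))
}

#' Bundle a rate conversion as a RateConversion object
#' @param kcat turnover number, 1/s.
#' @param temperature Kelvin.
#' @return A [RateConversion-class].
#' @export
rateConversion <- function(kcat, temperature = 313.15) {
    new("RateConversion", kcat = kcat, temperature = temperature,
        deltaG = eyringDG(kcat, temperature))
}

setMethod("show", "RateConversion", function(object) {
    cat(sprintf("RateConversion: kcat %.3g 1/s at %.2f K -> dG = %.1f kcal/mol\n",
                object@kcat, object@temperature, object@deltaG))
})
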