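#' @include AllClasses.R AllGenerics.R
NULL

## reduced rational stored as integer c(num, den); all methanogenic
## coefficients have denominators dividing 8 (quarters from water, eighths
## from methane), so plain integer arithmetic is exact.
.gcd <- function(a, b) {
    a <- abs(a); b <- abs(b)
    while (b != 0L) { t <- b; b <- a %% b; a <- t }
    a
}

.rational <- function(num, den) {
    num <- as.integer(num); den <- as.integer(den)
    if (den == 0L) stop("zero denominator")
    if (den < 0L) { num <- -num; den <- -den }
    g <- .gcd(num, den)
    if (g > 1L) { num <- num %/% g; den <- den %/% g }
    c(num, max(den, 1L))
}

.ratNumeric <- function(v) v[1L] / v[2L]

#' Built-in compound registry
#'
#' Molecular formulas for the substrates and reference compounds the
#' methane-accounting workflow uses: palmitate (C16H32O2), stearate
#' (C18H36O2), hexadecane (C16H34), octadecane (C18H38), cysteine
#' (C3H7NO2S), glucose (C6H12O6), acetate (C2H4O2) and methane (CH4).
#'
#' @param name compound name (case-insensitive).
#' @return a [MolecularFormula-class].
#' @examples
#' compoundFormula("palmitate")
#' @export
compoundFormula <- function(name) {
    reg <- list(
        palmitate  = c(16, 32, 2, 0, 0),
        stearate   = c(18, 36, 2, 0, 0),
        hexadecane = c(16, 34, 0, 0, 0),
        octadecane = c(18, 38, 0, 0, 0),
        cysteine   = c(3, 7, 2, 1, 1),
        glucose    = c(6, 12, 6, 0, 0),
        acetate    = c(2, 4, 2, 0, 0),
        methane    = c(1, 4, 0, 0, 0))
    key <- tolower(name)
    if (!key %in% names(reg))
        stop("unknown compound '", name, "'; known: ",
             paste(names(reg), collapse = ", "))
    a <- reg[[key]]
    molecularFormula(a[1], a[2], a[3], a[4], a[5], name = key)
}

.asFormula <- function(f) {
    if (is(f, "MolecularFormula")) return(f)
    if (is.character(f) && length(f) == 1L) return(compoundFormula(f))
    stop("substrate must be a MolecularFormula or a registered compound name")
}

#' Render a molecular formula as text
#'
#' @param f a [MolecularFormula-class].
#' @return e.g. `"C16H32O2 (palmitate)"`.
#' @export
formatFormula <- function(f) {
    f <- .asFormula(f)
    piece <- function(sym, k)
        if (k == 0L) "" else if (k == 1L) sym else paste0(sym, k)
    s <- paste0(piece("C", f@c), piece("H", f@h), piece("N", f@n),
                piece("O", f@o), piece("S", f@s))
    if (!is.na(f@name)) paste0(s, " (", f@name, ")") else s
}

#' Methanogenic conversion coefficients for a CcHhOoNnSs substrate
#'
#' Solves the element balance of complete anaerobic mineralization to CH4
#' and CO2, with nitrogen leaving as NH4+ (consuming one proton per N) and
#' sulfur as H2S:
#'
#' \deqn{CH_4 = c/2 + h/8 - o/4 - 3n/8 - s/4}
#' \deqn{H_2O = c - h/4 - o/2 + 3n/4 + s/2}
#'
#' with `CO2 = c - CH4`, `NH4+ = n`, `H2S = s`.  Arithmetic is exact
#' rational; the result's validity method re-asserts elemental balance in
#' integer arithmetic before it is returned.  Substrates whose computed CH4
#' or CO2 coefficient would be negative lie outside the model's validity
#' and are rejected.
#'
#' @param f a [MolecularFormula-class] or registered compound name.
#' @return a [BuswellCoefficients-class].
#' @examples
#' buswellCoefficients("palmitate")   # 7 H2O -> 11.5 CH4 + 4.5 CO2
#' buswellCoefficients("glucose")     # 3 CH4 + 3 CO2, no water
#' @export
buswellCoefficients <- function(f) {
    f <- .asFormula(f)
    ch4_8 <- 4L * f@c + f@h - 2L * f@o - 3L * f@n - 2L * f@s
    water4 <- 4L * f@c - f@h - 2L * f@o + 3L * f@n + 2L * f@s
    co2_8 <- 8L * f@c - ch4_8
    if (ch4_8 < 0L || co2_8 < 0L)
        stop("formula ", formatFormula(f),
             " is outside model validity (negative CH4 or CO2 coefficient)")
    new("BuswellCoefficients", formula = f,
        water = .rational(water4, 4L),
        ch4 = .rational(ch4_8, 8L),
        co2 = .rational(co2_8, 8L),
        nh4 = .rational(f@n, 1L),
        h2s = .rational(f@s, 1L))
}

#' @describeIn buswellCoefficients CH4 coefficient (mol per mol substrate)
#'   as numeric.
#' @param x a [BuswellCoefficients-class].
#' @export
setMethod("methaneCoefficient", "BuswellCoefficients",
          function(x) .ratNumeric(x@ch4))

#' @describeIn buswellCoefficients all coefficients as a one-row
#'   data.frame (numeric, moles per mole of substrate; water consumed,
#'   products positive).
#' @export
setMethod("coefficientTable", "BuswellCoefficients", function(x) {
    data.frame(formula = formatFormula(x@formula),
               water_consumed = .ratNumeric(x@water),
               ch4 = .ratNumeric(x@ch4), co2 = .ratNumeric(x@co2),
               nh4 = .ratNumeric(x@nh4), h2s = .ratNumeric(x@h2s),
               stringsAsFactors = FALSE)
})

setMethod("show", "BuswellCoefficients", function(object) {
    num <- function(v) {
        x <- .ratNumeric(v)
        if (x == round(x)) format(as.integer(round(x))) else format(x)
    }
    term <- function(v, lab) {
        x <- .ratNumeric(v)
        if (x == 0) NULL
        else if (x == 1) lab
        else paste0(num(v), " ", lab)
    }
    lhs <- c(formatFormula(object@formula), term(object@water, "H2O"),
             if (object@formula@n > 0L)
                 term(.rational(object@formula@n, 1L), "H+"))
    rhs <- c(term(object@ch4, "CH4"), term(object@co2, "CO2"),
             term(object@nh4, "NH4+"), term(object@h2s, "H2S"))
    cat("BuswellCoefficients:\n  ",
        paste(lhs[!vapply(lhs, is.null, logical(1))], collapse = " + "),
        " -> ",
        paste(rhs[!vapply(rhs, is.null, logical(1))], collapse = " + "),
        "\n", sep = "")
})

#' Theoretical methane yield
#'
#' Moles of CH4 expected from complete methanogenic conversion of a given
#' amount of substrate; linear in the amount.
#'
#' @param f substrate ([MolecularFormula-class] or compound name).
#' @param amountUmol substrate amount in micromoles (>= 0).
#' @return expected CH4 in micromoles.
#' @examples
#' theoreticalMethane("palmitate", 30)  # 345
#' @export
theoreticalMethane <- function(f, amountUmol) {
    if (amountUmol < 0) stop("amount must be >= 0")
    amountUmol * methaneCoefficient(buswellCoefficients(f))
}

#' Percent conversion of substrate to methane
#'
#' `100 * measured / theoretical`.  Reports the unrounded value and the
#' half-up integer rounding used for "approximately NN%" statements.
#' Measured methane exceeding the theoretical yield is flagged with a
#' warning, not an error (gas carry-over and background production can
#' push it over).
#'
#' @param measuredUmol measured CH4 (umol).
#' @param f substrate formula or compound name.
#' @param substrateUmol substrate added (umol, > 0).
#' @return list with `percent` (unrounded), `percent_rounded` (half-up
#'   integer), `theoretical_umol`.
#' @examples
#' percentConversion(289, "palmitate", 30)$percent_rounded  # 84
#' @export
percentConversion <- function(measuredUmol, f, substrateUmol) {
    if (substrateUmol <= 0) stop("substrate amount must be > 0")
    if (measuredUmol < 0) stop("measured methane must be >= 0")
    theo <- theoreticalMethane(f, substrateUmol)
    pct <- 100 * measuredUmol / theo
    if (pct > 100)
        warning(sprintf("measured methane exceeds theoretical yield (%.1f%%)",
                        pct))
    list(percent = pct,
         percent_rounded = floor(pct + 0.5),  # half-up, not half-to-even
         theoretical_umol = theo)
}

#' Methane ceiling attributable to the cysteine reductant
#'
#' Cultures reduced with cysteine sulfide can generate methane from the
#' cysteine itself; its methanogenic conversion yields 5 CH4 per 4
#' cysteine (coefficient 5/4, computed from the element balance, never
#' hard-coded).  The ceiling is the maximum CH4 attributable to the
#' reductant alone.
#'
#' @param cysteineUmol cysteine added (umol, >= 0).
#' @return ceiling in umol CH4.
#' @examples
#' reductantCeiling(4)     # 5
#' reductantCeiling(85.6)  # 107
#' @export
reductantCeiling <- function(cysteineUmol) {
    if (cysteineUmol < 0) stop("cysteine amount must be >= 0")
    cysteineUmol * methaneCoefficient(buswellCoefficients("cysteine"))
}

#' Attribute measured methane to substrate vs reductant
#'
#' Substrate degradation is supported only when measured methane strictly
#' exceeds the reductant ceiling; otherwise the verdict is inconclusive
#' (the reductant alone could account for the methane).
#'
#' @param measuredUmol measured CH4 (umol, >= 0).
#' @param ceilingUmol reductant-attributable ceiling (umol, >= 0), e.g.
#'   from [reductantCeiling()].
#' @return list with `verdict` (`"substrate_degradation_supported"` or
#'   `"inconclusive"`) and `margin_umol` (measured - ceiling).
#' @examples
#' attributeMethaneSource(187, 107)$verdict
#' attributeMethaneSource(60, 107)$verdict
#' @export
attributeMethaneSource <- function(measuredUmol, ceilingUmol) {
    if (measuredUmol < 0 || ceilingUmol < 0)
        stop("amounts must be >= 0")
    list(verdict = if (measuredUmol > ceilingUmol)
             "substrate_degradation_supported" else "inconclusive",
         margin_umol = measuredUmol - ceilingUmol)
}

#' Full conversion assessment for one culture
#'
#' Combines theoretical yield, percent conversion and reductant-ceiling
#' attribution into one report row.  Exactly one of `ceilingUmol` or
#' `reductantUmol` (cysteine amount, converted via [reductantCeiling()])
#' must be supplied when attribution is wanted; with neither, the verdict
#' column is `NA`.
#'
#' @param substrate formula or compound name.
#' @param substrateUmol substrate added (umol).
#' @param measuredUmol measured CH4 (umol).
#' @param ceilingUmol reductant ceiling (umol CH4), optional.
#' @param reductantUmol cysteine added (umol), optional alternative.
#' @param label optional culture label.
#' @return one-row data.frame: `culture`, `substrate`, `substrate_umol`,
#'   `measured_ch4_umol`, `theoretical_ch4_umol`, `percent_conversion`,
#'   `percent_rounded`, `reductant_ceiling_umol`, `verdict`.
#' @examples
#' assessConversion("stearate", 30, 384, ceilingUmol = 107)
#' @export
assessConversion <- function(substrate, substrateUmol, measuredUmol,
                             ceilingUmol = NA_real_, reductantUmol = NA_real_,
                             label = NA_character_) {
    f <- .asFormula(substrate)
    pc <- percentConversion(measuredUmol, f, substrateUmol)
    if (!is.na(ceilingUmol) && !is.na(reductantUmol))
        stop("supply either ceilingUmol or reductantUmol, not both")
    ceiling <- if (!is.na(reductantUmol)) reductantCeiling(reductantUmol)
               else ceilingUmol
    verdict <- if (is.na(ceiling)) NA_character_
               else attributeMethaneSource(measuredUmol, ceiling)$verdict
    data.frame(culture = if (is.na(label)) formatFormula(f) else label,
               substrate = formatFormula(f),
               substrate_umol = substrateUmol,
               measured_ch4_umol = measuredUmol,
               theoretical_ch4_umol = pc$theoretical_umol,
               percent_conversion = pc$percent,
               percent_rounded = pc$percent_rounded,
               reductant_ceiling_umol = ceiling,
               verdict = verdict,
               stringsAsFactors = FALSE)
}
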