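#' Derive a disorder-subtype prevalence
#'
#' Multiplies a base prevalence by the fraction of cases belonging to the
#' subtype of interest and truncates (toward zero) at a given number of
#' significant figures — truncation rather than rounding, so the reported
#' prevalence never overstates the product (0.036 x 0.82 = 0.02952 is
#' reported as 0.029, not 0.030). For idiopathic speech delay the inputs are
#' a 3.6\% prevalence of speech delay in 4-8-year-olds of which 82\% have no
#' motor speech disorder, giving 2.9\%.
#'
#' @param basePrevalence fraction in (0, 1], prevalence of the broader
#'   disorder.
#' @param subtypeFraction fraction in (0, 1], share of cases in the subtype.
#' @param sigFigs integer, significant figures kept in the reported value.
#' @return The subtype prevalence as a fraction.
#' @examples
#' derivePrevalence(0.036, 0.82)  # 0.029
#' @export
derivePrevalence <- function(basePrevalence, subtypeFraction, sigFigs = 2L) {
  stopifnot(length(basePrevalence) == 1L, length(subtypeFraction) == 1L)
  if (!is.finite(basePrevalence) || basePrevalence <= 0 || basePrevalence > 1)
    stop("basePrevalence must be in (0, 1]")
  if (!is.finite(subtypeFraction) || subtypeFraction <= 0 ||
      subtypeFraction > 1)
    stop("subtypeFraction must be in (0, 1]")
  x <- basePrevalence * subtypeFraction
  scale <- 10^(sigFigs - 1L - floor(log10(x)))
  trunc(x * scale + 1e-9) / scale  # epsilon guards exact products
}

#' Maximum credible population allele frequency
#'
#' The highest frequency a truly causal variant could plausibly reach in a
#' population database, given disease prevalence, allelic heterogeneity (the
#' maximum share of cases attributable to any one variant) and penetrance.
#' Under a monoallelic (heterozygous-carrier) model the ceiling is
#' \deqn{AF_{max} = \frac{prevalence \times heterogeneity}{2 \times
#' penetrance}} the factor 2 converting a genotype (carrier) frequency into
#' an allele frequency. With the study's inputs (prevalence 0.029,
#' heterogeneity 0.02, penetrance 0.90) the ceiling is 3.2e-4 to two
#' significant figures; full precision is returned and rounding is left to
#' the caller (comparisons in the cascade use the unrounded value).
#'
#' @param prevalence fraction in (0, 1].
#' @param heterogeneity fraction in (0, 1], maximum proportion of cases
#'   explained by a single variant.
#' @param penetrance fraction in (0, 1].
#' @param inheritance only `"monoallelic"` is supported.
#' @return The allele-frequency ceiling (full precision).
#' @examples
#' signif(maxCredibleAF(0.029, 0.02, 0.90), 2)  # 3.2e-04
#' @export
maxCredibleAF <- function(prevalence, heterogeneity, penetrance,
                          inheritance = "monoallelic") {
  inheritance <- match.arg(inheritance)
  for (x in list(prevalence, heterogeneity, penetrance))
    if (length(x) != 1L || !is.finite(x) || x <= 0 || x > 1)
      stop("prevalence, heterogeneity and penetrance must be in (0, 1]")
  prevalence * heterogeneity / (2 * penetrance)
}

#' Sensitivity grid for the allele-frequency ceiling
#'
#' Evaluates [maxCredibleAF()] over the Cartesian grid of supplied parameter
#' values, for exploring how sensitive the ceiling is to the (uncertain)
#' prevalence, heterogeneity and penetrance inputs.
#'
#' @param prevalence,heterogeneity,penetrance numeric vectors of fractions.
#' @param sigFigs significant figures for the displayed ceiling.
#' @return data.frame with one row per parameter combination and columns
#'   `prevalence`, `heterogeneity`, `penetrance`, `ceiling` (full precision),
#'   `ceiling_display` (rounded).
#' @examples
#' afSensitivityGrid(c(0.02, 0.029), 0.02, c(0.5, 0.9))
#' @export
afSensitivityGrid <- function(prevalence, heterogeneity, penetrance,
                              sigFigs = 2L) {
  g <- expand.grid(prevalence = prevalence, heterogeneity = heterogeneity,
                   penetrance = penetrance, KEEP.OUT.ATTRS = FALSE)
  g$ceiling <- mapply(maxCredibleAF, g$prevalence, g$heterogeneity,
                      g$penetrance)
  g$ceiling_display <- signif(g$ceiling, sigFigs)
  g
}

#' Build a filter configuration
#'
#' Returns a [FilterConfig-class] holding every threshold of the cascade,
#' defaulting to the study's values. The allele-frequency ceiling defaults to
#' `signif(maxCredibleAF(derivePrevalence(0.036, 0.82), 0.02, 0.90), 2)`.
#'
#' @param mafCeiling,minReadsPerAllele,pliMin,misZMin,gerpMin,revelMin
#'   numeric thresholds; see [FilterConfig-class].
#' @param nmdEndWindowBp,denovoRevelToleratedMax,denovoMisZMin numeric
#'   thresholds; see [FilterConfig-class].
#' @param applyReadQcToParents,requireZeroParentAltReads,toleranceNaBlocks
#'   logical switches; see [FilterConfig-class].
#' @return A validated [FilterConfig-class] object.
#' @examples
#' filterConfig()
#' filterConfig(toleranceNaBlocks = FALSE)
#' @export
filterConfig <- function(mafCeiling = signif(maxCredibleAF(
                           derivePrevalence(0.036, 0.82), 0.02, 0.90), 2L),
                         minReadsPerAllele = 4L,
                         pliMin = 0.9,
                         misZMin = 2.5,
                         gerpMin = 2,
                         revelMin = 0.5,
                         nmdEndWindowBp = 50L,
                         denovoRevelToleratedMax = 0.25,
                         denovoMisZMin = 3,
                         applyReadQcToParents = FALSE,
                         requireZeroParentAltReads = TRUE,
                         toleranceNaBlocks = TRUE) {
  new("FilterConfig",
      mafCeiling = mafCeiling,
      minReadsPerAllele = as.integer(minReadsPerAllele),
      pliMin = pliMin, misZMin = misZMin, gerpMin = gerpMin,
      revelMin = revelMin, nmdEndWindowBp = as.integer(nmdEndWindowBp),
      denovoRevelToleratedMax = denovoRevelToleratedMax,
      denovoMisZMin = denovoMisZMin,
      applyReadQcToParents = applyReadQcToParents,
      requireZeroParentAltReads = requireZeroParentAltReads,
      toleranceNaBlocks = toleranceNaBlocks)
}
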