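# Isotope constants (CIAAW/NIST): exact masses in Da, natural abundances as
# fractions. Each element's abundances sum to 1 within 1e-6 and masses
# strictly increase with mass number; both are enforced by .checkElements()
# at load time.

.ELEMENTS <- list(
  H  = list(massnum = c(1L, 2L),
            mass = c(1.00782503207, 2.0141017778),
            abundance = c(0.999885, 0.000115)),
  C  = list(massnum = c(12L, 13L),
            mass = c(12.0, 13.0033548378),
            abundance = c(0.9893, 0.0107)),
  N  = list(massnum = c(14L, 15L),
            mass = c(14.0030740048, 15.0001088982),
            abundance = c(0.99636, 0.00364)),
  O  = list(massnum = c(16L, 17L, 18L),
            mass = c(15.99491461956, 16.99913170, 17.9991610),
            abundance = c(0.99757, 0.00038, 0.00205)),
  S  = list(massnum = c(32L, 33L, 34L, 36L),
            mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P  = list(massnum = 31L, mass = 30.97376163, abundance = 1.0),
  F  = list(massnum = 19L, mass = 18.99840322, abundance = 1.0),
  I  = list(massnum = 127L, mass = 126.904473, abundance = 1.0),
  Na = list(massnum = 23L, mass = 22.9897692809, abundance = 1.0),
  K  = list(massnum = c(39L, 40L, 41L),
            mass = c(38.96370668, 39.96399848, 40.96182576),
            abundance = c(0.932581, 0.000117, 0.067302)),
  Cl = list(massnum = c(35L, 37L),
            mass = c(34.96885268, 36.96590259),
            abundance = c(0.7576, 0.2424)),
  Br = list(massnum = c(79L, 81L),
            mass = c(78.9183371, 80.9162906),
            abundance = c(0.5069, 0.4931)),
  Si = list(massnum = c(28L, 29L, 30L),
            mass = c(27.97692653, 28.97649470, 29.97377017),
            abundance = c(0.92223, 0.04685, 0.03092)),
  B  = list(massnum = c(10L, 11L),
            mass = c(10.0129370, 11.0093054),
            abundance = c(0.199, 0.801)),
  Li = list(massnum = c(6L, 7L),
            mass = c(6.015122795, 7.01600455),
            abundance = c(0.0759, 0.9241)),
  Mg = list(massnum = c(24L, 25L, 26L),
            mass = c(23.98504170, 24.98583692, 25.98259293),
            abundance = c(0.7899, 0.1000, 0.1101)),
  Ca = list(massnum = c(40L, 42L, 43L, 44L, 46L, 48L),
            mass = c(39.96259098, 41.95861801, 42.9587666, 43.9554818,
                     45.9536926, 47.952534),
            abundance = c(0.96941, 0.00647, 0.00135, 0.02086, 0.00004,
                          0.00187)),
  Fe = list(massnum = c(54L, 56L, 57L, 58L),
            mass = c(53.9396105, 55.9349375, 56.9353940, 57.9332756),
            abundance = c(0.05845, 0.91754, 0.02119, 0.00282)),
  Cu = list(massnum = c(63L, 65L),
            mass = c(62.9295975, 64.9277895),
            abundance = c(0.6915, 0.3085)),
  Zn = list(massnum = c(64L, 66L, 67L, 68L, 70L),
            mass = c(63.9291422, 65.9260334, 66.9271273, 67.9248442,
                     69.9253193),
            abundance = c(0.4917, 0.2773, 0.0404, 0.1845, 0.0061)),
  Se = list(massnum = c(74L, 76L, 77L, 78L, 80L, 82L),
            mass = c(73.9224764, 75.9192136, 76.9199140, 77.9173091,
                     79.9165213, 81.9166994),
            abundance = c(0.0089, 0.0937, 0.0763, 0.2377, 0.4961, 0.0873))
)

#' @keywords internal
.ELECTRON_MASS <- 0.00054857990907
#' @keywords internal
.PROTON_MASS <- 1.007276466621
# 13C - 12C; canonical isotopologue spacing
.ISOTOPE_SPACING <- 1.0033548378

.checkElements <- function(tab = .ELEMENTS) {
  for (sym in names(tab)) {
    e <- tab[[sym]]
    if (abs(sum(e$abundance) - 1) > 1e-6)
      stop("abundances of ", sym, " do not sum to 1")
    if (is.unsorted(e$mass, strictly = TRUE))
      stop("isotope masses of ", sym, " not strictly increasing")
    if (is.unsorted(e$massnum, strictly = TRUE))
      stop("mass numbers of ", sym, " not strictly increasing")
  }
  invisible(TRUE)
}

#' Element and isotope table
#'
#' Returns the built-in table of elements known to the package with, per
#' element, the nominal mass numbers, exact isotope masses (Da) and natural
#' abundances (fractions summing to 1).
#'
#' @return A data.frame with columns `symbol`, `massnum`, `mass`,
#'   `abundance`, one row per isotope.
#' @examples
#' head(elementTable())
#' @export
elementTable <- function() {
  do.call(rbind, lapply(names(.ELEMENTS), function(sym) {
    e <- .ELEMENTS[[sym]]
    data.frame(symbol = sym, massnum = e$massnum, mass = e$mass,
               abundance = e$abundance)
  }))
}

# most abundant isotope mass (monoisotopic convention) for one element
.monoMass <- function(sym) {
  e <- .ELEMENTS[[sym]]
  e$mass[which.max(e$abundance)]
}

.avgMass <- function(sym) {
  e <- .ELEMENTS[[sym]]
  sum(e$mass * e$abundance)
}
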