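# Molecular-formula parsing, exact masses, isotope-pattern convolution and
# adduct arithmetic.

#' Parse a molecular formula
#'
#' Parses formula strings built from element tokens with optional integer
#' counts (`"C6H12O6"`), parenthesized groups with multipliers
#' (`"Mg(OH)2"`), and isotope prefixes in square brackets
#' (`"[13]C6"` = six carbon-13 atoms). Charge notation is rejected: charges
#' belong to [Adduct-class] objects, which keeps formula algebra closed
#' under addition.
#'
#' @param text A formula string.
#' @return A [MolecularFormula-class].
#' @examples
#' parseFormula("C6H13NO2")           # leucine / isoleucine
#' parseFormula("[13]C2C4H13NO2")     # doubly 13C-labelled
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  pos <- 1L
  n <- nchar(s)

  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  take <- function() { ch <- peek(); pos <<- pos + 1L; ch }
  fail <- function(msg) stop("formula parse error in '", text, "': ", msg,
                             call. = FALSE)

  readInt <- function() {
    start <- pos
    while (grepl("^[0-9]$", peek())) pos <<- pos + 1L
    if (pos == start) return(NA_integer_)
    as.integer(substr(s, start, pos - 1L))
  }

  # group := (item)* ; item := isotope? element count? | "(" group ")" count?
  parseGroup <- function(depth) {
    counts <- integer(0)
    add <- function(key, k) {
      counts[key] <<- if (key %in% names(counts)) counts[[key]] + k else k
    }
    repeat {
      ch <- peek()
      if (ch == "" || ch == ")") break
      if (ch == "(") {
        take()
        inner <- parseGroup(depth + 1L)
        if (peek() != ")") fail("unbalanced parentheses")
        take()
        mult <- readInt()
        if (is.na(mult)) mult <- 1L
        if (mult == 0L) fail("group multiplier 0")
        for (key in names(inner)) add(key, inner[[key]] * mult)
      } else if (ch == "[") {
        take()
        iso <- readInt()
        if (is.na(iso)) fail("expected mass number after '['")
        if (peek() != "]") fail("expected ']' after mass number")
        take()
        sym <- readElement()
        cnt <- readInt()
        if (is.na(cnt)) cnt <- 1L
        if (cnt == 0L) fail(paste0("count 0 for [", iso, "]", sym))
        if (!sym %in% names(.ELEMENTS)) fail(paste("unknown element:", sym))
        if (!iso %in% .ELEMENTS[[sym]]$massnum)
          fail(paste0("unknown isotope: [", iso, "]", sym))
        add(paste0("[", iso, "]", sym), cnt)
      } else if (grepl("^[A-Z]$", ch)) {
        sym <- readElement()
        cnt <- readInt()
        if (is.na(cnt)) cnt <- 1L
        if (cnt == 0L) fail(paste("count 0 for", sym))
        if (!sym %in% names(.ELEMENTS)) fail(paste("unknown element:", sym))
        add(sym, cnt)
      } else {
        fail(paste0("unexpected character '", ch, "'"))
      }
    }
    counts
  }

  readElement <- function() {
    if (!grepl("^[A-Z]$", peek())) fail("expected element symbol")
    sym <- take()
    if (grepl("^[a-z]$", peek())) sym <- paste0(sym, take())
    sym
  }

  counts <- parseGroup(0L)
  if (peek() == ")") fail("unbalanced parentheses")
  new("MolecularFormula", counts = .orderCounts(counts))
}

# canonical key order: Hill-like (C, H, then alphabetical), fixed isotopes
# directly after their element
.orderCounts <- function(counts) {
  if (!length(counts)) return(integer(0))
  sym <- sub("^\\[[0-9]+\\]", "", names(counts))
  iso <- suppressWarnings(as.integer(gsub("\\[|\\]", "",
           regmatches(names(counts),
                      regexpr("^\\[[0-9]+\\]", names(counts))))))
  isoRank <- rep(0L, length(counts))
  hasIso <- grepl("^\\[", names(counts))
  isoRank[hasIso] <- iso
  rank <- match(sym, c("C", "H"), nomatch = 3L)
  counts[order(rank, sym, isoRank)]
}

#' Render a formula as a string
#'
#' Inverse of [parseFormula()]: `parseFormula(formulaString(f))` is
#' identical to `f`.
#'
#' @param f A [MolecularFormula-class].
#' @return A formula string in canonical (Hill-like) order.
#' @export
formulaString <- function(f) {
  stopifnot(is(f, "MolecularFormula"))
  if (!length(f@counts)) return("")
  paste0(names(f@counts),
         ifelse(f@counts > 1L, as.character(f@counts), ""),
         collapse = "")
}

#' Atom counts of a formula
#' @param f A [MolecularFormula-class].
#' @return Named integer vector; isotope-fixed atoms keep their
#'   `"[13]C"`-style keys.
#' @export
atomCounts <- function(f) {
  stopifnot(is(f, "MolecularFormula"))
  f@counts
}

#' @describeIn parseFormula Formula addition combines compositions;
#'   commutative and associative.
#' @param e1,e2 [MolecularFormula-class] objects.
#' @export
setMethod("+", signature("MolecularFormula", "MolecularFormula"),
  function(e1, e2) {
    counts <- e1@counts
    for (key in names(e2@counts)) {
      counts[key] <- if (key %in% names(counts))
        counts[[key]] + e2@counts[[key]] else e2@counts[[key]]
    }
    new("MolecularFormula", counts = .orderCounts(counts))
  })

setMethod("show", "MolecularFormula", function(object) {
  cat("MolecularFormula:", formulaString(object), "\n")
})

# resolve a composition key to (element record, fixed isotope index or NA)
.resolveKey <- function(key) {
  sym <- sub("^\\[[0-9]+\\]", "", key)
  e <- .ELEMENTS[[sym]]
  if (grepl("^\\[", key)) {
    iso <- as.integer(gsub("\\[|\\]", "",
             regmatches(key, regexpr("^\\[[0-9]+\\]", key))))
    list(element = e, isoIdx = match(iso, e$massnum))
  } else {
    list(element = e, isoIdx = NA_integer_)
  }
}

#' Monoisotopic mass
#'
#' Sum over atoms of the most-abundant-isotope exact mass; atoms with a
#' fixed mass number contribute that isotope's mass. Additive over formula
#' addition. Mass isomers such as leucine and isoleucine (both C6H13NO2)
#' have identical monoisotopic mass and are separable only
#' chromatographically.
#'
#' @param x A [MolecularFormula-class] or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopicMass("H2O")       # 18.010565
#' monoisotopicMass("C6H13NO2")  # 131.094629
#' @export
setMethod("monoisotopicMass", "MolecularFormula", function(x) {
  if (!length(x@counts)) return(0)
  sum(vapply(names(x@counts), function(key) {
    r <- .resolveKey(key)
    m <- if (is.na(r$isoIdx)) r$element$mass[which.max(r$element$abundance)]
         else r$element$mass[r$isoIdx]
    m * x@counts[[key]]
  }, numeric(1)))
})

#' @rdname monoisotopicMass
#' @export
setMethod("monoisotopicMass", "character",
          function(x) monoisotopicMass(parseFormula(x)))

#' Average (abundance-weighted) mass
#'
#' Natural-abundance-weighted mean isotope mass per element, summed over
#' the composition; at least the monoisotopic mass for typical organic
#' formulas. Fixed-isotope atoms contribute exactly their isotope's mass.
#'
#' @param x A [MolecularFormula-class] or a formula string.
#' @return Mass in Da.
#' @export
setMethod("averageMass", "MolecularFormula", function(x) {
  if (!length(x@counts)) return(0)
  sum(vapply(names(x@counts), function(key) {
    r <- .resolveKey(key)
    m <- if (is.na(r$isoIdx)) sum(r$element$mass * r$element$abundance)
         else r$element$mass[r$isoIdx]
    m * x@counts[[key]]
  }, numeric(1)))
})

#' @rdname averageMass
#' @export
setMethod("averageMass", "character",
          function(x) averageMass(parseFormula(x)))

# convolve two (mass, abundance) patterns; merge entries closer than mergeTol
# by abundance-weighted mass; prune below threshold, tracking pruned mass
.convolve <- function(p1, p2, threshold, mergeTol = 1e-9) {
  mass <- as.vector(outer(p1$mass, p2$mass, "+"))
  ab <- as.vector(outer(p1$abundance, p2$abundance, "*"))
  o <- order(mass)
  mass <- mass[o]; ab <- ab[o]
  # merge near-identical masses
  if (length(mass) > 1L) {
    grp <- cumsum(c(TRUE, diff(mass) > mergeTol))
    ab2 <- as.vector(tapply(ab, grp, sum))
    m2 <- as.vector(tapply(mass * ab, grp, sum)) / ab2
    mass <- m2; ab <- ab2
  }
  keep <- ab >= threshold
  list(mass = mass[keep], abundance = ab[keep],
       pruned = sum(ab[!keep]))
}

# single-atom pattern for a composition key
.atomPattern <- function(key) {
  r <- .resolveKey(key)
  if (is.na(r$isoIdx))
    list(mass = r$element$mass, abundance = r$element$abundance)
  else
    list(mass = r$element$mass[r$isoIdx], abundance = 1.0)
}

#' Isotope pattern by convolution
#'
#' Computes the isotopologue distribution of a formula by convolving the
#' per-element isotope distributions over the composition. Entries within
#' 1e-9 Da are merged by abundance-weighted mass. Pruning below
#' `minAbundance` is applied after every convolution step (bounding memory)
#' and the total pruned abundance is tracked, so
#' `sum(abundance) >= 1 - prunedAbundance` always holds. Abundances are
#' absolute (sum <= 1), not max-normalized.
#'
#' @param x A [MolecularFormula-class] or a formula string.
#' @param minAbundance Pruning threshold in \[0, 1).
#' @return An [IsotopePattern-class] sorted by ascending mass.
#' @examples
#' isotopePattern("C6H12O6", minAbundance = 1e-4)
#' @export
setMethod("isotopePattern", "MolecularFormula",
  function(x, minAbundance = 1e-4) {
    stopifnot(minAbundance >= 0, minAbundance < 1)
    pat <- list(mass = 0, abundance = 1)
    pruned <- 0
    for (key in names(x@counts)) {
      ap <- .atomPattern(key)
      k <- x@counts[[key]]
      for (i in seq_len(k)) {
        pat <- .convolve(pat, ap, minAbundance)
        pruned <- pruned + pat$pruned
        if (!length(pat$mass))
          stop("isotope pattern fully pruned; lower minAbundance")
      }
    }
    new("IsotopePattern", mass = pat$mass, abundance = pat$abundance,
        pruned = pruned, threshold = minAbundance)
  })

#' @rdname isotopePattern
#' @export
setMethod("isotopePattern", "character",
  function(x, minAbundance = 1e-4)
    isotopePattern(parseFormula(x), minAbundance = minAbundance))

#' @describeIn isotopePattern Masses (Da) of the pattern entries.
#' @param p An [IsotopePattern-class].
#' @export
patternMass <- function(p) p@mass

#' @describeIn isotopePattern Absolute abundances of the pattern entries.
#' @export
patternAbundance <- function(p) p@abundance

#' @describeIn isotopePattern Total abundance removed by pruning.
#' @export
prunedAbundance <- function(p) p@pruned

setMethod("show", "IsotopePattern", function(object) {
  cat(sprintf("IsotopePattern: %d entries, pruned %.3g (threshold %.3g)\n",
              length(object@mass), object@pruned, object@threshold))
  k <- min(length(object@mass), 8L)
  for (i in seq_len(k))
    cat(sprintf("  %12.6f  %.6g\n", object@mass[i], object@abundance[i]))
  if (length(object@mass) > k) cat("  ...\n")
})

#' Construct an adduct
#'
#' @param name Display name, e.g. `"[M+H]+"`.
#' @param delta Mass delta in Da (must already account for electrons).
#' @param charge Signed integer charge, non-zero.
#' @param multiplier Molecular multiplier, >= 1.
#' @return An [Adduct-class].
#' @export
adduct <- function(name, delta, charge, multiplier = 1L) {
  new("Adduct", name = as.character(name), delta = as.numeric(delta),
      charge = as.integer(charge), multiplier = as.integer(multiplier))
}

setMethod("show", "Adduct", function(object) {
  cat(sprintf("Adduct %s: delta %+0.6f Da, z %+d, multiplier %d\n",
              object@name, object@delta, object@charge, object@multiplier))
})

#' m/z of an ionized molecule
#'
#' `(multiplier * M + delta) / |charge|` for a neutral monoisotopic mass M.
#'
#' @param neutralMass Neutral monoisotopic mass in Da, > 0.
#' @param adduct An [Adduct-class].
#' @return The m/z value.
#' @examples
#' adductMz(monoisotopicMass("H2O"), defaultAdducts()[["[M+H]+"]])
#' @export
adductMz <- function(neutralMass, adduct) {
  stopifnot(is(adduct, "Adduct"), neutralMass > 0)
  if (adduct@charge == 0L) stop("adduct charge must be non-zero")
  (adduct@multiplier * neutralMass + adduct@delta) / abs(adduct@charge)
}

# Build the default ESI adduct library from element masses so the deltas
# stay consistent with the isotope table. gain/loss are atom compositions;
# charge carriers add/remove electrons.
.makeAdducts <- function() {
  mono <- function(txt) if (nzchar(txt)) monoisotopicMass(txt) else 0
  d <- function(gain, loss, z) mono(gain) - mono(loss) - z * .ELECTRON_MASS
  specs <- list(
    list("[M+H]+",       "H",      "",    +1L, 1L),
    list("[M+Na]+",      "Na",     "",    +1L, 1L),
    list("[M+K]+",       "K",      "",    +1L, 1L),
    list("[M+NH4]+",     "NH4",    "",    +1L, 1L),
    list("[M+H-H2O]+",   "H",      "H2O", +1L, 1L),
    list("[M+CH3OH+H]+", "CH4OH",  "",    +1L, 1L),
    list("[M+CH3CN+H]+", "C2H3NH", "",    +1L, 1L),
    list("[M]+",         "",       "",    +1L, 1L),
    list("[M+2H]2+",     "H2",     "",    +2L, 1L),
    list("[M+H+Na]2+",   "HNa",    "",    +2L, 1L),
    list("[2M+H]+",      "H",      "",    +1L, 2L),
    list("[2M+Na]+",     "Na",     "",    +1L, 2L),
    list("[M-H]-",       "",       "H",   -1L, 1L),
    list("[M+Cl]-",      "Cl",     "",    -1L, 1L),
    list("[M+HCOO]-",    "CHO2",   "",    -1L, 1L),
    list("[M-H2O-H]-",   "",       "H3O", -1L, 1L),
    list("[M+Na-2H]-",   "Na",     "H2",  -1L, 1L),
    list("[M+K-2H]-",    "K",      "H2",  -1L, 1L),
    list("[M-2H]2-",     "",       "H2",  -2L, 1L),
    list("[2M-H]-",      "",       "H",   -1L, 2L)
  )
  out <- lapply(specs, function(sp)
    adduct(sp[[1]], d(sp[[2]], sp[[3]], sp[[4]]), sp[[4]], sp[[5]]))
  names(out) <- vapply(out, function(a) a@name, character(1))
  out
}

#' Default ESI adduct library
#'
#' A fixed list of 20 common electrospray adducts with mass deltas derived
#' from the package's isotope table (electron mass included, so singly
#' protonated species use the proton mass 1.007276 Da, not the hydrogen
#' atom mass).
#'
#' @return Named list of [Adduct-class] objects.
#' @seealso [readAdducts()] to load or override from a file.
#' @export
defaultAdducts <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- .makeAdducts()
    cache
  }
})

#' Read an adduct library from a delimited file
#'
#' The file must have a header `name, delta_da, charge, multiplier`
#' (comma- or tab-separated).
#'
#' @param path Path to the file.
#' @return Named list of [Adduct-class] objects.
#' @export
readAdducts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sniffSep(path),
                          stringsAsFactors = FALSE)
  need <- c("name", "delta_da", "charge", "multiplier")
  if (!all(need %in% names(df)))
    stop("adduct file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    adduct(df$name[i], df$delta_da[i], df$charge[i], df$multiplier[i]))
  names(out) <- df$name
  out
}

.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}
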