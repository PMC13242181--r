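# Shared fixtures and independent oracles used across the suite.

# one-time proteowizard warm-up (its first open emits an informational
# warning that would otherwise surface inside a test)
local({
  p <- tempfile(fileext = ".mzML")
  writeMzML(peakMap(), p)
  suppressWarnings(invisible(readMzML(p)))
  unlink(p)
})

# simple peakmap: one m/z channel per compound, Gaussian traces on a grid
makeGaussianMap <- function(mzs, areas, mus, sigma = 2,
                            interval = 0.5, span = c(0, 600),
                            baseline = 0) {
  grid <- seq(span[1], span[2], by = interval)
  specs <- lapply(grid, function(t) {
    v <- areas * stats::dnorm(t, mus, sigma) + baseline
    keep <- v > 0
    spectrum(rt = t, mz = mzs[keep], intensity = v[keep])
  })
  peakMap(spectra = specs)
}

# ---- random tables and a naive list-of-rows oracle engine -----------------

randomTable <- function(seed, maxRows = 100L, mode = "memory") {
  set.seed(seed)
  n <- sample.int(maxRows, 1L)
  cols <- list(
    id = list(type = "integer", gen = function(n) {
      v <- sample.int(1000L, n, replace = TRUE)
      v[stats::runif(n) < 0.1] <- NA
      v
    }),
    x = list(type = "real", gen = function(n) {
      v <- round(stats::rnorm(n), 3)
      v[stats::runif(n) < 0.1] <- NA
      v
    }),
    grp = list(type = "text", gen = function(n) {
      v <- sample(c("a", "b", "c"), n, replace = TRUE)
      v[stats::runif(n) < 0.1] <- NA
      v
    }),
    flag = list(type = "boolean", gen = function(n) {
      v <- sample(c(TRUE, FALSE), n, replace = TRUE)
      v[stats::runif(n) < 0.1] <- NA
      v
    }))
  data <- lapply(cols, function(c) c$gen(n))
  createTable(names(cols), vapply(cols, `[[`, character(1), "type"),
              rows = data, mode = mode)
}

# scalar strict-missing expression evaluation on one row (independent of
# the package's vectorized evaluator)
oracleEvalRow <- function(node, row) {
  ev <- function(x) oracleEvalRow(x, row)
  switch(node$kind,
    col = row[[node$name]],
    lit = node$value,
    ismissing = is.na(ev(node$arg)),
    unop = {
      v <- ev(node$arg)
      if (node$op != "!" && is.na(v)) return(v)
      switch(node$op, "!" = if (is.na(v)) NA else !v, "-" = -v, "+" = v)
    },
    binop = {
      l <- ev(node$left); r <- ev(node$right)
      if (is.na(l) || is.na(r))
        return(NA)
      switch(node$op,
        "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r,
        "^" = l ^ r, "%%" = l %% r, "%/%" = l %/% r,
        "==" = l == r, "!=" = l != r, "<" = l < r, "<=" = l <= r,
        ">" = l > r, ">=" = l >= r, "&" = l && r, "|" = l || r)
    })
}

oracleFilter <- function(df, e) {
  keep <- vapply(seq_len(nrow(df)), function(r) {
    v <- oracleEvalRow(e@node, lapply(df, `[`, r))
    !is.na(v) && isTRUE(v)
  }, logical(1))
  df[keep, , drop = FALSE]
}

oracleJoin <- function(ldf, rdf, e, suffix = "__1", left = FALSE) {
  rn <- ifelse(names(rdf) %in% names(ldf), paste0(names(rdf), suffix),
               names(rdf))
  names(rdf) <- rn
  out <- NULL
  for (i in seq_len(nrow(ldf))) {
    lrow <- lapply(ldf, `[`, i)
    hits <- which(vapply(seq_len(nrow(rdf)), function(j) {
      v <- oracleEvalRow(e@node, c(lrow, lapply(rdf, `[`, j)))
      !is.na(v) && isTRUE(v)
    }, logical(1)))
    if (length(hits)) {
      block <- cbind(ldf[rep(i, length(hits)), , drop = FALSE],
                     rdf[hits, , drop = FALSE])
      out <- rbind(out, block)
    } else if (left) {
      na <- rdf[NA_integer_, , drop = FALSE]
      out <- rbind(out, cbind(ldf[i, , drop = FALSE], na))
    }
  }
  if (is.null(out)) out <- cbind(ldf[0, , drop = FALSE],
                                 rdf[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

oracleAggregate <- function(df, keys, aggs) {
  keyStr <- if (length(keys))
    apply(df[keys], 1, function(r)
      paste(ifelse(is.na(r), "\x01NA", paste0("v", r)), collapse = "\x1f"))
  else rep("", nrow(df))
  seen <- unique(keyStr)
  out <- NULL
  for (ks in seen) {
    rows <- df[keyStr == ks, , drop = FALSE]
    rec <- rows[1, keys, drop = FALSE]
    for (nm in names(aggs)) {
      fun <- aggs[[nm]][1]; cl <- aggs[[nm]][2]
      v <- rows[[cl]]
      v <- v[!is.na(v)]
      rec[[nm]] <- switch(fun,
        count = length(v),
        sum = if (length(v)) sum(as.numeric(v)) else NA,
        mean = if (length(v)) mean(as.numeric(v)) else NA,
        min = if (length(v)) min(v) else NA,
        max = if (length(v)) max(v) else NA,
        median = if (length(v)) stats::median(as.numeric(v)) else NA,
        first = if (length(v)) v[1] else NA)
    }
    out <- rbind(out, rec)
  }
  rownames(out) <- NULL
  out
}

# compare an MzTable with an oracle data.frame, value-wise with type
# coercion (oracle aggregation may return doubles where the engine keeps
# integers)
expectTableEqualsDf <- function(t, df) {
  got <- asDataFrame(t)
  expect_equal(nrow(got), nrow(df))
  expect_equal(names(got), names(df))
  for (nm in names(df)) {
    g <- got[[nm]]; o <- df[[nm]]
    if (is.numeric(g) || is.numeric(o)) {
      expect_equal(as.numeric(g), as.numeric(o), tolerance = 1e-12)
    } else {
      expect_identical(as.character(g), as.character(o))
    }
  }
}

# amino-acid target list used by the workflow tests: two references plus
# the co-eluting mass-isomer pair (same formula, distinct rt windows)
aminoAcidTargets <- function(rtTol = 6) {
  data.frame(
    name = c("Gly", "Ala", "Val", "LeuA", "IleA"),
    formula = c("C2H5NO2", "C3H7NO2", "C5H11NO2", "C6H13NO2",
                "C6H13NO2"),
    adduct = "[M+H]+",
    rt_sec = c(100, 170, 240, 300, 320),
    rt_tol_sec = rtTol,
    mz_tol = 10, mz_tol_unit = "ppm",
    role = c("reference", "reference", "reference", "analyte",
             "analyte"),
    stringsAsFactors = FALSE)
}

makeIntegratedPeakTable <- function(nPeaks = 6, seed = 1) {
  set.seed(seed)
  mzs <- seq(150, 150 + nPeaks - 1)
  mus <- seq(100, by = 40, length.out = nPeaks)
  areas <- runif(nPeaks, 5e3, 5e4)
  pm <- makeGaussianMap(mzs, areas, mus, sigma = 2, interval = 0.5,
                        span = c(50, 100 + 40 * nPeaks))
  pt <- createTable(
    c("id", "mzmin", "mzmax", "rtmin", "rtmax", "peakmap"),
    c("integer", "real", "real", "real", "real", "peakmap"))
  key <- registerRef(pt, pm)
  rows <- lapply(seq_len(nPeaks), function(i)
    list(i, mzs[i] - 0.01, mzs[i] + 0.01, mus[i] - 8, mus[i] + 8, key))
  pt <- createTable(columnNames(pt), columnTypes(pt), rows,
                    registry = pt@registry)
  list(pt = pt, areas = areas, mus = mus, pm = pm, key = key)
}

aminoAcidCompounds <- function() {
  tg <- aminoAcidTargets()
  simCompounds(name = tg$name, formula = tg$formula,
               area = c(2e5, 3e5, 2.5e5, 1e5, 1.5e5),
               rt = tg$rt_sec, sigma = 2)
}
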