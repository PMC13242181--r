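# mzML input (through mzR/proteowizard) and output (generated directly so
# SRM chromatograms can be written, which mzR's writer does not support).
# The writer emits indexed mzML with zlib-compressed 64-bit arrays; the
# reader accepts 32-bit and uncompressed arrays as well (proteowizard
# handles decoding).

.b64encode <- function(x) {
  r <- writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
  base64enc::base64encode(memCompress(r, "gzip"))  # zlib stream
}

.binaryXml <- function(x, what = c("mz", "int", "time")) {
  what <- match.arg(what)
  cv <- switch(what,
    mz = paste0('<cvParam cvRef="MS" accession="MS:1000514" ',
                'name="m/z array" unitCvRef="MS" unitAccession="MS:1000040"',
                ' unitName="m/z"/>'),
    int = paste0('<cvParam cvRef="MS" accession="MS:1000515" ',
                 'name="intensity array" unitCvRef="MS" ',
                 'unitAccession="MS:1000131" ',
                 'unitName="number of detector counts"/>'),
    time = paste0('<cvParam cvRef="MS" accession="MS:1000595" ',
                  'name="time array" unitCvRef="UO" ',
                  'unitAccession="UO:0000010" unitName="second"/>'))
  b <- .b64encode(x)
  paste0('<binaryDataArray encodedLength="', nchar(b), '">',
         '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
         '<cvParam cvRef="MS" accession="MS:1000574" ',
         'name="zlib compression"/>', cv,
         '<binary>', b, '</binary></binaryDataArray>')
}

.spectrumXml <- function(s, index) {
  pol <- if (s@polarity > 0L)
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>'
  else if (s@polarity < 0L)
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan"/>'
  else ""
  prec <- ""
  if (nrow(s@precursors)) {
    ions <- vapply(seq_len(nrow(s@precursors)), function(i) {
      p <- s@precursors[i, ]
      chg <- if (!is.na(p$charge))
        sprintf(paste0('<cvParam cvRef="MS" accession="MS:1000041" ',
                       'name="charge state" value="%d"/>'),
                as.integer(p$charge)) else ""
      iso <- if (!is.na(p$isolationWidth))
        sprintf(paste0('<isolationWindow><cvParam cvRef="MS" ',
                       'accession="MS:1000827" name="isolation window ',
                       'target m/z" value="%.10g" unitCvRef="MS" ',
                       'unitAccession="MS:1000040" unitName="m/z"/>',
                       '<cvParam cvRef="MS" accession="MS:1000828" ',
                       'name="isolation window lower offset" value="%.10g"',
                       ' unitCvRef="MS" unitAccession="MS:1000040" ',
                       'unitName="m/z"/><cvParam cvRef="MS" ',
                       'accession="MS:1000829" name="isolation window ',
                       'upper offset" value="%.10g" unitCvRef="MS" ',
                       'unitAccession="MS:1000040" unitName="m/z"/>',
                       '</isolationWindow>'),
                p$mz, p$isolationWidth, p$isolationWidth) else ""
      sprintf(paste0('<precursor>%s<selectedIonList count="1">',
                     '<selectedIon><cvParam cvRef="MS" ',
                     'accession="MS:1000744" name="selected ion m/z" ',
                     'value="%.10g" unitCvRef="MS" ',
                     'unitAccession="MS:1000040" unitName="m/z"/>%s',
                     '</selectedIon></selectedIonList><activation>',
                     '<cvParam cvRef="MS" accession="MS:1000044" ',
                     'name="dissociation method"/></activation>',
                     '</precursor>'),
              iso, p$mz, chg)
    }, character(1))
    prec <- paste0('<precursorList count="', nrow(s@precursors), '">',
                   paste(ions, collapse = ""), '</precursorList>')
  }
  paste0(
    '<spectrum index="', index, '" id="scan=', index + 1L,
    '" defaultArrayLength="', length(s@mz), '">',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="',
    s@msLevel, '"/>', pol,
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
    '<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum"/>',
    '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" ',
    'name="no combination"/><scan>',
    sprintf(paste0('<cvParam cvRef="MS" accession="MS:1000016" ',
                   'name="scan start time" value="%.12g" unitCvRef="UO" ',
                   'unitAccession="UO:0000010" unitName="second"/>'), s@rt),
    '</scan></scanList>', prec,
    '<binaryDataArrayList count="2">',
    .binaryXml(s@mz, "mz"), .binaryXml(s@intensity, "int"),
    '</binaryDataArrayList></spectrum>')
}

.chromatogramXml <- function(ch, index) {
  id <- switch(ch@kind,
    SRM = sprintf("SRM SIC Q1=%.10g Q3=%.10g", ch@precursorMz,
                  ch@productMz),
    TIC = "TIC",
    EIC = sprintf("EIC %d", index + 1L))
  kindCv <- switch(ch@kind,
    SRM = paste0('<cvParam cvRef="MS" accession="MS:1001473" ',
                 'name="selected reaction monitoring chromatogram"/>'),
    TIC = paste0('<cvParam cvRef="MS" accession="MS:1000235" ',
                 'name="total ion current chromatogram"/>'),
    EIC = paste0('<cvParam cvRef="MS" accession="MS:1000627" ',
                 'name="selected ion current chromatogram"/>'))
  win <- function(mz, acc)
    sprintf(paste0('<isolationWindow><cvParam cvRef="MS" ',
                   'accession="MS:1000827" name="isolation window target ',
                   'm/z" value="%.10g" unitCvRef="MS" ',
                   'unitAccession="MS:1000040" unitName="m/z"/>',
                   '</isolationWindow>'), mz)
  pp <- ""
  if (ch@kind == "SRM")
    pp <- paste0('<precursor>', win(ch@precursorMz),
                 '<activation><cvParam cvRef="MS" accession="MS:1000044" ',
                 'name="dissociation method"/></activation></precursor>',
                 '<product>', win(ch@productMz), '</product>')
  paste0('<chromatogram index="', index, '" id="', id,
         '" defaultArrayLength="', length(ch@rt), '">', kindCv, pp,
         '<binaryDataArrayList count="2">',
         .binaryXml(ch@rt, "time"), .binaryXml(ch@intensity, "int"),
         '</binaryDataArrayList></chromatogram>')
}

#' Write a PeakMap to mzML
#'
#' Emits standards-conformant indexed mzML: 64-bit zlib-compressed binary
#' arrays, a spectrumList and (when chromatograms are present) a
#' chromatogramList, and the trailing index with byte offsets. Values
#' round-trip bit-identically through [readMzML()].
#'
#' @param pm A [PeakMap-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMzML <- function(pm, path) {
  specXml <- vapply(seq_along(pm@spectra), function(i)
    .spectrumXml(pm@spectra[[i]], i - 1L), character(1))
  chXml <- vapply(seq_along(pm@chromatograms), function(i)
    .chromatogramXml(pm@chromatograms[[i]], i - 1L), character(1))

  head1 <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml">\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass ',
    'Spectrometry Ontology" URI="https://raw.githubusercontent.com/',
    'HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.',
    'githubusercontent.com/bio-ontology-research-group/unit-ontology/',
    'master/unit.obo"/></cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>',
    if (length(chXml)) paste0(
      '<cvParam cvRef="MS" accession="MS:1001473" ',
      'name="selected reaction monitoring chromatogram"/>') else "",
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="mzforge" version="0.1.0">',
    '<cvParam cvRef="MS" accession="MS:1000799" ',
    'name="custom unreleased software tool" value="mzforge"/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"><cvParam cvRef="MS" ',
    'accession="MS:1000031" name="instrument model"/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="DP1">',
    '<processingMethod order="1" softwareRef="mzforge">',
    '<cvParam cvRef="MS" accession="MS:1000544" ',
    'name="Conversion to mzML"/></processingMethod></dataProcessing>',
    '</dataProcessingList>\n',
    '<run id="', if (!is.null(pm@metadata$runId)) pm@metadata$runId
                 else "run1",
    '" defaultInstrumentConfigurationRef="IC1">\n')

  parts <- character(0)
  specOffsets <- integer(0)
  chOffsets <- integer(0)
  nbytes <- function(x) nchar(x, type = "bytes")
  pos <- nbytes(head1)
  add <- function(x) { parts <<- c(parts, x); pos <<- pos + nbytes(x) }

  add(paste0('<spectrumList count="', length(specXml),
             '" defaultDataProcessingRef="DP1">\n'))
  for (x in specXml) {
    specOffsets <- c(specOffsets, pos)
    add(paste0(x, "\n"))
  }
  add('</spectrumList>\n')
  if (length(chXml)) {
    add(paste0('<chromatogramList count="', length(chXml),
               '" defaultDataProcessingRef="DP1">\n'))
    for (x in chXml) {
      chOffsets <- c(chOffsets, pos)
      add(paste0(x, "\n"))
    }
    add('</chromatogramList>\n')
  }
  add('</run>\n</mzML>\n')

  idxOffset <- pos
  idx <- paste0(
    '<indexList count="', 1L + (length(chXml) > 0L), '">\n',
    '<index name="spectrum">\n',
    paste0(sprintf('<offset idRef="scan=%d">%d</offset>\n',
                   seq_along(specOffsets), specOffsets), collapse = ""),
    '</index>\n',
    if (length(chXml)) paste0(
      '<index name="chromatogram">\n',
      paste0(vapply(seq_along(chOffsets), function(i) {
        ch <- pm@chromatograms[[i]]
        id <- switch(ch@kind,
          SRM = sprintf("SRM SIC Q1=%.10g Q3=%.10g", ch@precursorMz,
                        ch@productMz),
          TIC = "TIC", EIC = sprintf("EIC %d", i))
        sprintf('<offset idRef="%s">%d</offset>\n', id, chOffsets[i])
      }, character(1)), collapse = ""),
      '</index>\n') else "",
    '</indexList>\n',
    '<indexListOffset>', idxOffset, '</indexListOffset>\n',
    '</indexedmzML>\n')

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(head1, paste0(parts, collapse = ""), idx), con,
            eos = NULL)
  invisible(path)
}

# per-chromatogram time unit ("second"/"minute") scanned from the raw file,
# in document order; mzR returns chromatogram times unconverted
.chromTimeUnits <- function(path) {
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  m <- gregexpr(paste0('name="time array"[^>]*unitAccession="([^"]+)"'),
                txt)[[1]]
  if (m[1] == -1L) return(character(0))
  hits <- regmatches(txt, gregexpr(
    'name="time array"[^>]*unitAccession="[^"]+"', txt))[[1]]
  acc <- sub('.*unitAccession="([^"]+)".*', "\\1", hits)
  ifelse(acc == "UO:0000031", "minute", "second")
}

#' Read an mzML file
#'
#' Loads every spectrum and chromatogram of a centroided mzML file into a
#' [PeakMap-class], with all retention times converted to seconds
#' regardless of the file's declared unit. Profile-mode spectra trigger a
#' warning and are loaded unchanged (no centroiding is applied).
#'
#' @param path Path to an mzML file.
#' @return A [PeakMap-class].
#' @export
readMzML <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  h <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(try(mzR::close(h), silent = TRUE))

  specs <- list()
  hd <- mzR::header(h)
  if (nrow(hd)) {
    if (any(hd$centroided %in% FALSE))
      warning("profile-mode spectra present; loaded without centroiding")
    pk <- mzR::peaks(h)
    if (is.matrix(pk)) pk <- list(pk)
    specs <- lapply(seq_len(nrow(hd)), function(i) {
      prec <- if (hd$msLevel[i] >= 2L)
        data.frame(mz = hd$precursorMZ[i],
                   charge = ifelse(hd$precursorCharge[i] == 0L, NA_integer_,
                                   hd$precursorCharge[i]),
                   isolationWidth =
                     if ("isolationWindowUpperOffset" %in% names(hd))
                       hd$isolationWindowUpperOffset[i] else NA_real_)
      else NULL
      pol <- if (hd$polarity[i] == 1L) 1L
             else if (hd$polarity[i] == 0L) -1L else 0L
      spectrum(rt = hd$retentionTime[i], mz = pk[[i]][, 1],
               intensity = pk[[i]][, 2], msLevel = hd$msLevel[i],
               polarity = pol, precursors = prec)
    })
  }

  chroms <- list()
  # chromatogramHeader warns ("pwiz not yet initialized") on files without
  # a chromatogram list; that is an expected shape, not a problem
  ch <- withCallingHandlers(
    tryCatch(mzR::chromatogramHeader(h), error = function(e) NULL),
    warning = function(w) {
      if (grepl("pwiz not yet initialized", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!is.null(ch) && nrow(ch)) {
    units <- .chromTimeUnits(path)
    for (i in seq_len(nrow(ch))) {
      cc <- mzR::chromatogram(h, i)
      rt <- cc[, 1]
      if (length(units) >= i && units[i] == "minute") rt <- rt * 60
      pre <- ch$precursorIsolationWindowTargetMZ[i]
      pro <- ch$productIsolationWindowTargetMZ[i]
      kind <- if (!is.na(pre) && !is.na(pro)) "SRM"
              else if (grepl("^TIC$", ch$chromatogramId[i])) "TIC"
              else "EIC"
      chroms[[i]] <- chromatogram(rt = rt, intensity = cc[, 2],
                                  kind = kind, precursorMz = pre,
                                  productMz = pro)
    }
  }
  peakMap(spectra = specs, chromatograms = chroms,
          metadata = list(source = path))
}
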