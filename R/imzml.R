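# Continuous-mode imzML input/output.
#
# imzML stores metadata in an mzML-style XML file and the numeric arrays in a
# sidecar binary file (.ibd) that begins with the 16-byte UUID referenced from
# the XML. In continuous mode all pixels share one m/z axis, stored once; each
# spectrum then stores only its intensity vector. Only that dialect is
# supported here (uncompressed 64-bit floats); processed-mode files raise an
# unsupported-dialect error.

.IMS_CONTINUOUS <- "IMS:1000030"
.IMS_PROCESSED <- "IMS:1000031"
.IMS_UUID <- "IMS:1000080"
.IMS_POS_X <- "IMS:1000050"
.IMS_POS_Y <- "IMS:1000051"
.IMS_EXT_OFFSET <- "IMS:1000102"
.IMS_EXT_LENGTH <- "IMS:1000103"
.IMS_EXT_ENCLEN <- "IMS:1000104"

.randomUUIDBytes <- function() {
    # RFC 4122 v4 UUID from the current RNG stream
    b <- as.raw(sample(0:255, 16, replace = TRUE))
    b[7] <- as.raw(bitwOr(bitwAnd(as.integer(b[7]), 0x0F), 0x40))
    b[9] <- as.raw(bitwOr(bitwAnd(as.integer(b[9]), 0x3F), 0x80))
    b
}

.uuidString <- function(bytes) {
    h <- tolower(paste(format(bytes), collapse = ""))
    paste(substr(h, 1, 8), substr(h, 9, 12), substr(h, 13, 16),
          substr(h, 17, 20), substr(h, 21, 32), sep = "-")
}

#' Write an MSIDataCube as continuous-mode imzML
#'
#' Writes `<path>.imzML` plus the binary `<path>.ibd` companion (64-bit
#' floats, no compression). The cube's 0-based coordinates are converted to
#' the 1-based pixel positions imzML mandates. The round trip through
#' [readImzML()] is lossless.
#'
#' @param cube an [MSIDataCube-class].
#' @param path output path; the `.imzML`/`.ibd` extensions are added (or the
#'   `.imzML` extension replaced) as needed.
#' @return the `.imzML` path, invisibly.
#' @export
writeImzML <- function(cube, path) {
    stopifnot(is(cube, "MSIDataCube"))
    base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
    xml_path <- paste0(base, ".imzML")
    ibd_path <- paste0(base, ".ibd")

    n_mz <- length(cube@mz)
    n_px <- nrow(cube@intensities)
    uuid <- .randomUUIDBytes()

    con <- file(ibd_path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(uuid, con)
    writeBin(as.numeric(cube@mz), con, size = 8, endian = "little")
    for (i in seq_len(n_px))
        writeBin(as.numeric(cube@intensities[i, ]), con, size = 8,
                 endian = "little")

    mz_offset <- 16
    int_offsets <- 16 + 8 * n_mz + (seq_len(n_px) - 1) * 8 * n_mz

    cv <- function(ref, acc, name, value = NULL, unit = NULL) {
        v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
        u <- if (is.null(unit)) "" else unit
        sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s%s/>',
                ref, acc, name, v, u)
    }
    head <- c(
        '<?xml version="1.0" encoding="ISO-8859-1"?>',
        '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
        '<cvList count="3">',
        '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="1.3.1" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
        '<cv id="UO" fullName="Unit Ontology" version="1.15" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
        '<cv id="IMS" fullName="Imaging MS Ontology" version="0.9.1" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
        '</cvList>',
        '<fileDescription><fileContent>',
        cv("MS", "MS:1000579", "MS1 spectrum"),
        cv("IMS", .IMS_CONTINUOUS, "continuous"),
        cv("IMS", .IMS_UUID, "universally unique identifier",
           paste0("{", .uuidString(uuid), "}")),
        '</fileContent></fileDescription>',
        '<referenceableParamGroupList count="2">',
        '<referenceableParamGroup id="mzArray">',
        cv("MS", "MS:1000514", "m/z array", unit = ' unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"'),
        cv("MS", "MS:1000523", "64-bit float"),
        cv("MS", "MS:1000576", "no compression"),
        cv("IMS", "IMS:1000101", "external data", "true"),
        '</referenceableParamGroup>',
        '<referenceableParamGroup id="intensityArray">',
        cv("MS", "MS:1000515", "intensity array", unit = ' unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"'),
        cv("MS", "MS:1000523", "64-bit float"),
        cv("MS", "MS:1000576", "no compression"),
        cv("IMS", "IMS:1000101", "external data", "true"),
        '</referenceableParamGroup>',
        '</referenceableParamGroupList>',
        '<softwareList count="1"><software id="MetaboStrat" version="0.99"/></softwareList>',
        '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
        cv("IMS", "IMS:1000042", "max count of pixels x", cube@dim[1L]),
        cv("IMS", "IMS:1000043", "max count of pixels y", cube@dim[2L]),
        '</scanSettings></scanSettingsList>',
        '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
        '<dataProcessingList count="1"><dataProcessing id="export"><processingMethod order="1" softwareRef="MetaboStrat">',
        cv("MS", "MS:1000544", "Conversion to mzML"),
        '</processingMethod></dataProcessing></dataProcessingList>',
        '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
        sprintf('<spectrumList count="%d" defaultDataProcessingRef="export">',
                n_px))

    spectra <- vapply(seq_len(n_px), function(i) {
        paste0(
            sprintf('<spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">',
                    i, i - 1L, n_mz),
            '<scanList count="1">',
            cv("MS", "MS:1000795", "no combination"),
            '<scan>',
            cv("IMS", .IMS_POS_X, "position x", cube@coords[i, 1L] + 1L),
            cv("IMS", .IMS_POS_Y, "position y", cube@coords[i, 2L] + 1L),
            '</scan></scanList>',
            '<binaryDataArrayList count="2">',
            '<binaryDataArray encodedLength="0">',
            '<referenceableParamGroupRef ref="mzArray"/>',
            cv("IMS", .IMS_EXT_LENGTH, "external array length", n_mz),
            cv("IMS", .IMS_EXT_ENCLEN, "external encoded length", 8 * n_mz),
            cv("IMS", .IMS_EXT_OFFSET, "external offset", mz_offset),
            '<binary/></binaryDataArray>',
            '<binaryDataArray encodedLength="0">',
            '<referenceableParamGroupRef ref="intensityArray"/>',
            cv("IMS", .IMS_EXT_LENGTH, "external array length", n_mz),
            cv("IMS", .IMS_EXT_ENCLEN, "external encoded length", 8 * n_mz),
            cv("IMS", .IMS_EXT_OFFSET, "external offset",
               format(int_offsets[i], scientific = FALSE)),
            '<binary/></binaryDataArray>',
            '</binaryDataArrayList></spectrum>')
    }, character(1))

    tail <- c('</spectrumList></run></mzML>')
    writeLines(c(head, spectra, tail), xml_path)
    invisible(xml_path)
}

.cvValue <- function(node, accession) {
    p <- xml2::xml_find_first(
        node, sprintf(".//cvParam[@accession='%s']", accession))
    if (inherits(p, "xml_missing")) NA_character_ else xml2::xml_attr(p, "value")
}

#' Read a continuous-mode imzML file
#'
#' Parses the XML index, reads the shared m/z axis once and one intensity
#' vector per pixel from the `.ibd` companion. Processed-mode files (per-pixel
#' m/z axes) are not supported and raise an error; spectra without pixel
#' positions raise a format error.
#'
#' @param path path to the `.imzML` file (the `.ibd` must sit next to it).
#' @return an [MSIDataCube-class] with 0-based coordinates.
#' @export
readImzML <- function(path) {
    .assert(file.exists(path), "imzML file not found: %s", path)
    base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
    ibd_path <- paste0(base, ".ibd")
    .assert(file.exists(ibd_path), "binary companion not found: %s", ibd_path)

    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)

    fc <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
    is_processed <- !inherits(xml2::xml_find_first(
        fc, sprintf(".//cvParam[@accession='%s']", .IMS_PROCESSED)),
        "xml_missing")
    is_continuous <- !inherits(xml2::xml_find_first(
        fc, sprintf(".//cvParam[@accession='%s']", .IMS_CONTINUOUS)),
        "xml_missing")
    if (is_processed || !is_continuous)
        stop("unsupported imzML dialect: only continuous-mode files with a ",
             "shared m/z axis are readable", call. = FALSE)

    spectra <- xml2::xml_find_all(doc, ".//run/spectrumList/spectrum")
    .assert(length(spectra) > 0, "imzML file contains no spectra")

    parse_one <- function(sp) {
        x <- .cvValue(xml2::xml_find_first(sp, ".//scan"), .IMS_POS_X)
        y <- .cvValue(xml2::xml_find_first(sp, ".//scan"), .IMS_POS_Y)
        if (is.na(x) || is.na(y))
            stop("imzML format error: spectrum without pixel coordinates",
                 call. = FALSE)
        arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
        mz_off <- int_off <- mz_len <- int_len <- NA_real_
        for (a in arrays) {
            ref <- xml2::xml_attr(
                xml2::xml_find_first(a, "./referenceableParamGroupRef"), "ref")
            is_mz <- if (!is.na(ref)) grepl("mz", ref, ignore.case = TRUE) else
                !inherits(xml2::xml_find_first(
                    a, ".//cvParam[@accession='MS:1000514']"), "xml_missing")
            off <- as.numeric(.cvValue(a, .IMS_EXT_OFFSET))
            len <- as.numeric(.cvValue(a, .IMS_EXT_LENGTH))
            if (is_mz) { mz_off <- off; mz_len <- len }
            else { int_off <- off; int_len <- len }
        }
        c(x = as.numeric(x), y = as.numeric(y), mz_off = mz_off,
          mz_len = mz_len, int_off = int_off, int_len = int_len)
    }
    info <- t(vapply(spectra, parse_one, numeric(6)))
    .assert(!anyNA(info[, c("mz_off", "int_off")]),
            "imzML format error: missing external offsets")
    .assert(length(unique(info[, "mz_off"])) == 1L &&
            length(unique(info[, "mz_len"])) == 1L,
            "unsupported imzML dialect: spectra do not share one m/z axis")

    con <- file(ibd_path, "rb")
    on.exit(close(con), add = TRUE)
    n_mz <- info[1L, "mz_len"]
    seek(con, info[1L, "mz_off"])
    mz_axis <- readBin(con, "double", n = n_mz, size = 8, endian = "little")
    mat <- matrix(0, nrow(info), n_mz)
    for (i in seq_len(nrow(info))) {
        seek(con, info[i, "int_off"])
        mat[i, ] <- readBin(con, "double", n = info[i, "int_len"], size = 8,
                            endian = "little")
    }
    coords <- cbind(x = info[, "x"], y = info[, "y"]) - 1
    rownames(coords) <- NULL
    storage.mode(coords) <- "integer"
    MSIDataCube(mz_axis, mat, coords,
                dim = c(max(coords[, 1L]) + 1L, max(coords[, 2L]) + 1L))
}
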