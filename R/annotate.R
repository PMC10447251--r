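# Tentative metabolite identification of discriminating ions against a local
# compound table, with pathway frequency ranking and lipid-name curation.

.PROTON_MASS <- 1.007276467

#' Adduct rules
#'
#' Mass-shift rules mapping a neutral monoisotopic mass M to an observed m/z
#' (singly charged). The negative-polarity default covers the deprotonated
#' ion [M-H]- and the chloride adduct [M+Cl]-.
#'
#' @param polarity "negative" or "positive".
#' @return data.frame with columns `adduct` and `shift` (Da added to M).
#' @export
defaultAdducts <- function(polarity = c("negative", "positive")) {
    polarity <- match.arg(polarity)
    if (polarity == "negative")
        data.frame(adduct = c("[M-H]-", "[M+Cl]-"),
                   shift = c(-.PROTON_MASS, 34.968853),
                   stringsAsFactors = FALSE)
    else
        data.frame(adduct = c("[M+H]+", "[M+Na]+"),
                   shift = c(.PROTON_MASS, 21.981944),
                   stringsAsFactors = FALSE)
}

#' Match query ions against a compound database
#'
#' Reports every (query, compound, adduct) triple whose relative mass error
#' `|observed - theoretical| / theoretical * 1e6` is within `ppm_tol`
#' (inclusive). Ambiguity is preserved: one query may hit several compounds
#' and adducts. The default 5 ppm tolerance matches sub-5-ppm instrument mass
#' accuracy.
#'
#' @param queries numeric vector of observed m/z.
#' @param db compound table ([generateCompoundDB()] schema, one row per
#'   compound-pathway pair; compounds are deduplicated for matching).
#' @param adducts adduct rule table ([defaultAdducts()] schema), non-empty.
#' @param ppm_tol tolerance in ppm (> 0).
#' @return data.frame: `query_mz`, `adduct`, `compound_name`,
#'   `theoretical_mz`, `ppm_error` (signed), plus a `pathways` list-column of
#'   per-match data.frames (`pathway`, `subclass`).
#' @export
matchIons <- function(queries, db, adducts = defaultAdducts(), ppm_tol = 5) {
    .assert(ppm_tol > 0, "ppm_tol must be positive")
    .assert(nrow(adducts) >= 1, "adduct list must not be empty")
    validateCompoundDB(db)
    compounds <- unique(db[, c("compound_name", "monoisotopic_mass")])
    pw_by_compound <- split(db[, c("pathway", "subclass")], db$compound_name)

    out <- list()
    for (ai in seq_len(nrow(adducts))) {
        theo <- compounds$monoisotopic_mass + adducts$shift[ai]
        for (q in queries) {
            ppm <- (q - theo) / theo * 1e6
            # inclusive boundary with a 1e-9 ppm guard against float rounding
            hit <- which(abs(ppm) <= ppm_tol + 1e-9)
            if (!length(hit)) next
            out[[length(out) + 1L]] <- data.frame(
                query_mz = q, adduct = adducts$adduct[ai],
                compound_name = compounds$compound_name[hit],
                theoretical_mz = theo[hit], ppm_error = ppm[hit],
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(query_mz = numeric(0), adduct = character(0),
                          compound_name = character(0),
                          theoretical_mz = numeric(0),
                          ppm_error = numeric(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res$pathways <- lapply(res$compound_name, function(nm) {
        p <- pw_by_compound[[nm]]
        rownames(p) <- NULL
        p
    })
    res
}

# scan s for "CLASS(...)" lipid tokens with balanced parentheses; returns a
# data.frame of token start/end positions and the inner chain text
.findLipidTokens <- function(s) {
    chars <- strsplit(s, "")[[1]]
    tokens <- list()
    i <- 1L
    n <- length(chars)
    while (i <= n) {
        if (grepl("^[A-Za-z]$", chars[i])) {
            j <- i
            while (j < n && grepl("^[A-Za-z0-9-]$", chars[j + 1L])) j <- j + 1L
            if (j < n && chars[j + 1L] == "(") {
                depth <- 0L
                k <- j + 1L
                while (k <= n) {
                    if (chars[k] == "(") depth <- depth + 1L
                    if (chars[k] == ")") {
                        depth <- depth - 1L
                        if (depth == 0L) break
                    }
                    k <- k + 1L
                }
                if (k <= n) {
                    inner <- substr(s, j + 2L, k - 1L)
                    # lipid chains start with digits (optionally O-/P-/d/t prefix)
                    if (grepl("^(?:[OPdt]-?)?\\d+:", inner)) {
                        tokens[[length(tokens) + 1L]] <- list(
                            class_start = i, open = j + 1L, close = k,
                            class_name = substr(s, i, j), inner = inner)
                        i <- k + 1L
                        next
                    }
                }
            }
            i <- j + 1L
        } else i <- i + 1L
    }
    tokens
}

.sumChains <- function(inner, context) {
    # strip double-bond position annotations: parenthesised groups inside
    depth <- 0L
    kept <- character(0)
    for (ch in strsplit(inner, "")[[1]]) {
        if (ch == "(") { depth <- depth + 1L; next }
        if (ch == ")") { depth <- depth - 1L; next }
        if (depth == 0L) kept <- c(kept, ch)
    }
    flat <- paste(kept, collapse = "")
    chains <- strsplit(flat, "[/_]")[[1]]
    carbons <- dbonds <- 0L
    for (ch in chains) {
        m <- regmatches(ch, regexec("^(?:[OPdt]-?)?(\\d+):(\\d+)$", ch))[[1]]
        if (length(m) != 3)
            stop(sprintf("malformed lipid chain token '%s' in '%s'",
                         ch, context), call. = FALSE)
        carbons <- carbons + as.integer(m[2])
        dbonds <- dbonds + as.integer(m[3])
    }
    sprintf("%d:%d", carbons, dbonds)
}

#' Shorten a lipid name to its sum composition
#'
#' Collapses side-chain detail in lipid shorthand: chains are summed
#' (`CLASS(c1:d1/c2:d2)` becomes `CLASS(c1+c2:d1+d2)`) and double-bond
#' position annotations are removed, so e.g. `PC(22:1(13Z)/20:0)` becomes
#' `PC(42:1)`. Text without a lipid token (including already shortened names)
#' passes through unchanged; the transformation is idempotent. Pathway names
#' containing a lipid token (e.g. "Phosphatidylcholine Biosynthesis
#' PC(22:1(13Z)/20:0)") are shortened in place.
#'
#' @param name character vector of names.
#' @return character vector of curated names.
#' @export
shortenLipidName <- function(name) {
    vapply(name, function(s) {
        tokens <- .findLipidTokens(s)
        if (!length(tokens)) return(s)
        # rebuild right-to-left so earlier offsets stay valid
        for (tk in rev(tokens)) {
            summed <- .sumChains(tk$inner, s)
            s <- paste0(substr(s, 1L, tk$open - 1L), "(", summed, ")",
                        substring(s, tk$close + 1L))
        }
        s
    }, character(1), USE.NAMES = FALSE)
}

#' Rank pathways by unique discriminating ions
#'
#' Curates pathway names (lipid tokens shortened to sum compositions;
#' pathways of the same subclass that collapse to the same curated name are
#' merged) and counts, per curated pathway, the number of distinct query m/z
#' with at least one member compound. Pathways are reported in descending
#' order of that count, ties alphabetical.
#'
#' @param matches output of [matchIons()].
#' @return data.frame: `pathway` (curated), `subclass`, `n_unique_mz`,
#'   `member_mz` (list-column of the distinct query m/z).
#' @export
rankPathways <- function(matches) {
    if (!nrow(matches))
        return(data.frame(pathway = character(0), subclass = character(0),
                          n_unique_mz = integer(0)))
    long <- do.call(rbind, lapply(seq_len(nrow(matches)), function(i) {
        pw <- matches$pathways[[i]]
        if (is.null(pw) || !nrow(pw)) return(NULL)
        data.frame(query_mz = matches$query_mz[i], pathway = pw$pathway,
                   subclass = pw$subclass, stringsAsFactors = FALSE)
    }))
    if (is.null(long))
        return(data.frame(pathway = character(0), subclass = character(0),
                          n_unique_mz = integer(0)))
    long$curated <- shortenLipidName(long$pathway)
    key <- paste(long$subclass, long$curated, sep = "\r")
    agg <- lapply(split(long, key), function(d) {
        mzs <- sort(unique(d$query_mz))
        data.frame(pathway = d$curated[1], subclass = d$subclass[1],
                   n_unique_mz = length(mzs), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
    member <- lapply(split(long, key), function(d) sort(unique(d$query_mz)))
    out$member_mz <- member
    out <- out[order(-out$n_unique_mz, out$pathway), , drop = FALSE]
    rownames(out) <- NULL
    out
}
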