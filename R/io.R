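## Plate-export I/O.
##
## Melt table: delimited text, wide format; first column = temperature
## (deg C), one column per well, header row = well labels. Comma or tab
## delimiter chosen by file extension (.csv vs .tsv/.txt/.tab).
## Ligand map: CSV/TSV with columns well, ligand_conc_molar,
## replicate_group.

.delimFor <- function(path) {
    if (grepl("\\.(tsv|txt|tab)$", path, ignore.case = TRUE)) "\t" else ","
}

.readDelim <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, sep = .delimFor(path), header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a well-to-ligand map
#'
#' @param path CSV/TSV with columns \code{well},
#'   \code{ligand_conc_molar} and optionally \code{replicate_group}.
#' @return data.frame with those columns.
#' @export
readLigandMap <- function(path) {
    map <- .readDelim(path)
    need <- c("well", "ligand_conc_molar")
    miss <- setdiff(need, colnames(map))
    if (length(miss))
        stop("ligand map ", path, " missing column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(map$well))
        stop("ligand map lists well(s) more than once: ",
             paste(unique(map$well[duplicated(map$well)]), collapse = ", "))
    if (!is.numeric(map$ligand_conc_molar) ||
        any(is.na(map$ligand_conc_molar)) ||
        any(map$ligand_conc_molar < 0))
        stop("ligand_conc_molar must be numeric and nonnegative")
    if (is.null(map$replicate_group))
        map$replicate_group <- match(map$ligand_conc_molar,
                                     sort(unique(map$ligand_conc_molar)))
    map
}

#' Read a plate melt-curve export plus its ligand map
#'
#' Wide-format delimited text (first column temperature in deg C, one
#' fluorescence column per well, header = well labels) joined with a ligand
#' map. Wells present in the data but absent from the map are skipped with
#' a warning; map entries naming absent wells are an error.
#'
#' @param path melt table (CSV or TSV by extension).
#' @param ligandMapPath ligand map (see [readLigandMap()]).
#' @param normalized is the signal already on the fraction-unfolded scale?
#' @return a [MeltExperiment-class].
#' @export
readMeltTable <- function(path, ligandMapPath, normalized = FALSE) {
    tab <- .readDelim(path)
    if (ncol(tab) < 2L)
        stop("melt table ", path,
             " needs a temperature column plus at least one well column")
    temperature <- tab[[1]]
    if (!is.numeric(temperature) || anyNA(temperature))
        stop("melt table ", path,
             ": first column (temperature) must be numeric with no missing values")
    if (any(diff(temperature) <= 0))
        stop("melt table ", path,
             ": temperatures must be strictly increasing")
    wells <- colnames(tab)[-1]
    if (anyDuplicated(wells))
        stop("melt table ", path, ": duplicate well column(s): ",
             paste(unique(wells[duplicated(wells)]), collapse = ", "))
    for (w in wells)
        if (!is.numeric(tab[[w]]) || anyNA(tab[[w]]))
            stop("melt table ", path, ": column '", w,
                 "' contains non-numeric or missing values")

    map <- readLigandMap(ligandMapPath)
    absent <- setdiff(map$well, wells)
    if (length(absent))
        stop("ligand map references well(s) absent from ", path, ": ",
             paste(absent, collapse = ", "))
    unmapped <- setdiff(wells, map$well)
    if (length(unmapped))
        warning("skipping unmapped well(s): ",
                paste(unmapped, collapse = ", "), call. = FALSE)
    keep <- map$well
    sig <- as.matrix(tab[keep])
    MeltExperiment(sig, temperature, map$ligand_conc_molar,
                   replicateGroup = map$replicate_group,
                   normalized = normalized)
}

#' Write a MeltExperiment as a wide melt table (and ligand map)
#'
#' Emits the same delimited wide format [readMeltTable()] consumes, so a
#' write/read cycle reproduces the object.
#'
#' @param x a [MeltExperiment-class].
#' @param path output melt table (.csv or .tsv).
#' @param ligandMapPath optional output path for the matching ligand map.
#' @return invisibly, \code{path}.
#' @export
writeMeltTable <- function(x, path, ligandMapPath = NULL) {
    stopifnot(methods::is(x, "MeltExperiment"))
    tab <- data.frame(temperature = temperatures(x), check.names = FALSE)
    tab <- cbind(tab, as.data.frame(signalValues(x), check.names = FALSE))
    utils::write.table(tab, path, sep = .delimFor(path), row.names = FALSE,
                       quote = FALSE)
    if (!is.null(ligandMapPath)) {
        cd <- SummarizedExperiment::colData(x)
        map <- data.frame(well = colnames(x),
                          ligand_conc_molar = cd$ligand_conc_molar,
                          replicate_group = cd$replicate_group)
        utils::write.table(map, ligandMapPath,
                           sep = .delimFor(ligandMapPath),
                           row.names = FALSE, quote = FALSE)
    }
    invisible(path)
}
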