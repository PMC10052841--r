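#' Read a DIP genotype table
#'
#' Reads a delimited genotype table with header columns \code{sample_id},
#' \code{population}, \code{continent}, optionally \code{sex}, followed by
#' one column per locus. Genotype cells may be allele-pair strings
#' (\code{"I/I"}, \code{"I/D"}, \code{"D/I"}, \code{"D/D"}, \code{"N/N"}
#' for a failed call) or insertion-dosage digits \code{0/1/2}
#' (\code{NA}/empty = missing). Dosage is the count of insertion alleles.
#'
#' @param path path to the file.
#' @param sep field separator; tab by default, use \code{","} for CSV.
#' @param markerClass optional named character vector assigning a marker
#'   class (\code{"autosomal_dip"}, \code{"y_dip"}, \code{"amelogenin"})
#'   to locus names; unnamed loci default to \code{"autosomal_dip"}.
#' @return A \linkS4class{DipGenotypes} object with column order preserved.
#' @export
readGenotypeTable <- function(path, sep = "\t", markerClass = NULL) {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character", check.names = FALSE)
    required <- c("sample_id", "population", "continent")
    if (!all(required %in% names(tab)))
        stop("genotype table needs columns: ", paste(required, collapse = ", "))
    if (anyDuplicated(tab$sample_id))
        stop("duplicate sample_id: ",
             paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
                   collapse = ", "))
    meta <- intersect(c(required, "sex"), names(tab))
    loci <- setdiff(names(tab), meta)
    if (!length(loci)) stop("no locus columns found")
    d <- matrix(NA_integer_, length(loci), nrow(tab),
                dimnames = list(loci, tab$sample_id))
    for (j in seq_along(loci)) {
        cells <- tab[[loci[j]]]
        dos <- .decodeGenotypes(cells, locus = loci[j], samples = tab$sample_id)
        d[j, ] <- dos
    }
    mc <- rep("autosomal_dip", length(loci))
    if (!is.null(markerClass)) {
        hit <- intersect(names(markerClass), loci)
        mc[match(hit, loci)] <- markerClass[hit]
    }
    DipGenotypes(d, population = tab$population, continent = tab$continent,
                 sex = if ("sex" %in% names(tab)) tab$sex else NULL,
                 markerClass = mc)
}

.decodeGenotypes <- function(cells, locus, samples) {
    cells <- toupper(trimws(cells))
    out <- rep(NA_integer_, length(cells))
    pair <- grepl("^[IDN]/[IDN]$", cells)
    digit <- cells %in% c("0", "1", "2")
    missing <- cells %in% c("N/N", "", "NA", ".")
    bad <- !(pair | digit | missing)
    if (any(bad))
        stop("unknown genotype token '", cells[which(bad)[1]],
             "' at sample '", samples[which(bad)[1]], "', locus '", locus, "'")
    out[digit] <- as.integer(cells[digit])
    pp <- pair & !missing
    out[pp] <- vapply(strsplit(cells[pp], "/", fixed = TRUE),
                      function(a) {
                          if ("N" %in% a) return(NA_integer_)
                          sum(a == "I")
                      }, integer(1))
    out
}

#' Write a DIP genotype table
#'
#' Inverse of \code{\link{readGenotypeTable}}: writes sample metadata and
#' allele-pair genotype strings (\code{I/I}, \code{I/D}, \code{D/D},
#' \code{N/N}) to a delimited text file.
#'
#' @param g a \linkS4class{DipGenotypes} object.
#' @param path output path.
#' @param sep field separator (tab by default).
#' @return \code{path}, invisibly.
#' @export
writeGenotypeTable <- function(g, path, sep = "\t") {
    d <- dosage(g)
    code <- c(`0` = "D/D", `1` = "I/D", `2` = "I/I")
    cells <- matrix("N/N", nrow(d), ncol(d))
    ok <- !is.na(d)
    cells[ok] <- code[as.character(d[ok])]
    out <- data.frame(sample_id = colnames(d),
                      population = populationLabels(g),
                      continent = continentLabels(g),
                      check.names = FALSE)
    if ("sex" %in% names(colData(g))) out$sex <- colData(g)$sex
    out <- cbind(out, as.data.frame(t(cells)) |>
                     stats::setNames(rownames(d)))
    utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write a long-format allele-frequency table
#'
#' The canonical frequency exchange format is a four-column delimited
#' table: \code{locus}, \code{population}, \code{p_ins}, \code{n}
#' (diploid sample size).
#'
#' @param path file path.
#' @param sep field separator.
#' @return \code{readFrequencyTable} returns a
#'   \linkS4class{DipFrequencies}; \code{writeFrequencyTable} returns
#'   \code{path} invisibly.
#' @export
readFrequencyTable <- function(path, sep = "\t") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE)
    need <- c("locus", "population", "p_ins", "n")
    if (!all(need %in% names(tab)))
        stop("frequency table needs columns: ", paste(need, collapse = ", "))
    loci <- unique(tab$locus)
    pops <- unique(tab$population)
    p <- matrix(NA_real_, length(loci), length(pops),
                dimnames = list(loci, pops))
    p[cbind(match(tab$locus, loci), match(tab$population, pops))] <- tab$p_ins
    n <- tab$n[match(pops, tab$population)]
    DipFrequencies(p, n = n)
}

#' @rdname readFrequencyTable
#' @param f a \linkS4class{DipFrequencies} object.
#' @export
writeFrequencyTable <- function(f, path, sep = "\t") {
    p <- pIns(f)
    long <- data.frame(locus = rep(rownames(p), ncol(p)),
                       population = rep(colnames(p), each = nrow(p)),
                       p_ins = as.vector(p),
                       n = rep(sampleSizes(f), each = nrow(p)))
    utils::write.table(long, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write / read a PHYLIP square distance matrix
#'
#' Standard PHYLIP format: a first line with the taxon count, then one row
#' per taxon with the name padded to 10 characters followed by the full
#' row of distances.
#'
#' @param d a \linkS4class{DipDistance} object (or square symmetric
#'   matrix with dimnames).
#' @param path output path.
#' @param relaxedNames allow names longer than 10 characters (written
#'   whitespace-separated); otherwise names are truncated to 10 characters
#'   and a collision after truncation is an error.
#' @return \code{path} invisibly; \code{readPhylipDistance} returns a
#'   labelled numeric matrix.
#' @export
writePhylipDistance <- function(d, path, relaxedNames = FALSE) {
    m <- if (is(d, "DipDistance")) as.matrix(d) else as.matrix(d)
    if (nrow(m) == 0L) stop("empty distance matrix")
    labs <- rownames(m)
    if (!relaxedNames) {
        short <- substr(labs, 1, 10)
        if (anyDuplicated(short))
            stop("label collision after PHYLIP 10-character padding; ",
                 "use relaxedNames = TRUE")
        labs <- formatC(short, width = -10)
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(format(nrow(m)), con)
    for (i in seq_len(nrow(m)))
        writeLines(paste(labs[i],
                         paste(formatC(m[i, ], format = "g", digits = 17),
                               collapse = " ")), con)
    invisible(path)
}

#' @rdname writePhylipDistance
#' @export
readPhylipDistance <- function(path) {
    lines <- readLines(path)
    ntax <- as.integer(lines[1])
    parts <- strsplit(trimws(lines[1 + seq_len(ntax)]), "\\s+")
    labs <- vapply(parts, `[`, "", 1)
    m <- t(vapply(parts, function(x) as.numeric(x[-1]), numeric(ntax)))
    dimnames(m) <- list(labs, labs)
    m
}

#' Write a tree in Newick format
#'
#' Thin wrapper over \code{\link[ape]{write.tree}} keeping branch lengths
#' at full precision.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(tree, path) {
    ape::write.tree(tree, file = path, digits = 17)
    invisible(path)
}

#' Write an analysis result as JSON
#'
#' @param x a list of results (numbers, vectors, nested lists).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultsJson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    invisible(path)
}
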