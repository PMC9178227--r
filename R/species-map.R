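#' Construct a copy-to-species mapping
#'
#' @param table optional two-column data source: either a named character
#'   vector (names = copy ids), a data.frame with columns \code{copy_id} and
#'   \code{species_id} (or the first two columns), or a path to a two-column
#'   tab-separated file (header optional).
#' @param sep delimiter for the fallback rule \dQuote{species = label up to
#'   the first separator}; default \code{"|"}.
#' @return a [SpeciesMap-class] object.
#' @examples
#' m <- speciesMap()                      # delimiter rule on "|"
#' resolveSpecies(c("hsap|g1", "ptro|g2"), m)
#' @export
speciesMap <- function(table = NULL, sep = "|") {
    tab <- character(0)
    if (!is.null(table)) {
        if (is.character(table) && length(table) == 1L && is.null(names(table))
            && file.exists(table))
            table <- .readMapFile(table)
        if (is.data.frame(table)) {
            if (ncol(table) < 2L)
                stop("species map table needs two columns (copy_id, species_id)")
            tab <- setNames(as.character(table[[2L]]), as.character(table[[1L]]))
        } else if (is.character(table) && !is.null(names(table))) {
            tab <- table
        } else {
            stop("'table' must be a named character vector, data.frame or file path")
        }
    }
    new("SpeciesMap", table = tab, sep = sep)
}

.readMapFile <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, comment.char = "")
    # tolerate an optional header line
    if (identical(tolower(as.character(df[1L, 1L])), "copy_id"))
        df <- df[-1L, , drop = FALSE]
    df
}

#' Resolve copy labels to species
#'
#' Explicit table entries win; remaining labels fall back to the delimiter
#' rule (prefix before the first separator; the whole label when the
#' separator does not occur).  When the map was built from an explicit table
#' with no usable delimiter fallback, labels absent from the table raise an
#' error naming them.
#'
#' @param labels character vector of copy ids.
#' @param map a [SpeciesMap-class].
#' @return character vector of species ids, named by \code{labels}.
#' @export
resolveSpecies <- function(labels, map = speciesMap()) {
    stopifnot(is(map, "SpeciesMap"))
    if (!length(labels)) return(setNames(character(0), character(0)))
    if (anyNA(labels) || any(!nzchar(labels)))
        stop("empty or NA copy labels cannot be resolved to a species")
    out <- unname(map@table[labels])
    todo <- is.na(out)
    if (any(todo)) {
        if (length(map@table) && !nzchar(map@sep))
            stop("unmapped copy labels: ",
                 paste(labels[todo], collapse = ", "))
        out[todo] <- vapply(strsplit(labels[todo], map@sep, fixed = TRUE),
                            `[[`, character(1), 1L)
    }
    if (anyNA(out) || any(!nzchar(out)))
        stop("unmapped copy labels: ", paste(labels[is.na(out) | !nzchar(out)],
                                             collapse = ", "))
    setNames(out, labels)
}

#' Construct a gene family
#'
#' @param tree an [ape::phylo] tree or a Newick string; tips are gene copies.
#' @param map a [SpeciesMap-class]; default: delimiter rule on \code{"|"}.
#' @param lengths optional named numeric vector of ungapped sequence lengths
#'   covering every tip, or a path to a two-column tab-separated file.
#' @param familyId identifier for the family.
#' @return a [GeneFamily-class] object.
#' @examples
#' fam <- geneFamily("((A|1:1,A|2:1):1,B|1:2);", familyId = "fam1")
#' @export
geneFamily <- function(tree, map = speciesMap(), lengths = NULL,
                       familyId = "family") {
    if (is.character(tree)) tree <- parseNewick(tree)
    if (is.null(lengths)) {
        lengths <- numeric(0)
    } else if (is.character(lengths) && length(lengths) == 1L) {
        df <- read.table(lengths, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
        lengths <- setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
    }
    new("GeneFamily", tree = tree, map = map, lengths = lengths,
        familyId = familyId)
}

#' @describeIn geneFamily tree of a family or ortholog set
#' @param x a [GeneFamily-class] or [OrthologSet-class]
#' @export
familyTree <- function(x) x@tree

#' @describeIn geneFamily family identifier
#' @export
familyId <- function(x) x@familyId

#' Members and provenance of an ortholog set
#' @param x an [OrthologSet-class]
#' @return \code{members()}: copy ids; \code{removedCopies()}: pruned copy
#'   ids; \code{provenance()}: the method tag.
#' @export
members <- function(x) x@members

#' @rdname members
#' @export
removedCopies <- function(x) x@removed

#' @rdname members
#' @export
provenance <- function(x) x@method
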