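#' @import methods
#' @importFrom ape read.tree write.tree keep.tip drop.tip is.monophyletic
#'   di2multi Ntip Nnode dist.nodes node.depth.edgelength rphylo
#' @importFrom stats median rexp rmultinom rnorm runif sd pnorm setNames
#' @importFrom utils read.table write.table
NULL

setOldClass("phylo")

#' Copy-to-species mapping
#'
#' Maps gene-copy identifiers (tip labels of gene-family trees) to species
#' identifiers.  Resolution uses an explicit lookup table when one is given;
#' otherwise a delimiter rule applies: the species is the part of the label
#' before the first separator (the whole label when the separator is absent).
#' A label that cannot be resolved is always a hard error, never silently
#' dropped, because silent drops corrupt occupancy counts downstream.
#'
#' @slot table named character vector: names are copy ids, values species ids.
#'   May be empty when the delimiter rule is used.
#' @slot sep single-character separator for the delimiter rule (default
#'   \code{"|"}); ignored for labels present in \code{table}.
#' @seealso [speciesMap()], [resolveSpecies()]
#' @export
setClass("SpeciesMap",
         representation(table = "character", sep = "character"),
         prototype(table = character(0), sep = "|"))

setValidity("SpeciesMap", function(object) {
    if (length(object@sep) != 1L || is.na(object@sep))
        return("'sep' must be a single non-NA string")
    if (length(object@table) && is.null(names(object@table)))
        return("'table' must be a named character vector (copy id -> species)")
    if (length(object@table) && anyDuplicated(names(object@table)))
        return("duplicated copy ids in species table")
    TRUE
})

#' A multi-copy gene family
#'
#' A gene-family tree (possibly with several copies per species), the mapping
#' of its tips to species, and, optionally, ungapped sequence lengths used to
#' pick survivors when lineage-specific duplicates are trimmed.
#'
#' @slot tree an [ape::phylo] tree whose tips are gene copies.
#' @slot map a [SpeciesMap-class] resolving every tip to a species.
#' @slot lengths named numeric vector of ungapped sequence lengths (residues),
#'   one per tip; length zero when unknown.
#' @slot familyId single string identifying the family.
#' @export
setClass("GeneFamily",
         representation(tree = "phylo", map = "SpeciesMap",
                        lengths = "numeric", familyId = "character"),
         prototype(lengths = numeric(0), familyId = "family"))

setValidity("GeneFamily", function(object) {
    tips <- object@tree$tip.label
    if (anyDuplicated(tips))
        return(paste0("duplicate tip labels: ",
                      paste(unique(tips[duplicated(tips)]), collapse = ", ")))
    sp <- tryCatch(resolveSpecies(tips, object@map), error = function(e) e)
    if (inherits(sp, "error")) return(conditionMessage(sp))
    if (length(object@lengths)) {
        missing <- setdiff(tips, names(object@lengths))
        if (length(missing))
            return(paste0("lengths table does not cover tips: ",
                          paste(missing, collapse = ", ")))
        if (any(object@lengths <= 0 | is.na(object@lengths)))
            return("sequence lengths must be positive")
    }
    if (length(object@familyId) != 1L)
        return("'familyId' must be a single string")
    TRUE
})

#' An extracted ortholog set
#'
#' A pruned gene tree with at most one copy per species, together with
#' provenance: the decomposition method that produced it, the source family,
#' and the copies that were pruned away.
#'
#' Method tags: \code{SCC} single-copy cluster, \code{LSD}/\code{TSD}
#' duplicate trimming, \code{SE} subtree extraction, \code{MI} maximum
#' inclusion, \code{MO} monophyletic outgroups, \code{ONE} random one-paralog
#' sampling.
#'
#' @slot tree pruned [ape::phylo] tree.
#' @slot members copy ids retained (the tip labels of \code{tree}).
#' @slot species named character vector: species of each member.
#' @slot method one of \code{"SCC","LSD","TSD","SE","MI","MO","ONE"}.
#' @slot familyId id of the source [GeneFamily-class].
#' @slot removed copy ids of the source family not present in this set.
#' @export
setClass("OrthologSet",
         representation(tree = "phylo", members = "character",
                        species = "character", method = "character",
                        familyId = "character", removed = "character"))

setValidity("OrthologSet", function(object) {
    if (!object@method %in% c("SCC", "LSD", "TSD", "SE", "MI", "MO", "ONE"))
        return("unknown method tag")
    if (!setequal(object@members, object@tree$tip.label))
        return("'members' must equal the tip labels of 'tree'")
    if (anyDuplicated(object@species))
        return(paste0("species represented more than once: ",
                      paste(unique(object@species[duplicated(object@species)]),
                            collapse = ", ")))
    TRUE
})

#' A simulated gene family with true node labels
#'
#' A [GeneFamily-class] produced by the duplication--loss simulator.  Every
#' internal node of the tree is labelled \code{"D"} (duplication) or
#' \code{"S"} (speciation); these truth labels define the true ortholog
#' groups via [trueOrthologSets()].
#'
#' @slot nDuplications number of duplication events surviving in the tree.
#' @export
setClass("SimFamily", contains = "GeneFamily",
         representation(nDuplications = "integer"))

setValidity("SimFamily", function(object) {
    lab <- object@tree$node.label
    if (is.null(lab) || !all(lab %in% c("S", "D")))
        return("every internal node must be labelled 'S' or 'D'")
    TRUE
})

setMethod("show", "GeneFamily", function(object) {
    sp <- resolveSpecies(object@tree$tip.label, object@map)
    cat(sprintf("%s '%s': %d copies in %d species%s\n",
                class(object), object@familyId, length(sp),
                length(unique(sp)),
                if (length(object@lengths)) " (+lengths)" else ""))
})

setMethod("show", "OrthologSet", function(object) {
    cat(sprintf("OrthologSet [%s] from '%s': %d species, %d copies removed\n",
                object@method, object@familyId, length(object@members),
                length(object@removed)))
})
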