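## Branch-wise classification of single-copy gene trees against a reference
## species tree, and gene concordance factors (gCF).

.checkSpeciesTree <- function(stree) {
    n <- length(stree$tip.label)
    if (n < 4L) stop("species tree needs >= 4 leaves for concordance analysis")
    if (anyDuplicated(stree$tip.label))
        stop("species tree has duplicated species labels")
    if (!ape::is.binary(stree) || !ape::is.rooted(stree))
        stop("species tree must be rooted and strictly binary")
    invisible(n)
}

#' Quadripartitions of a species tree
#'
#' For every internal branch of the (unrooted view of the) rooted binary
#' species tree, returns the four disjoint species groups it defines:
#' \code{A} and \code{B} are the clades below the two children of the
#' branch's lower node, \code{C} is the sibling clade, and \code{D} holds
#' all remaining species.  The two root-adjacent rooted edges map to one
#' unrooted branch, emitted once.  A binary \eqn{n}-leaf tree has
#' \eqn{n - 3} such branches.
#'
#' @param stree rooted, strictly binary [ape::phylo] species tree with
#'   >= 4 leaves.
#' @return named list of quadripartitions; each element is a list with
#'   \code{id}, \code{node} (the lower node in \code{stree}), and character
#'   vectors \code{A}, \code{B}, \code{C}, \code{D}.
#' @export
quadripartitions <- function(stree) {
    n <- .checkSpeciesTree(stree)
    root <- n + 1L
    clades <- .cladeTips(stree)
    kids <- split(stree$edge[, 2L], stree$edge[, 1L])
    par <- .parents(stree)
    labs <- stree$tip.label
    rootKids <- kids[[as.character(root)]]
    out <- list()
    rootDone <- FALSE
    for (v in sort(setdiff(unique(stree$edge[, 1L]), root))) {
        ch <- kids[[as.character(v)]]
        A <- labs[clades[[ch[1L]]]]
        B <- labs[clades[[ch[2L]]]]
        u <- par[v]
        if (u == root) {
            w <- setdiff(rootKids, v)
            if (w <= n) next                 # other side is a leaf: terminal branch
            if (rootDone) next               # emit the spanning branch once
            rootDone <- TRUE
            wk <- kids[[as.character(w)]]
            C <- labs[clades[[wk[1L]]]]
            D <- labs[clades[[wk[2L]]]]
        } else {
            sib <- setdiff(kids[[as.character(u)]], v)
            C <- labs[clades[[sib]]]
            D <- setdiff(labs, c(A, B, C))
        }
        out[[length(out) + 1L]] <- list(node = v, A = A, B = B, C = C, D = D)
    }
    ids <- sprintf("b%02d", seq_along(out))
    for (i in seq_along(out)) out[[i]]$id <- ids[i]
    names(out) <- ids
    out
}

## classify one gene tree (given its split keys and present species)
## against one quadripartition
.classifyKeys <- function(keys, present, q) {
    A <- intersect(q$A, present); B <- intersect(q$B, present)
    C <- intersect(q$C, present); D <- intersect(q$D, present)
    if (!length(A) || !length(B) || !length(C) || !length(D))
        return("NOT_DECISIVE")
    ref <- sort(present)[1L]
    side <- function(x) {
        if (ref %in% x) x <- setdiff(present, x)
        paste(sort(x), collapse = "\r")
    }
    hit <- c(CONCORDANT = side(c(A, B)) %in% keys,
             ALT1       = side(c(A, C)) %in% keys,
             ALT2       = side(c(B, C)) %in% keys)
    if (sum(hit) > 1L)   # conflicting splits cannot coexist in one tree
        stop("internal error: more than one candidate split present")
    if (any(hit)) names(hit)[which(hit)] else "PARAPHYLETIC"
}

#' Classify a gene tree at one species-tree branch
#'
#' Tests, on the gene tree pruned to the species of the quadripartition,
#' which of the three resolutions of the branch is present as a bipartition:
#' \code{(A+B | C+D)} is \code{CONCORDANT}, \code{(A+C | B+D)} is
#' \code{ALT1}, \code{(B+C | A+D)} is \code{ALT2}.  A gene tree missing all
#' species of any group is \code{NOT_DECISIVE}; a decisive tree displaying
#' none of the three splits (e.g. because a reference clade is not
#' monophyletic, or the region is collapsed into a polytomy) is
#' \code{PARAPHYLETIC}.  Rooting of the gene tree is irrelevant: split
#' presence is a rooting-free property.
#'
#' @param gtree [ape::phylo] gene tree with at most one copy per species.
#' @param map a [SpeciesMap-class] resolving gene-tree tips to species.
#' @param q one quadripartition from [quadripartitions()].
#' @return one of \code{"CONCORDANT"}, \code{"ALT1"}, \code{"ALT2"},
#'   \code{"PARAPHYLETIC"}, \code{"NOT_DECISIVE"}.
#' @export
classifyGeneTree <- function(gtree, map = speciesMap(), q) {
    sp <- resolveSpecies(gtree$tip.label, map)
    if (anyDuplicated(sp))
        stop("gene tree has several copies of: ",
             paste(unique(sp[duplicated(sp)]), collapse = ", "),
             "; decompose the family into ortholog sets first")
    all4 <- c(q$A, q$B, q$C, q$D)
    keepTips <- gtree$tip.label[sp %in% all4]
    if (length(keepTips) < 4L) return("NOT_DECISIVE")
    sub <- pruneTo(gtree, keepTips)
    present <- unname(resolveSpecies(sub$tip.label, map))
    keys <- .splitKeys(sub, labels = present)
    .classifyKeys(keys, present, q)
}

#' Branch-wise concordance table and gene concordance factors
#'
#' Classifies every gene tree at every internal branch of the species tree
#' and tallies, per branch, the decisive, concordant, two alternative
#' (minor-topology) and paraphyletic gene trees.  The gene concordance
#' factor is \code{gCF = 100 * n_concordant / n_decisive}.
#'
#' @param gtrees non-empty list of single-copy-per-species [ape::phylo] gene
#'   trees (species not in the reference tree are ignored).
#' @param map a [SpeciesMap-class].
#' @param stree rooted binary [ape::phylo] species tree.
#' @return data.frame with one row per internal branch: \code{branch_id},
#'   \code{groups} (the four species groups, semicolon-joined),
#'   \code{n_decisive}, \code{n_concordant}, \code{n_alt1}, \code{n_alt2},
#'   \code{n_paraphyletic}, \code{gCF}.  The per-tree labels are attached as
#'   attribute \code{"labels"} (branch x tree character matrix) for
#'   downstream introgression testing.
#' @export
concordanceTable <- function(gtrees, map = speciesMap(), stree) {
    if (!length(gtrees)) stop("no gene trees supplied")
    qs <- quadripartitions(stree)
    lab <- matrix(NA_character_, nrow = length(qs), ncol = length(gtrees),
                  dimnames = list(names(qs), NULL))
    for (j in seq_along(gtrees)) {
        g <- gtrees[[j]]
        sp <- resolveSpecies(g$tip.label, map)
        if (anyDuplicated(sp))
            stop("gene tree ", j, " has several copies of: ",
                 paste(unique(sp[duplicated(sp)]), collapse = ", "),
                 "; decompose the family into ortholog sets first")
        keepTips <- g$tip.label[sp %in% stree$tip.label]
        if (length(keepTips) < 4L) { lab[, j] <- "NOT_DECISIVE"; next }
        sub <- if (length(keepTips) == length(g$tip.label)) g else
            pruneTo(g, keepTips)
        present <- unname(resolveSpecies(sub$tip.label, map))
        keys <- .splitKeys(sub, labels = present)
        for (i in seq_along(qs))
            lab[i, j] <- .classifyKeys(keys, present, qs[[i]])
    }
    tally <- function(i) {
        x <- lab[i, ]
        c(n_concordant = sum(x == "CONCORDANT"),
          n_alt1 = sum(x == "ALT1"),
          n_alt2 = sum(x == "ALT2"),
          n_paraphyletic = sum(x == "PARAPHYLETIC"))
    }
    counts <- t(vapply(seq_along(qs), tally, integer(4)))
    nDec <- rowSums(counts)
    out <- data.frame(
        branch_id = names(qs),
        groups = vapply(qs, function(q)
            paste(vapply(list(q$A, q$B, q$C, q$D),
                         function(g) paste(sort(g), collapse = ","),
                         character(1)), collapse = ";"), character(1)),
        n_decisive = as.integer(nDec),
        n_concordant = counts[, "n_concordant"],
        n_alt1 = counts[, "n_alt1"],
        n_alt2 = counts[, "n_alt2"],
        n_paraphyletic = counts[, "n_paraphyletic"],
        gCF = ifelse(nDec > 0, 100 * counts[, "n_concordant"] / nDec, NA_real_),
        row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "labels") <- lab
    out
}

#' Discordant fraction of a branch
#'
#' The fraction of decisive gene trees that support one of the two minor
#' topologies: \code{(n_alt1 + n_alt2) / n_decisive}.  This is the quantity
#' gated at 5\% before introgression testing; the Delta test consumes only
#' the two minor-topology classes, so paraphyletic trees do not count as
#' discordant by default.  Set \code{includeParaphyletic = TRUE} for the
#' alternative \code{1 - n_concordant / n_decisive}.
#'
#' @param bc a row subset (or all) of a [concordanceTable()] data.frame.
#' @param includeParaphyletic count paraphyletic trees as discordant.
#' @return numeric vector in \code{[0,1]}; \code{NA} (with a warning) for
#'   branches with no decisive gene tree.
#' @export
discordantFraction <- function(bc, includeParaphyletic = FALSE) {
    out <- if (includeParaphyletic)
        1 - bc$n_concordant / bc$n_decisive
    else
        (bc$n_alt1 + bc$n_alt2) / bc$n_decisive
    bad <- bc$n_decisive == 0
    if (any(bad)) {
        warning("discordant fraction undefined for branches with no decisive gene trees: ",
                paste(bc$branch_id[bad], collapse = ", "))
        out[bad] <- NA_real_
    }
    out
}
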