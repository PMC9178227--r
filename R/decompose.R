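## Tree-based decomposition of multi-copy gene families into ortholog sets.
##
## All methods only ever remove leaves; none invents topology.  Occupancy
## (the MIN-k threshold, `minTaxa`) is applied after extraction and counts
## distinct species.

.speciesOfTips <- function(fam) resolveSpecies(fam@tree$tip.label, fam@map)

## deterministic 31-bit sub-seed from (seed, key) so per-family / per-branch
## random streams are independent of processing order
.deriveSeed <- function(seed, key) {
    h <- 0
    for (c in utf8ToInt(as.character(key))) h <- (h * 131 + c) %% 2147483399
    as.integer((abs(seed) + h * 2654435) %% 2147483399 + 1)
}

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
    }
    set.seed(seed)
    expr
}

## rooted working copy: midpoint-root when branch lengths allow, otherwise
## use the rooting the tree was read with
.rootedTree <- function(tree) {
    if (length(tree$tip.label) < 2L) return(tree)
    if (!is.null(tree$edge.length) && sum(tree$edge.length) > 0)
        suppressWarnings(midpointRoot(tree))
    else tree
}

.rootNode <- function(tree) length(tree$tip.label) + 1L

.parents <- function(tree) {
    par <- integer(length(tree$tip.label) + tree$Nnode)
    par[tree$edge[, 2L]] <- tree$edge[, 1L]
    par
}

.makeSet <- function(fam, tipLabels, method) {
    tr <- pruneTo(fam@tree, tipLabels)
    sp <- resolveSpecies(tr$tip.label, fam@map)
    new("OrthologSet", tree = tr, members = tr$tip.label, species = sp,
        method = method, familyId = fam@familyId,
        removed = setdiff(fam@tree$tip.label, tr$tip.label))
}

.replaceTree <- function(fam, tipLabels) {
    tr <- pruneTo(fam@tree, tipLabels)
    lengths <- if (length(fam@lengths)) fam@lengths[tr$tip.label] else numeric(0)
    initialize(fam, tree = tr, lengths = lengths)
}

#' Single-copy cluster filter
#'
#' Keeps a family unchanged, as an ortholog set with provenance \code{SCC},
#' if and only if every represented species has exactly one gene copy and at
#' least \code{minTaxa} species are represented.
#'
#' @param family a [GeneFamily-class].
#' @param minTaxa occupancy threshold (MIN-k): minimum number of distinct
#'   species.
#' @return an [OrthologSet-class], or \code{NULL} when the family fails the
#'   filter.
#' @export
filterSCC <- function(family, minTaxa = 4L) {
    sp <- .speciesOfTips(family)
    if (anyDuplicated(sp)) return(NULL)
    if (length(unique(sp)) < minTaxa) return(NULL)
    .makeSet(family, family@tree$tip.label, "SCC")
}

## maximal clades (internal nodes) satisfying pred on (tips-below, species)
.maximalClades <- function(tree, sp, pred) {
    nt <- length(tree$tip.label)
    clades <- .cladeTips(tree)
    par <- .parents(tree)
    ok <- vapply(seq_along(clades), function(v) pred(clades[[v]]), logical(1))
    hits <- integer(0)
    for (v in which(ok)) {
        p <- par[v]
        if (p == 0L || !ok[p]) hits <- c(hits, v)
    }
    list(nodes = hits, clades = clades)
}

#' Trim lineage-specific duplicates
#'
#' Every maximal clade whose leaves all belong to a single species and that
#' contains two or more copies is reduced to one surviving leaf.  With a
#' sequence-length table present, the survivor is the copy whose ungapped
#' length is closest to the median length over all sequences of the family
#' (lower median for even counts; distance ties broken by tip order).
#' Without lengths, the copy with the smallest root-to-tip distance survives
#' (ties broken lexicographically by copy id).  The operation is idempotent
#' and only removes leaves.
#'
#' @param family a [GeneFamily-class]; midpoint-rooted internally when
#'   unrooted.
#' @return the trimmed [GeneFamily-class] (unchanged when no such clade
#'   exists).  Removed copies are the set difference of the tip labels.
#' @export
trimLSD <- function(family) {
    family <- as(family, "GeneFamily")   # truth labels do not survive rerooting
    tree <- .rootedTree(family@tree)
    fam <- initialize(family, tree = tree)
    sp <- .speciesOfTips(fam)
    mx <- .maximalClades(tree, sp, function(tips)
        length(unique(sp[tips])) == 1L)
    targets <- mx$nodes[vapply(mx$nodes, function(v)
        length(mx$clades[[v]]) >= 2L, logical(1))]
    if (!length(targets)) return(fam)
    med <- if (length(fam@lengths)) {
        x <- sort(unname(fam@lengths[tree$tip.label]))
        x[(length(x) + 1L) %/% 2L]          # lower-median convention
    } else NA_real_
    depths <- if (is.null(tree$edge.length)) NULL else
        ape::node.depth.edgelength(tree)
    drop <- integer(0)
    for (v in targets) {
        tips <- mx$clades[[v]]                       # in tip-number order
        labs <- tree$tip.label[tips]
        keep <- if (length(fam@lengths)) {
            d <- abs(fam@lengths[labs] - med)
            tips[which.min(d)]                       # first minimum = input order
        } else if (!is.null(depths)) {
            d <- depths[tips]
            cand <- tips[d <= min(d) + 1e-12 * max(d, 1)]
            cand[order(tree$tip.label[cand])][1L]    # lexicographic tie-break
        } else {
            tips[order(labs)][1L]
        }
        drop <- c(drop, setdiff(tips, keep))
    }
    .replaceTree(fam, tree$tip.label[-drop])
}

#' Trim two-species duplicates
#'
#' After lineage-specific trimming (applied internally; idempotent), every
#' maximal clade whose leaf species-set has size exactly two and that
#' contains three or more leaves is reduced to the cross-species pair (one
#' copy per species) with the minimum patristic distance.  Distance ties are
#' broken by the lexicographically smallest copy pair.  A two-leaf
#' cross-species cherry has no duplicate and is untouched.
#'
#' @param family a [GeneFamily-class] with branch lengths (needed for the
#'   distance rule).
#' @return the trimmed [GeneFamily-class].
#' @export
trimTSD <- function(family) {
    fam <- trimLSD(family)
    tree <- fam@tree
    sp <- .speciesOfTips(fam)
    mx <- .maximalClades(tree, sp, function(tips)
        length(unique(sp[tips])) == 2L)
    targets <- mx$nodes[vapply(mx$nodes, function(v)
        length(mx$clades[[v]]) >= 3L, logical(1))]
    if (!length(targets)) return(fam)
    if (is.null(tree$edge.length))
        stop("two-species duplicate trimming requires branch lengths")
    D <- ape::dist.nodes(tree)
    drop <- integer(0)
    for (v in targets) {
        tips <- mx$clades[[v]]
        spv <- sp[tips]
        s12 <- unique(spv)
        a <- tips[spv == s12[1L]]
        b <- tips[spv == s12[2L]]
        pairs <- expand.grid(a = a, b = b)
        d <- D[cbind(pairs$a, pairs$b)]
        tol <- 1e-12 * max(d, 1)
        best <- which(d <= min(d) + tol)
        if (length(best) > 1L) {
            key <- vapply(best, function(i)
                paste(sort(tree$tip.label[c(pairs$a[i], pairs$b[i])]),
                      collapse = "\r"), character(1))
            best <- best[order(key)[1L]]
        } else best <- best[1L]
        keep <- c(pairs$a[best], pairs$b[best])
        drop <- c(drop, setdiff(tips, keep))
    }
    .replaceTree(fam, tree$tip.label[-drop])
}

## per-node flag: no species appears twice in the clade below
.dupFreeFlags <- function(tree, sp) {
    clades <- .cladeTips(tree)
    vapply(clades, function(tips) !anyDuplicated(sp[tips]), logical(1))
}

#' Subtree extraction (SE)
#'
#' Midpoint-roots the gene tree, trims lineage-specific and two-species
#' duplicates, and then extracts every maximal duplicate-free rooted
#' subtree: a node whose subtree contains no species twice while its
#' parent's subtree does (the root qualifies when the whole tree is
#' duplicate-free).  The extracted subtrees are leaf-disjoint and jointly
#' cover all post-trim leaves; sets with fewer than \code{minTaxa} species
#' are then discarded.  A single pass is performed -- remainders are not
#' re-analyzed (that iterative variant is [extractMI()]).
#'
#' @inheritParams filterSCC
#' @return list of [OrthologSet-class] objects (possibly empty).
#' @export
extractSE <- function(family, minTaxa = 4L) {
    fam <- trimTSD(family)
    tree <- fam@tree
    sp <- .speciesOfTips(fam)
    if (length(tree$tip.label) == 1L) {
        ok <- length(unique(sp)) >= minTaxa   # only when minTaxa == 1
        return(if (ok) list(.makeSet(family, tree$tip.label, "SE")) else list())
    }
    flags <- .dupFreeFlags(tree, sp)
    par <- .parents(tree)
    clades <- .cladeTips(tree)
    out <- list()
    for (v in seq_along(flags)) {
        if (!flags[v]) next
        p <- par[v]
        if (p != 0L && flags[p]) next        # not maximal
        tips <- clades[[v]]
        if (length(unique(sp[tips])) < minTaxa) next
        out[[length(out) + 1L]] <- .makeSet(family, tree$tip.label[tips], "SE")
    }
    out
}

## connected components of the tree after deleting the given edges;
## returns a list of tip-index vectors
.componentsAfterCuts <- function(tree, cutEdges) {
    nNodes <- length(tree$tip.label) + tree$Nnode
    comp <- seq_len(nNodes)
    find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
    for (k in seq_len(nrow(tree$edge))) {
        if (k %in% cutEdges) next
        a <- find(tree$edge[k, 1L]); b <- find(tree$edge[k, 2L])
        if (a != b) comp[a] <- b
    }
    roots <- vapply(seq_len(length(tree$tip.label)), find, integer(1))
    split(seq_along(roots), roots)
}

## total branch length strictly inside the clade below node v
.cladeLength <- function(tree, v, cladeNodesList) {
    if (is.null(tree$edge.length)) return(0)
    inside <- cladeNodesList[[v]]
    sum(tree$edge.length[tree$edge[, 1L] %in% inside])
}

## all nodes (tips + internals) below-or-at each node
.cladeNodes <- function(tree) {
    nt <- length(tree$tip.label)
    out <- as.list(seq_len(nt + tree$Nnode))
    po <- ape::reorder.phylo(tree, "postorder")$edge
    for (k in seq_len(nrow(po)))
        out[[po[k, 1L]]] <- c(out[[po[k, 1L]]], out[[po[k, 2L]]])
    out
}

#' Maximum inclusion (MI)
#'
#' First, every branch longer than \code{cutoff} (terminal or internal) is
#' cut and the tree decomposes into the resulting components -- this removes
#' potential pseudoorthologs on long branches.  Then, within each component,
#' the method repeatedly extracts the duplicate-free subtree (clade of the
#' midpoint-rooted component) with the largest number of distinct species,
#' provided it has at least \code{minTaxa} species, and re-analyzes the
#' remainder, stopping when no qualifying subtree is left.  A component that
#' is already duplicate-free is emitted whole.  Ties among equally large
#' subtrees prefer the smaller total branch length, then traversal order.
#'
#' @inheritParams filterSCC
#' @param cutoff long-branch cutoff in the tree's length units (the scale of
#'   the trees being analyzed: e.g. 0.4 substitutions/site for ML trees or
#'   500 changes for parsimony trees).  \code{Inf} disables cutting.
#' @return list of [OrthologSet-class] objects.
#' @export
extractMI <- function(family, minTaxa = 4L, cutoff = Inf) {
    tree <- family@tree
    if (is.finite(cutoff) && is.null(tree$edge.length))
        stop("a finite long-branch cutoff requires branch lengths")
    comps <- if (is.finite(cutoff)) {
        ## cut on the unrooted tree: a rooted representation splits one
        ## unrooted branch in two at the root, which would hide long root
        ## branches (and midpoint rooting would subdivide the longest one)
        if (length(tree$tip.label) > 2L && ape::is.rooted(tree))
            tree <- ape::unroot(tree)
        cuts <- which(tree$edge.length > cutoff)
        .componentsAfterCuts(tree, cuts)
    } else list(seq_along(tree$tip.label))
    out <- list()
    for (tipIdx in comps) {
        if (length(tipIdx) < max(2L, minTaxa)) next
        sub <- .rootedTree(pruneTo(tree, tree$tip.label[tipIdx]))
        repeat {
            sp <- resolveSpecies(sub$tip.label, family@map)
            if (!anyDuplicated(sp)) {
                if (length(unique(sp)) >= minTaxa)
                    out[[length(out) + 1L]] <-
                        .makeSet(family, sub$tip.label, "MI")
                break
            }
            flags <- .dupFreeFlags(sub, sp)
            clades <- .cladeTips(sub)
            root <- .rootNode(sub)
            cand <- setdiff(which(flags), root)
            if (!length(cand)) break
            nsp <- vapply(cand, function(v) length(unique(sp[clades[[v]]])),
                          integer(1))
            if (max(nsp) < minTaxa) break
            cand <- cand[nsp == max(nsp)]
            if (length(cand) > 1L) {
                cn <- .cladeNodes(sub)
                tl <- vapply(cand, function(v) .cladeLength(sub, v, cn),
                             numeric(1))
                tol <- 1e-12 * max(tl, 1)
                cand <- cand[tl <= min(tl) + tol]
                cand <- sort(cand)
            }
            v <- cand[1L]
            out[[length(out) + 1L]] <-
                .makeSet(family, sub$tip.label[clades[[v]]], "MI")
            rest <- setdiff(seq_along(sub$tip.label), clades[[v]])
            if (length(rest) < 2L) break
            sub <- pruneTo(sub, sub$tip.label[rest])
        }
    }
    out
}

#' Monophyletic outgroups (MO)
#'
#' Considers the family only when the outgroup copies present are
#' single-copy per outgroup species and monophyletic; it then roots the tree
#' on the outgroup clade and walks from root to tips, pruning at every
#' duplication node (a node whose child subtrees share at least one
#' species): the child with more distinct species is kept (ties: fewer gene
#' copies, then traversal order).  The surviving ingroup tree is returned
#' when at least \code{minTaxa} ingroup species remain.
#'
#' @inheritParams filterSCC
#' @param outgroups non-empty character vector of outgroup species ids,
#'   disjoint from the ingroup species of interest.
#' @return an [OrthologSet-class] (ingroup only), or \code{NULL} when there
#'   is no usable outgroup, the outgroup fails the single-copy or monophyly
#'   gates, or too few ingroup species survive.
#' @export
extractMO <- function(family, outgroups, minTaxa = 4L) {
    stopifnot(length(outgroups) >= 1L)
    tree <- family@tree
    sp <- resolveSpecies(tree$tip.label, family@map)
    ogTips <- which(sp %in% outgroups)
    if (!length(ogTips)) return(NULL)                    # no outgroup
    if (anyDuplicated(sp[ogTips])) return(NULL)          # multi-copy outgroup
    if (length(ogTips) < length(tree$tip.label) - 1L) {
        ## unrooted monophyly: outgroup tips must form one side of a branch
        clades <- .cladeTips(tree)
        sets <- lapply(clades, sort)
        og <- sort(ogTips)
        compl <- sort(setdiff(seq_along(tree$tip.label), ogTips))
        mono <- any(vapply(sets, function(s) identical(s, og) ||
                           identical(s, compl), logical(1)))
        if (!mono) return(NULL)
    }
    if (length(ogTips) == length(tree$tip.label)) return(NULL)
    rooted <- if (length(ogTips) < length(tree$tip.label) - 1L ||
                  length(ogTips) > 1L)
        ape::root(tree, outgroup = tree$tip.label[ogTips], resolve.root = TRUE)
    else
        ape::root(tree, outgroup = tree$tip.label[ogTips], resolve.root = TRUE)
    spR <- resolveSpecies(rooted$tip.label, family@map)
    clades <- .cladeTips(rooted)
    kids <- split(rooted$edge[, 2L], rooted$edge[, 1L])
    dropped <- integer(0)
    walk <- function(node) {
        ch <- kids[[as.character(node)]]
        if (is.null(ch)) return(invisible())
        spSets <- lapply(ch, function(c0) unique(spR[clades[[c0]]]))
        dup <- length(unlist(spSets)) > length(unique(unlist(spSets)))
        if (dup) {
            nsp <- lengths(spSets)
            best <- which(nsp == max(nsp))
            if (length(best) > 1L) {
                ncp <- vapply(ch[best], function(c0) length(clades[[c0]]),
                              integer(1))
                best <- best[ncp == min(ncp)]
            }
            best <- best[1L]
            for (i in seq_along(ch))
                if (i != best)
                    dropped <<- c(dropped, clades[[ch[i]]])
            walk(ch[best])
        } else {
            for (c0 in ch) walk(c0)
        }
    }
    walk(.rootNode(rooted))
    keep <- setdiff(seq_along(rooted$tip.label), dropped)
    ingroup <- keep[!spR[keep] %in% outgroups]
    if (!length(ingroup)) return(NULL)
    if (length(unique(spR[ingroup])) < minTaxa) return(NULL)
    .makeSet(family, rooted$tip.label[ingroup], "MO")
}

#' Randomly sample one copy per species
#'
#' Chooses one gene copy uniformly at random per represented species,
#' without regard to orthology.  The random stream is derived from
#' \code{(seed, familyId)}, so the selection for a family does not depend on
#' processing order and is reproducible.
#'
#' @inheritParams filterSCC
#' @param seed global integer seed.
#' @return an [OrthologSet-class] with provenance \code{ONE}, or \code{NULL}
#'   when fewer than \code{minTaxa} species are represented.
#' @export
sampleOneParalog <- function(family, minTaxa = 4L, seed = 1L) {
    sp <- .speciesOfTips(family)
    speciesIds <- sort(unique(sp))
    if (length(speciesIds) < minTaxa) return(NULL)
    chosen <- .withSeed(.deriveSeed(seed, family@familyId), {
        vapply(speciesIds, function(s) {
            copies <- family@tree$tip.label[sp == s]
            copies[sample.int(length(copies), 1L)]
        }, character(1))
    })
    .makeSet(family, chosen, "ONE")
}

#' Summary statistics over a family collection
#'
#' @param families non-empty list of [GeneFamily-class] objects.
#' @return list with \code{nFamilies}, \code{nCopies}, \code{meanCopies}
#'   (raw), \code{meanCopiesRounded} (nearest integer), and
#'   \code{occupancy}, a named integer vector giving, per species, the
#'   number of families it occurs in.
#' @export
familyStats <- function(families) {
    if (!length(families)) stop("empty family list")
    perFam <- lapply(families, function(f)
        unique(unname(.speciesOfTips(f))))
    nCopies <- sum(vapply(families, function(f)
        length(f@tree$tip.label), integer(1)))
    occ <- table(unlist(perFam))
    meanCopies <- nCopies / length(families)
    list(nFamilies = length(families),
         nCopies = nCopies,
         meanCopies = meanCopies,
         meanCopiesRounded = as.integer(round(meanCopies)),
         occupancy = setNames(as.integer(occ), names(occ)))
}
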