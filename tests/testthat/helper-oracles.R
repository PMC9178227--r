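## Independent oracles and fixture builders used across the suite.
## Oracles deliberately avoid the package's internal split machinery:
## clade enumeration goes through phangorn::Descendants.

## canonical keys of all non-trivial unrooted splits, by brute clade
## enumeration (phangorn code path, independent of OrthoDelta internals)
oracleSplits <- function(tree, labels = tree$tip.label) {
    n <- length(tree$tip.label)
    if (n < 4L) return(character(0))
    ref <- sort(labels)[1L]
    desc <- phangorn::Descendants(tree, (n + 1L):(n + tree$Nnode), "tips")
    keys <- character(0)
    for (tips in desc) {
        side <- labels[tips]
        if (ref %in% side) side <- setdiff(labels, side)
        if (length(side) >= 2L && length(side) <= n - 2L)
            keys <- c(keys, paste(sort(side), collapse = "\r"))
    }
    unique(keys)
}

## brute-force RF from the oracle split sets
oracleRF <- function(t1, t2) {
    k1 <- oracleSplits(t1); k2 <- oracleSplits(t2)
    length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

## classification of a gene tree at a quadripartition, re-derived from the
## definition using oracle splits
oracleClassify <- function(gtree, map, q) {
    sp <- resolveSpecies(gtree$tip.label, map)
    keep <- gtree$tip.label[sp %in% c(q$A, q$B, q$C, q$D)]
    if (length(keep) < 4L) return("NOT_DECISIVE")
    sub <- ape::keep.tip(gtree, keep)
    present <- unname(resolveSpecies(sub$tip.label, map))
    A <- intersect(q$A, present); B <- intersect(q$B, present)
    C <- intersect(q$C, present); D <- intersect(q$D, present)
    if (!length(A) || !length(B) || !length(C) || !length(D))
        return("NOT_DECISIVE")
    keys <- oracleSplits(sub, labels = present)
    ref <- sort(present)[1L]
    side <- function(x) {
        if (ref %in% x) x <- setdiff(present, x)
        paste(sort(x), collapse = "\r")
    }
    if (side(c(A, B)) %in% keys) return("CONCORDANT")
    if (side(c(A, C)) %in% keys) return("ALT1")
    if (side(c(B, C)) %in% keys) return("ALT2")
    "PARAPHYLETIC"
}

## brute-force subtree extraction: enumerate every rooted subtree of the
## trimmed tree, keep duplicate-free ones, select the maximal ones, apply
## the occupancy filter
oracleSE <- function(fam, minTaxa) {
    tr <- familyTree(trimTSD(fam))
    sp <- resolveSpecies(tr$tip.label)
    n <- length(tr$tip.label)
    tipsOf <- c(as.list(seq_len(n)),
                phangorn::Descendants(tr, (n + 1L):(n + tr$Nnode), "tips"))
    dupfree <- vapply(tipsOf, function(t) !anyDuplicated(sp[t]), logical(1))
    sets <- list()
    for (v in seq_along(tipsOf)) {
        if (!dupfree[v]) next
        p <- tr$edge[tr$edge[, 2L] == v, 1L]
        if (length(p) && dupfree[p]) next
        if (length(unique(sp[tipsOf[[v]]])) < minTaxa) next
        sets <- c(sets, list(sort(tr$tip.label[tipsOf[[v]]])))
    }
    sets
}

## sorted canonical form of a collection of ortholog sets, for comparison
setCollection <- function(sets) {
    keys <- lapply(sets, function(s)
        sort(if (is(s, "OrthologSet")) members(s) else s))
    keys[order(vapply(keys, paste, character(1), collapse = ","))]
}

## ultrametric caterpillar species tree on n species (a, b, c, ...) with
## every internal branch of the given length (coalescent units)
caterpillarTree <- function(n, internal = 0.5) {
    labs <- letters[seq_len(n)]
    cur <- sprintf("(%s:1,%s:1)", labs[1L], labs[2L])
    h <- 1
    for (i in 3:n) {
        cur <- sprintf("(%s:%g,%s:%g)", cur, internal, labs[i], h + internal)
        h <- h + internal
    }
    parseNewick(paste0(cur, ";"))
}

## random gene tree on the species of a species tree (uniform topology)
randomGeneTree <- function(stree) {
    tr <- ape::rtree(length(stree$tip.label))
    tr$tip.label <- sample(stree$tip.label)
    tr
}
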