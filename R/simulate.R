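## Synthetic-data generators: species trees, multispecies-coalescent (MSC)
## gene trees, duplication-loss gene families with true node labels, and
## closed-form triplet-count draws with optional introgression.
##
## All time is in coalescent units; duplication/loss rates are per copy per
## coalescent unit.  Every generator is reproducible given (seed, config).

#' Simulate a species tree
#'
#' Pure-birth (Yule) rooted binary ultrametric tree with branch lengths
#' interpreted as coalescent units.
#'
#' @param nSpecies number of species (>= 4).
#' @param speciationRate birth rate per lineage per coalescent unit.
#' @param seed integer seed.
#' @return an [ape::phylo] species tree with tips \code{s01, s02, ...}.
#' @export
simSpeciesTree <- function(nSpecies, speciationRate = 1, seed = 1L) {
    stopifnot(nSpecies >= 4L, speciationRate > 0)
    tr <- .withSeed(seed,
        ape::rphylo(nSpecies, birth = speciationRate, death = 0))
    tr$tip.label <- sprintf("s%02d", seq_len(nSpecies))
    tr
}

## ages (time above the tips) of all nodes of an ultrametric tree
.nodeAges <- function(tree) {
    n <- length(tree$tip.label)
    depth <- ape::node.depth.edgelength(tree)
    max(depth) - depth
}

## coalesce lineages along a branch from age t0 up to t1 (Inf at the root);
## each lineage is list(str=, age=); pairwise rate 1 per pair
.coalesceSegment <- function(lineages, t0, t1) {
    t <- t0
    while (length(lineages) >= 2L) {
        k <- length(lineages)
        w <- rexp(1L, rate = k * (k - 1) / 2)
        if (t + w >= t1) break
        t <- t + w
        ij <- sort(sample.int(k, 2L))
        a <- lineages[[ij[1L]]]; b <- lineages[[ij[2L]]]
        merged <- list(str = sprintf("(%s:%.10g,%s:%.10g)",
                                     a$str, t - a$age, b$str, t - b$age),
                       age = t)
        lineages[[ij[2L]]] <- NULL
        lineages[[ij[1L]]] <- merged
    }
    lineages
}

#' Simulate single-copy gene trees under the multispecies coalescent
#'
#' One gene lineage is sampled per species; within every species-tree
#' branch, lineages coalesce at rate 1 per pair (branch lengths in
#' coalescent units), and remaining lineages coalesce above the root.  For
#' a rooted triple with internal branch \eqn{T} this gives the classical
#' discordance probability \eqn{(2/3) e^{-T}}.
#'
#' @param stree ultrametric [ape::phylo] species tree, lengths in
#'   coalescent units.
#' @param nLoci number of independent loci.
#' @param seed integer seed.
#' @return list of [ape::phylo] gene trees; tips are the species labels.
#' @export
simMSCGeneTrees <- function(stree, nLoci, seed = 1L) {
    stopifnot(nLoci >= 1L)
    n <- length(stree$tip.label)
    ages <- .nodeAges(stree)
    kids <- split(stree$edge[, 2L], stree$edge[, 1L])
    root <- n + 1L
    ## internal nodes in order of increasing age: children always first
    ord <- (n + 1L):(n + stree$Nnode)
    ord <- ord[order(ages[ord])]
    .withSeed(seed, {
        lapply(seq_len(nLoci), function(locus) {
            lin <- vector("list", n + stree$Nnode)
            for (i in seq_len(n))
                lin[[i]] <- list(list(str = stree$tip.label[i], age = 0))
            for (v in ord) {
                pool <- list()
                for (c0 in kids[[as.character(v)]]) {
                    up <- .coalesceSegment(lin[[c0]], ages[c0], ages[v])
                    pool <- c(pool, up)
                }
                lin[[v]] <- pool
            }
            final <- .coalesceSegment(lin[[root]], ages[root], Inf)
            parseNewick(paste0(final[[1L]]$str, ";"))
        })
    })
}

#' Simulate a multi-copy gene family by duplication and loss
#'
#' A single gene copy enters at the species-tree root and evolves down the
#' tree; along every branch each extant copy duplicates at rate
#' \code{lambda} (spawning an independent subtree from that point) and is
#' lost at rate \code{mu}.  Surviving copies speciate at species-tree
#' nodes.  Internal nodes of the returned gene tree carry truth labels:
#' \code{"D"} for duplications, \code{"S"} for speciations (nodes left with
#' a single surviving child are suppressed).  With
#' \code{lambda = mu = 0} the gene tree reproduces the species tree
#' exactly, with all-\code{S} labels and one copy per species.
#'
#' @param stree rooted [ape::phylo] species tree with branch lengths.
#' @param lambda duplication rate per copy per coalescent unit.
#' @param mu loss rate per copy per coalescent unit.
#' @param seed integer seed (combined with \code{familyId}).
#' @param familyId identifier; also keys the family's random stream.
#' @param noiseSd optional lognormal branch-length noise (sdlog; 0 = off),
#'   useful to exercise distance-based tie-breaking downstream.
#' @return a [SimFamily-class], or \code{NULL} when all copies are lost.
#' @export
simDLFamily <- function(stree, lambda = 0.3, mu = 0.2, seed = 1L,
                        familyId = "fam", noiseSd = 0) {
    stopifnot(lambda >= 0, mu >= 0, noiseSd >= 0)
    if (is.null(stree$edge.length)) stop("species tree needs branch lengths")
    n <- length(stree$tip.label)
    kids <- split(stree$edge[, 2L], stree$edge[, 1L])
    elen <- numeric(n + stree$Nnode)
    elen[stree$edge[, 2L]] <- stree$edge.length
    counter <- integer(n)
    rate <- lambda + mu
    ## a copy at distance `remaining` above `node` on its branch; returns
    ## list(str, blen) for the surviving subtree, or NULL
    evolve <- function(node, remaining) {
        ev <- if (rate > 0) rexp(1L, rate) else Inf
        if (ev >= remaining) {
            if (node <= n) {                       # reached a species tip
                counter[node] <<- counter[node] + 1L
                return(list(str = paste0(stree$tip.label[node], "|",
                                         counter[node]),
                            blen = remaining))
            }
            ch <- kids[[as.character(node)]]
            rs <- lapply(ch, function(c0) evolve(c0, elen[c0]))
            rs <- rs[!vapply(rs, is.null, logical(1))]
            if (!length(rs)) return(NULL)
            if (length(rs) == 1L)
                return(list(str = rs[[1L]]$str,
                            blen = remaining + rs[[1L]]$blen))
            inner <- paste(vapply(rs, function(r)
                sprintf("%s:%.10g", r$str, r$blen), character(1)),
                collapse = ",")
            return(list(str = sprintf("(%s)S", inner), blen = remaining))
        }
        if (runif(1L) < lambda / rate) {           # duplication
            r1 <- evolve(node, remaining - ev)
            r2 <- evolve(node, remaining - ev)
            alive <- Filter(Negate(is.null), list(r1, r2))
            if (!length(alive)) return(NULL)
            if (length(alive) == 1L)
                return(list(str = alive[[1L]]$str,
                            blen = ev + alive[[1L]]$blen))
            return(list(str = sprintf("(%s:%.10g,%s:%.10g)D",
                                      alive[[1L]]$str, alive[[1L]]$blen,
                                      alive[[2L]]$str, alive[[2L]]$blen),
                        blen = ev))
        }
        NULL                                       # loss
    }
    ## the root "branch" has length 0, so the first event is always the
    ## root speciation itself
    top <- .withSeed(.deriveSeed(seed, familyId), evolve(n + 1L, 0))
    if (is.null(top)) return(NULL)
    str <- top$str
    if (!startsWith(str, "(")) {                   # single surviving copy
        tree <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = str,
                     edge.length = 0, Nnode = 1L, node.label = "S")
        class(tree) <- "phylo"
    } else {
        tree <- parseNewick(paste0(str, ";"))
    }
    if (noiseSd > 0 && !is.null(tree$edge.length) && nrow(tree$edge) > 0)
        tree$edge.length <- tree$edge.length *
            .withSeed(.deriveSeed(seed, paste0(familyId, "/noise")),
                      exp(rnorm(nrow(tree$edge), -noiseSd^2 / 2, noiseSd)))
    nd <- sum(tree$node.label == "D")
    new("SimFamily", tree = tree, map = speciesMap(),
        lengths = numeric(0), familyId = familyId,
        nDuplications = as.integer(nd))
}

#' @describeIn simDLFamily simulate a collection of families
#'   (\code{fam0001}, \code{fam0002}, ...); families in which every copy is
#'   lost are skipped, so fewer than \code{nFamilies} entries may return.
#' @param nFamilies number of families to draw.
#' @export
simDLFamilies <- function(stree, nFamilies, lambda = 0.3, mu = 0.2,
                          seed = 1L, noiseSd = 0) {
    fams <- lapply(seq_len(nFamilies), function(i)
        simDLFamily(stree, lambda, mu, seed,
                    familyId = sprintf("fam%04d", i), noiseSd = noiseSd))
    Filter(Negate(is.null), fams)
}

#' Triplet topology counts under the MSC with optional introgression
#'
#' Closed-form generator for the Delta test.  With probability
#' \code{1 - gamma} a locus follows the species history: concordant with
#' probability \eqn{1 - (2/3) e^{-\tau}} and each minor topology with
#' probability \eqn{(1/3) e^{-\tau}}, where \eqn{\tau} is the internal
#' branch length in coalescent units.  With probability \code{gamma} the
#' locus follows the introgressed history, whose major topology is the
#' first minor class: \code{alt1} receives \eqn{1 - (2/3) e^{-\tau'}} and
#' \code{concordant}/\code{alt2} each \eqn{(1/3) e^{-\tau'}}.
#'
#' @param nLoci number of loci to draw.
#' @param tau internal branch length (coalescent units).
#' @param tauPrime post-introgression internal branch length.
#' @param gamma introgression fraction in \code{[0, 1]}.
#' @param seed integer seed.
#' @return named integer vector \code{c(concordant, alt1, alt2)} summing to
#'   \code{nLoci}; the class probabilities are attached as attribute
#'   \code{"prob"}.
#' @export
simTripletCounts <- function(nLoci, tau = 1, tauPrime = tau, gamma = 0,
                             seed = 1L) {
    stopifnot(nLoci >= 1L, tau >= 0, tauPrime >= 0, gamma >= 0, gamma <= 1)
    pSpec <- c(1 - (2 / 3) * exp(-tau),
               (1 / 3) * exp(-tau),
               (1 / 3) * exp(-tau))
    pIntro <- c((1 / 3) * exp(-tauPrime),
                1 - (2 / 3) * exp(-tauPrime),
                (1 / 3) * exp(-tauPrime))
    p <- (1 - gamma) * pSpec + gamma * pIntro
    counts <- .withSeed(seed, as.integer(rmultinom(1L, nLoci, p)))
    out <- setNames(counts, c("concordant", "alt1", "alt2"))
    attr(out, "prob") <- setNames(p, names(out))
    out
}

#' True ortholog groups of a simulated family
#'
#' The maximal duplication-free clades of the truth-labelled gene tree:
#' each group is the leaf set of a largest clade containing no \code{"D"}
#' node, i.e. a set of copies whose history within the clade consists of
#' speciations only.  Groups are disjoint and jointly cover all copies.
#'
#' @param fam a [SimFamily-class].
#' @param minTaxa minimum number of distinct species per reported group.
#' @return list of character vectors of copy ids.
#' @export
trueOrthologSets <- function(fam, minTaxa = 1L) {
    tree <- fam@tree
    nt <- length(tree$tip.label)
    lab <- tree$node.label
    hasD <- logical(nt + tree$Nnode)
    po <- ape::reorder.phylo(tree, "postorder")$edge
    for (v in (nt + 1L):(nt + tree$Nnode))
        hasD[v] <- identical(lab[v - nt], "D")
    for (k in seq_len(nrow(po)))
        hasD[po[k, 1L]] <- hasD[po[k, 1L]] || hasD[po[k, 2L]]
    par <- .parents(tree)
    clades <- .cladeTips(tree)
    sp <- .speciesOfTips(fam)
    out <- list()
    for (v in seq_along(hasD)) {
        if (hasD[v]) next
        p <- par[v]
        if (p != 0L && !hasD[p]) next          # not maximal
        tips <- clades[[v]]
        if (length(unique(sp[tips])) < minTaxa) next
        out[[length(out) + 1L]] <- tree$tip.label[tips]
    }
    out
}
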