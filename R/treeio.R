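## Newick I/O and elementary tree surgery.  Trees are ape "phylo" objects
## throughout; branch lengths are substitutions/site (ML), change counts
## (MP) or coalescent units (simulations) depending on provenance.

#' Parse a Newick string
#'
#' Strict wrapper around [ape::read.tree()]: the text must be a single
#' well-formed Newick statement terminated by \code{";"}, with unique leaf
#' labels.  Quoted labels, internal-node labels (kept as annotations, not
#' taxa), missing branch lengths and scientific-notation lengths are all
#' accepted, since inputs come from heterogeneous inference tools.
#'
#' @param text a single Newick string.
#' @return an [ape::phylo] object.
#' @examples
#' tr <- parseNewick("(A:1,B:2);")
#' @export
parseNewick <- function(text) {
    if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
        stop("empty Newick input")
    text <- trimws(text)
    ## parenthesis balance check with position of first offence
    bare <- gsub("'[^']*'", "", text)   # ignore parentheses inside quotes
    depth <- 0L
    chars <- strsplit(bare, "", fixed = TRUE)[[1L]]
    for (i in seq_along(chars)) {
        if (chars[i] == "(") depth <- depth + 1L
        else if (chars[i] == ")") {
            depth <- depth - 1L
            if (depth < 0L)
                stop("unbalanced parentheses at position ", i)
        }
    }
    if (depth != 0L)
        stop("unbalanced parentheses: ", depth, " '(' left open")
    if (!grepl(";", text, fixed = TRUE))
        stop("Newick statement must be terminated by ';'")
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr) || is.null(tr$tip.label))
        stop("malformed Newick string")
    if (anyDuplicated(tr$tip.label))
        stop("duplicate leaf labels: ",
             paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                   collapse = ", "))
    tr
}

#' Serialize a tree to Newick
#'
#' \code{parseNewick(writeNewick(t))} reproduces the topology, labels and
#' branch lengths of \code{t}.
#'
#' @param tree an [ape::phylo] object.
#' @param file optional path; when given, the Newick line is written there.
#' @return the Newick string, invisibly when \code{file} is given.
#' @export
writeNewick <- function(tree, file = NULL) {
    txt <- ape::write.tree(tree, digits = 12)
    if (!is.null(file)) {
        writeLines(txt, file)
        return(invisible(txt))
    }
    txt
}

#' Read trees from a file or directory
#'
#' A single file may hold one tree per line (\dQuote{treelist} mode); a
#' directory is read as one Newick file per tree (files sorted by name for
#' reproducibility).
#'
#' @param path file or directory path.
#' @return a list of [ape::phylo] objects, named by file or line.
#' @export
readTrees <- function(path) {
    if (dir.exists(path)) {
        files <- sort(list.files(path, pattern = "\\.(nwk|newick|tre|treefile|txt)$",
                                 full.names = TRUE))
        if (!length(files)) stop("no Newick files found in ", path)
        trees <- lapply(files, function(f)
            parseNewick(paste(readLines(f, warn = FALSE), collapse = "")))
        names(trees) <- basename(files)
        return(trees)
    }
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("no trees in ", path)
    trees <- lapply(lines, parseNewick)
    names(trees) <- sprintf("tree%04d", seq_along(trees))
    trees
}

## tip indices of the clade below every node, indexed 1..(Ntip+Nnode)
.cladeTips <- function(tree) {
    nt <- length(tree$tip.label)
    out <- vector("list", nt + tree$Nnode)
    for (i in seq_len(nt)) out[[i]] <- i
    po <- ape::reorder.phylo(tree, "postorder")$edge
    for (k in seq_len(nrow(po))) {
        p <- po[k, 1L]; ch <- po[k, 2L]
        out[[p]] <- c(out[[p]], out[[ch]])
    }
    out
}

## canonical keys of the non-trivial bipartitions (unrooted splits) of a tree;
## labels defaults to tip labels but may be any per-tip relabelling
.splitKeys <- function(tree, labels = tree$tip.label) {
    n <- length(tree$tip.label)
    if (n < 4L) return(character(0))
    ref <- sort(labels)[1L]
    clades <- .cladeTips(tree)
    keys <- character(0)
    nt <- n
    for (node in (nt + 1L):(nt + tree$Nnode)) {
        side <- labels[clades[[node]]]
        if (ref %in% side) side <- setdiff(labels, side)
        if (length(side) < 2L || length(side) > n - 2L) next
        keys <- c(keys, paste(sort(side), collapse = "\r"))
    }
    unique(keys)
}

#' Robinson-Foulds distance
#'
#' Symmetric difference of the non-trivial bipartition sets of two trees on
#' the same leaves.  The normalized value divides by the total number of
#' non-trivial splits present in the two trees, which handles polytomies and
#' reduces to \eqn{2(n-3)} for two binary trees.
#'
#' @param t1,t2 [ape::phylo] trees on identical leaf sets (>= 4 leaves).
#' @return list with elements \code{raw} (integer) and \code{normalized}
#'   (in \code{[0,1]}).
#' @examples
#' rfDistance(parseNewick("((A,B),(C,D));"), parseNewick("((A,C),(B,D));"))
#' @export
rfDistance <- function(t1, t2) {
    l1 <- t1$tip.label; l2 <- t2$tip.label
    if (!setequal(l1, l2)) {
        only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
        stop("leaf sets differ; only in tree 1: {",
             paste(only1, collapse = ","), "}; only in tree 2: {",
             paste(only2, collapse = ","), "}")
    }
    if (length(l1) < 4L) stop("RF distance needs >= 4 leaves")
    k1 <- .splitKeys(t1); k2 <- .splitKeys(t2)
    raw <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
    denom <- length(k1) + length(k2)
    list(raw = as.integer(raw),
         normalized = if (denom > 0L) raw / denom else 0)
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique path between leaves \code{a} and
#' \code{b}.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param a,b leaf labels.
#' @return non-negative numeric.
#' @export
patristicDistance <- function(tree, a, b) {
    if (is.null(tree$edge.length)) stop("tree has no branch lengths")
    ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
    if (is.na(ia) || is.na(ib))
        stop("leaf not in tree: ", paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "))
    if (ia == ib) return(0)
    ape::dist.nodes(tree)[ia, ib]
}

#' Prune a tree to a subset of leaves
#'
#' Removes all leaves not in \code{keep} and suppresses the resulting
#' degree-2 nodes, summing branch lengths, so that path lengths among kept
#' leaves are conserved.
#'
#' @param tree [ape::phylo].
#' @param keep character vector of leaf labels (subset of the tree's).
#' @return the pruned [ape::phylo]; for a single kept leaf, a one-tip tree
#'   whose branch length is that leaf's root-to-tip depth.
#' @export
pruneTo <- function(tree, keep) {
    keep <- unique(keep)
    unknown <- setdiff(keep, tree$tip.label)
    if (length(unknown))
        stop("unknown leaf labels: ", paste(unknown, collapse = ", "))
    if (!length(keep)) stop("'keep' must contain at least one leaf")
    if (length(keep) == length(tree$tip.label)) return(tree)
    if (length(keep) == 1L) {
        depth <- if (is.null(tree$edge.length)) 0 else
            ape::node.depth.edgelength(tree)[match(keep, tree$tip.label)]
        out <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = keep,
                    edge.length = depth, Nnode = 1L)
        class(out) <- "phylo"
        return(out)
    }
    ape::keep.tip(tree, keep)
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.  When
#' several paths attain the maximum, the lexicographically smallest leaf
#' pair is used, so the result is deterministic.  When the midpoint falls
#' exactly on a node, the incident path edge nearer the first leaf of the
#' chosen pair is subdivided at the node (one root child edge has length 0).
#' Total tree length is conserved.
#'
#' @param tree [ape::phylo] with branch lengths, >= 2 leaves.
#' @return a rooted [ape::phylo] whose two deepest root-to-leaf paths are
#'   equal (up to numerical tolerance).
#' @export
midpointRoot <- function(tree) {
    if (is.null(tree$edge.length))
        stop("midpoint rooting requires branch lengths")
    n <- length(tree$tip.label)
    if (n < 2L) stop("midpoint rooting requires >= 2 leaves")
    total <- sum(tree$edge.length)
    if (total <= 0) {
        warning("all branch lengths are zero; rooting on first edge in traversal order")
        return(phytools::reroot(tree, node.number = tree$edge[1L, 2L],
                                position = 0))
    }
    if (n == 2L) {
        tree$edge.length <- rep(total / 2, length(tree$edge.length))
        return(tree)
    }
    D <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
    dmax <- max(D)
    tol <- 1e-12 * max(dmax, 1)
    idx <- which(D >= dmax - tol, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    pairLab <- cbind(tree$tip.label[idx[, 1L]], tree$tip.label[idx[, 2L]])
    pairKey <- apply(pairLab, 1L, function(r) paste(sort(r), collapse = "\r"))
    best <- order(pairKey)[1L]
    ia <- idx[best, 1L]; ib <- idx[best, 2L]
    if (tree$tip.label[ia] > tree$tip.label[ib]) { tmp <- ia; ia <- ib; ib <- tmp }
    half <- D[ia, ib] / 2
    path <- ape::nodepath(tree, ia, ib)
    elen <- function(u, v) {
        k <- which((tree$edge[, 1L] == u & tree$edge[, 2L] == v) |
                   (tree$edge[, 1L] == v & tree$edge[, 2L] == u))
        tree$edge.length[k[1L]]
    }
    cum <- 0
    for (i in seq_len(length(path) - 1L)) {
        L <- elen(path[i], path[i + 1L])
        if (cum + L >= half - tol) {
            x <- min(max(half - cum, 0), L)   # distance from path[i]
            k <- which(tree$edge[, 1L] == path[i] & tree$edge[, 2L] == path[i + 1L])
            if (length(k)) {   # walking down: parent is path[i]
                child <- path[i + 1L]; posFromParent <- x
            } else {           # walking up: parent is path[i+1]
                child <- path[i]; posFromParent <- L - x
            }
            out <- phytools::reroot(tree, node.number = child,
                                    position = posFromParent)
            return(out)
        }
        cum <- cum + L
    }
    stop("internal error: midpoint not located")   # nocov
}

#' Collapse short internal branches into polytomies
#'
#' Every internal branch whose length is \code{<= tol} is contracted.
#' Terminal branches are never collapsed (a leaf cannot be removed by
#' contraction), and the leaf set is unchanged.  The default \code{tol = 0}
#' collapses exact zero-length branches only.
#'
#' @param tree [ape::phylo] with branch lengths on internal edges.
#' @param tol non-negative length threshold.
#' @return [ape::phylo], possibly with polytomies.
#' @export
collapseShortBranches <- function(tree, tol = 0) {
    if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol < 0)
        stop("'tol' must be a single non-negative number")
    if (is.null(tree$edge.length)) stop("tree has no branch lengths")
    nt <- length(tree$tip.label)
    mark <- tree$edge[, 2L] > nt & tree$edge.length <= tol
    if (!any(mark)) return(tree)
    ## sentinel: di2multi contracts edges with length < its tol (strict),
    ## so flag exactly the chosen edges with a negative length
    tree$edge.length[mark] <- -1
    out <- ape::di2multi(tree, tol = 0)
    out
}
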