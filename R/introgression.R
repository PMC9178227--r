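## The Delta minor-topology asymmetry test for introgression.
##
## Under the multispecies coalescent without gene flow, the two minor
## (discordant) resolutions of a species-tree branch are equally probable,
## so Delta = (nDF1 - nDF2)/(nDF1 + nDF2) is expected to be zero; gene flow
## inflates one minor topology and pushes Delta toward one.

#' The Delta statistic
#'
#' \code{(nDF1 - nDF2) / (nDF1 + nDF2)}, where DF1 is the most common and
#' DF2 the least common minor topology at a branch.  Counts are reordered
#' internally, so the result lies in \code{[0, 1]} and is invariant to
#' which minor class is labelled first.
#'
#' @param nDF1,nDF2 non-negative counts of the two minor topologies.
#' @return Delta in \code{[0,1]}; \code{NA} (with a warning) when both
#'   counts are zero, in which case the branch is reported untested.
#' @examples
#' deltaStatistic(75, 25)   # 0.5
#' @export
deltaStatistic <- function(nDF1, nDF2) {
    stopifnot(length(nDF1) == 1L, length(nDF2) == 1L,
              nDF1 >= 0, nDF2 >= 0)
    if (nDF1 + nDF2 == 0) {
        warning("no discordant gene trees: Delta undefined")
        return(NA_real_)
    }
    abs(nDF1 - nDF2) / (nDF1 + nDF2)
}

#' Dunn-Sidak per-test level
#'
#' \code{1 - (1 - alpha)^(1/m)}: the per-test significance level that
#' controls the family-wise error at \code{alpha} across \code{m}
#' independent tests.  Equals \code{alpha} at \code{m = 1} and is strictly
#' decreasing in \code{m}.
#'
#' @param m number of tests (>= 1).
#' @param alpha family-wise level in (0, 1).
#' @return the adjusted per-test level.
#' @export
sidakThreshold <- function(m, alpha = 0.05) {
    if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1)
        stop("'m' must be a positive number of tests")
    stopifnot(alpha > 0, alpha < 1)
    1 - (1 - alpha)^(1 / m)
}

#' Bootstrap null for the Delta statistic at one branch
#'
#' Fixes the identities of DF1 and DF2 from the observed counts, then draws
#' \code{B} resamples (with replacement, same size) of the branch's
#' classification list -- all decisive gene trees, not only the discordant
#' ones, so the discordant count varies across replicates exactly as it
#' would under gene-tree resampling.  Per replicate the signed statistic
#' \code{(n_DF1 - n_DF2)/(n_DF1 + n_DF2)} is computed (it may be negative
#' because DF1/DF2 are not re-identified).  The Z-score divides the
#' observed Delta by the bootstrap standard deviation; the p-value is the
#' two-sided normal tail.  \code{pMethod = "percentile"} instead reports
#' the fraction of replicates whose \code{|Delta_b|} reaches the observed
#' value.
#'
#' Because resampling a label list with replacement is a multinomial draw
#' over the label classes, the replicates are generated directly from
#' \code{rmultinom} on the observed class counts; this is exact, not an
#' approximation.
#'
#' @param labels character vector of per-gene-tree classifications for one
#'   branch (values among \code{CONCORDANT}, \code{ALT1}, \code{ALT2},
#'   \code{PARAPHYLETIC}; non-decisive trees must already be excluded), or
#'   a named count vector with those names.
#' @param B number of bootstrap replicates.
#' @param seed integer seed for the branch's random stream.
#' @param pMethod \code{"normal"} (default) or \code{"percentile"}.
#' @return list with \code{delta} (observed), \code{sdBoot}, \code{z},
#'   \code{p}, \code{nDF1}, \code{nDF2}.
#' @export
bootstrapDelta <- function(labels, B = 2000L, seed = 1L,
                           pMethod = c("normal", "percentile")) {
    pMethod <- match.arg(pMethod)
    stopifnot(B >= 1L)
    classes <- c("CONCORDANT", "ALT1", "ALT2", "PARAPHYLETIC")
    if (is.numeric(labels) && !is.null(names(labels))) {
        counts <- setNames(numeric(4), classes)
        counts[names(labels)] <- labels
    } else {
        bad <- setdiff(unique(labels), c(classes, "NOT_DECISIVE"))
        if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
        labels <- labels[labels != "NOT_DECISIVE"]
        counts <- vapply(classes, function(k) sum(labels == k), numeric(1))
    }
    n <- sum(counts)
    if (counts["ALT1"] + counts["ALT2"] == 0)
        stop("no discordant (minor-topology) gene trees at this branch")
    ## DF1 fixed from the observed counts; ALT1 wins ties deterministically
    df1 <- if (counts["ALT2"] > counts["ALT1"]) "ALT2" else "ALT1"
    df2 <- setdiff(c("ALT1", "ALT2"), df1)
    deltaObs <- (counts[df1] - counts[df2]) / (counts[df1] + counts[df2])
    reps <- .withSeed(seed,
        rmultinom(B, size = n, prob = counts / n))
    rownames(reps) <- classes
    num <- reps[df1, ] - reps[df2, ]
    den <- reps[df1, ] + reps[df2, ]
    deltaB <- ifelse(den > 0, num / den, 0)
    sdBoot <- sd(deltaB)
    if (sdBoot == 0) {
        warning("degenerate bootstrap null (zero variance); p set to 1")
        z <- if (deltaObs == 0) 0 else Inf
        p <- 1
    } else {
        z <- deltaObs / sdBoot
        p <- switch(pMethod,
                    normal = 2 * pnorm(-abs(z)),
                    percentile = mean(abs(deltaB) >= deltaObs))
        if (pMethod == "percentile" && p == 0) p <- 1 / (B + 1)
    }
    list(delta = unname(deltaObs), sdBoot = sdBoot, z = unname(z),
         p = unname(p),
         nDF1 = unname(counts[df1]), nDF2 = unname(counts[df2]))
}

#' Branch-wise introgression test over a set of gene trees
#'
#' Classifies every gene tree at every internal branch of the species tree
#' (via [concordanceTable()]), gates branches whose discordant fraction
#' exceeds \code{minDiscordance}, runs the bootstrap Delta test on each
#' gated-in branch, and applies the Dunn-Sidak correction with \code{m}
#' equal to the number of branches actually tested.  Per-branch random
#' streams are derived from \code{(seed, branch id)}, so adding or removing
#' branches never perturbs the others.
#'
#' @param gtrees list of single-copy-per-species [ape::phylo] gene trees.
#' @param map a [SpeciesMap-class].
#' @param stree rooted binary [ape::phylo] species tree.
#' @param B bootstrap replicates (default 2000).
#' @param alpha family-wise significance level (default 0.05).
#' @param minDiscordance gate: branches with a discordant fraction at or
#'   below this value are reported but not tested (default 0.05).
#' @param seed master integer seed.
#' @param pMethod p-value method, see [bootstrapDelta()].
#' @return data.frame with one row per internal branch (tested or not):
#'   \code{branch_id}, \code{n_decisive}, \code{n_concordant}, \code{nDF1},
#'   \code{nDF2}, \code{delta}, \code{sd_boot}, \code{z}, \code{p},
#'   \code{alpha_adjusted}, \code{significant}, \code{tested}.
#' @export
testIntrogression <- function(gtrees, map = speciesMap(), stree,
                              B = 2000L, alpha = 0.05,
                              minDiscordance = 0.05, seed = 1L,
                              pMethod = c("normal", "percentile")) {
    pMethod <- match.arg(pMethod)
    stopifnot(B >= 1L, alpha > 0, alpha < 1,
              minDiscordance >= 0, minDiscordance < 1)
    bc <- concordanceTable(gtrees, map, stree)
    frac <- suppressWarnings(discordantFraction(bc))
    testable <- !is.na(frac) & frac > minDiscordance &
        (bc$n_alt1 + bc$n_alt2) > 0
    m <- sum(testable)
    alphaAdj <- if (m > 0) sidakThreshold(m, alpha) else NA_real_
    k <- nrow(bc)
    out <- data.frame(
        branch_id = bc$branch_id,
        n_decisive = bc$n_decisive,
        n_concordant = bc$n_concordant,
        nDF1 = pmax(bc$n_alt1, bc$n_alt2),
        nDF2 = pmin(bc$n_alt1, bc$n_alt2),
        delta = NA_real_, sd_boot = NA_real_, z = NA_real_, p = NA_real_,
        alpha_adjusted = rep(alphaAdj, k),
        significant = FALSE, tested = testable,
        stringsAsFactors = FALSE)
    for (i in which(testable)) {
        counts <- c(CONCORDANT = bc$n_concordant[i], ALT1 = bc$n_alt1[i],
                    ALT2 = bc$n_alt2[i], PARAPHYLETIC = bc$n_paraphyletic[i])
        res <- bootstrapDelta(counts, B = B,
                              seed = .deriveSeed(seed, bc$branch_id[i]),
                              pMethod = pMethod)
        out$delta[i] <- res$delta
        out$sd_boot[i] <- res$sdBoot
        out$z[i] <- res$z
        out$p[i] <- res$p
        out$significant[i] <- is.finite(res$p) && res$p < alphaAdj
    }
    attr(out, "concordance") <- bc
    attr(out, "m") <- m
    out
}
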