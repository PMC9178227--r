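## Gene-family decomposition methods.  Small hand-built families exercise
## the documented rules; simulated families check the global invariants.

fam <- function(nwk, ...) geneFamily(nwk, ...)

test_that("single-copy filter keeps exactly the single-copy, occupied families", {
    f1 <- fam("((a|1:1,b|1:1):1,(c|1:1,(d|1:1,e|1:1):1):1);")
    s <- filterSCC(f1, minTaxa = 4)
    expect_s4_class(s, "OrthologSet")
    expect_equal(provenance(s), "SCC")
    expect_length(removedCopies(s), 0)

    expect_null(filterSCC(fam("((a|1:1,a|2:1):1,b|1:1);"), minTaxa = 2))
    expect_null(filterSCC(fam("(a|1:1,(b|1:1,c|1:1):1);"), minTaxa = 4))
})

test_that("LSD trimming keeps the copy nearest the family-wide median length", {
    f <- fam("((A|1:1,A|2:1):1,B|1:1);",
             lengths = c("A|1" = 300, "A|2" = 200, "B|1" = 250))
    out <- trimLSD(f)
    ## median 250; |300-250| == |200-250| -> tie broken by input order: A|1
    expect_setequal(familyTree(out)$tip.label, c("A|1", "B|1"))

    ## no duplicates: identity
    f2 <- fam("((A|1:1,B|1:1):1,C|1:1);")
    expect_setequal(familyTree(trimLSD(f2))$tip.label,
                    familyTree(f2)$tip.label)

    ## nested single-species clade collapses to one copy
    f3 <- fam("(((A|1:1,A|2:1):1,A|3:1):1,B|1:3);")
    out3 <- trimLSD(f3)
    spp <- resolveSpecies(familyTree(out3)$tip.label)
    expect_equal(sum(spp == "A"), 1L)
    expect_equal(sum(spp == "B"), 1L)

    ## without lengths: smallest root-to-tip distance survives
    f4 <- fam("((A|1:0.1,A|2:2):1,(B|1:1,C|1:1):1);")
    out4 <- familyTree(trimLSD(f4))
    expect_true("A|1" %in% out4$tip.label)
    expect_false("A|2" %in% out4$tip.label)

    ## idempotent, and only removes leaves
    again <- trimLSD(out3)
    expect_setequal(familyTree(again)$tip.label, familyTree(out3)$tip.label)
    expect_true(all(familyTree(out3)$tip.label %in% familyTree(f3)$tip.label))
})

test_that("TSD trimming keeps the closest cross-species pair", {
    f <- fam("((A|1:1,B|1:1):1,(A|2:5,B|2:5):1);")
    out <- trimTSD(f)
    expect_setequal(familyTree(out)$tip.label, c("A|1", "B|1"))

    ## A1,A2,B1 clade: keep B1 plus the A copy nearer to B1
    f2 <- fam("(((A|1:1,B|1:1):1,A|2:2):1,C|1:6);")
    out2 <- trimTSD(f2)
    expect_setequal(familyTree(out2)$tip.label, c("A|1", "B|1", "C|1"))

    ## two-leaf cross-species cherry untouched
    f3 <- fam("((A|1:1,B|1:1):1,C|1:1);")
    expect_setequal(familyTree(trimTSD(f3))$tip.label,
                    familyTree(f3)$tip.label)

    ## idempotence
    expect_setequal(familyTree(trimTSD(out))$tip.label,
                    familyTree(out)$tip.label)
})

test_that("subtree extraction returns maximal duplicate-free subtrees", {
    ## multi-copy family with a nested duplicate, as-given rooting (no lengths)
    f <- fam("(((A|1,B|1),(A|2,C|1)),D|1);")
    sets <- extractSE(f, minTaxa = 2)
    expect_equal(setCollection(sets),
                 setCollection(list(c("A|1", "B|1"), c("A|2", "C|1"))))

    ## duplicate-free family: the whole tree, at the root
    f2 <- fam("((a|1:1,b|1:1):1,(c|1:1,d|1:1):1);")
    sets2 <- extractSE(f2, minTaxa = 4)
    expect_length(sets2, 1L)
    expect_setequal(members(sets2[[1]]), familyTree(f2)$tip.label)

    ## no output set repeats a species
    for (s in c(sets, sets2))
        expect_false(anyDuplicated(resolveSpecies(members(s))) > 0)
})

test_that("maximum inclusion iterates and emits duplicate-free remainders whole", {
    f <- fam("(((A|1,B|1),(A|2,C|1)),D|1);")
    sets <- extractMI(f, minTaxa = 2)
    ## first extraction {A1,B1}; the remainder ((A2,C1),D1) is duplicate-free
    ## and re-queued whole
    expect_equal(setCollection(sets),
                 setCollection(list(c("A|1", "B|1"), c("A|2", "C|1", "D|1"))))

    ## duplication-free tree emitted whole
    f2 <- fam("((a|1:1,b|1:1):1,(c|1:1,d|1:1):1);")
    sets2 <- extractMI(f2, minTaxa = 4)
    expect_length(sets2, 1L)
    expect_setequal(members(sets2[[1]]), familyTree(f2)$tip.label)
})

test_that("the MI long-branch cutoff removes long-branch leaves from every set", {
    ## d sits on a 0.5 branch; cutoff 0.4 cuts it off
    f <- fam("((a|1:0.1,b|1:0.1):0.1,(c|1:0.1,d|1:0.5):0.1);")
    sets <- extractMI(f, minTaxa = 2, cutoff = 0.4)
    expect_true(length(sets) >= 1L)
    expect_false(any(vapply(sets, function(s) "d|1" %in% members(s),
                            logical(1))))
    ## without a cutoff the whole (duplicate-free) family survives
    sets2 <- extractMI(f, minTaxa = 2)
    expect_setequal(members(sets2[[1]]), familyTree(f)$tip.label)
    expect_error(extractMI(fam("((a|1,b|1),c|1);"), 2, cutoff = 0.4),
                 "branch lengths")
})

test_that("monophyletic-outgroup pruning gates and prunes at duplications", {
    ## outgroup not monophyletic: nothing
    f1 <- fam("((A|1:1,O|1:1):1,(B|1:1,P|1:1):1);")
    expect_null(extractMO(f1, outgroups = c("O", "P"), minTaxa = 2))

    ## duplication-free with monophyletic outgroup: full ingroup back
    f2 <- fam("(((A|1:1,B|1:1):1,C|1:1):1,(O|1:1,P|1:1):2);")
    s2 <- extractMO(f2, outgroups = c("O", "P"), minTaxa = 3)
    expect_setequal(members(s2), c("A|1", "B|1", "C|1"))

    ## root-adjacent duplication: larger-species side kept
    f3 <- fam(paste0("(((A|1:1,(B|1:1,(C|1:1,(D|1:1,E|1:1):1):1):1):1,",
                     "(A|2:1,B|2:1):1):1,(O|1:1,P|1:1):2);"))
    s3 <- extractMO(f3, outgroups = c("O", "P"), minTaxa = 2)
    expect_setequal(members(s3), c("A|1", "B|1", "C|1", "D|1", "E|1"))

    ## multi-copy outgroup species: nothing
    f4 <- fam("((A|1:1,B|1:1):1,(O|1:1,O|2:1):1);")
    expect_null(extractMO(f4, outgroups = "O", minTaxa = 2))
    ## no outgroup present: nothing
    expect_null(extractMO(f2, outgroups = "Z", minTaxa = 2))
})

test_that("one-paralog sampling is deterministic per (seed, family) and complete", {
    f <- fam("((A|1:1,A|2:1):1,(B|1:1,(C|1:1,C|2:1):1):1);", familyId = "fx")
    s1 <- sampleOneParalog(f, minTaxa = 2, seed = 7)
    s2 <- sampleOneParalog(f, minTaxa = 2, seed = 7)
    expect_identical(members(s1), members(s2))
    expect_equal(provenance(s1), "ONE")
    sp <- resolveSpecies(members(s1))
    expect_setequal(unname(sp), c("A", "B", "C"))
    expect_false(anyDuplicated(sp) > 0)
    expect_true("B|1" %in% members(s1))     # forced single-copy choice
    expect_null(sampleOneParalog(f, minTaxa = 4, seed = 7))

    ## different seeds eventually differ (4 possible selections)
    picks <- vapply(1:20, function(s)
        paste(members(sampleOneParalog(f, 2, seed = s)), collapse = ","),
        character(1))
    expect_gt(length(unique(picks)), 1L)
})

test_that("family statistics add up", {
    f3 <- fam("((x|1:1,y|1:1):1,z|1:1);", familyId = "a")
    f5 <- fam("((x|1:1,x|2:1):1,(y|1:1,(z|1:1,w|1:1):1):1);", familyId = "b")
    st <- familyStats(list(f3, f5))
    expect_equal(st$nFamilies, 2L)
    expect_equal(st$nCopies, 8L)
    expect_equal(st$meanCopies, 4)
    expect_equal(st$meanCopiesRounded, 4L)
    expect_equal(unname(st$occupancy[c("x", "w")]), c(2L, 1L))
    expect_equal(familyStats(list(f3))$meanCopies, 3)
    expect_error(familyStats(list()), "empty")
})

test_that("no decomposition method ever emits a species twice (simulated families)", {
    st <- simSpeciesTree(8, 1, seed = 77)
    fams <- simDLFamilies(st, 120, lambda = 0.5, mu = 0.3, seed = 77)
    checkSets <- function(sets) {
        for (s in sets) {
            if (is.null(s)) next
            sp <- resolveSpecies(members(s))
            expect_false(anyDuplicated(sp) > 0)
        }
    }
    for (f in fams) {
        checkSets(list(filterSCC(f, 2)))
        checkSets(extractSE(f, 2))
        checkSets(extractMI(f, 2))
        checkSets(list(extractMO(f, outgroups = "s01", minTaxa = 2)))
        checkSets(list(sampleOneParalog(f, 2, seed = 9)))
        ## trims only remove leaves and leave no trimmable clade behind
        tt <- trimTSD(f)
        expect_true(all(familyTree(tt)$tip.label %in%
                        familyTree(f)$tip.label))
        sp <- resolveSpecies(familyTree(tt)$tip.label)
        again <- trimTSD(tt)
        expect_setequal(familyTree(again)$tip.label,
                        familyTree(tt)$tip.label)
    }
})

test_that("on duplication-free simulations every method returns the family intact", {
    st <- simSpeciesTree(7, 1, seed = 5)
    fams <- simDLFamilies(st, 25, lambda = 0, mu = 0, seed = 5)
    for (f in fams) {
        tips <- familyTree(f)$tip.label
        expect_setequal(members(filterSCC(f, 4)), tips)
        expect_setequal(familyTree(trimLSD(f))$tip.label, tips)
        expect_setequal(familyTree(trimTSD(f))$tip.label, tips)
        se <- extractSE(f, 4); mi <- extractMI(f, 4)
        expect_length(se, 1L); expect_length(mi, 1L)
        expect_setequal(members(se[[1]]), tips)
        expect_setequal(members(mi[[1]]), tips)
        mo <- extractMO(f, outgroups = "s01", minTaxa = 4)
        expect_setequal(members(mo),
                        setdiff(tips, tips[startsWith(tips, "s01")]))
    }
})
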