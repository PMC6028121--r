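test_that("QIIME-classic tables round-trip and both dialect quirks parse", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("# Constructed from biom file",
                 "#OTU ID\ts1\ts2",
                 "g__A\t10\t0",
                 "g__B\t5\t5",
                 "g__C\t0\t10"), tmp)
    at <- readAbundanceTable(tmp)
    expect_equal(unname(colSums(abundances(at))), c(15, 15))
    expect_equal(taxonIds(at), c("g__A", "g__B", "g__C"))

    out <- withr::local_tempfile(fileext = ".tsv")
    writeAbundanceTable(at, out)
    back <- readAbundanceTable(out)
    expect_identical(abundances(back), abundances(at))

    ## transposed file with the orientation flag gives the identical table
    tr <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample\tg__A\tg__B\tg__C",
                 "s1\t10\t5\t0",
                 "s2\t0\t5\t10"), tr)
    att <- readAbundanceTable(tr, orientation = "samples_rows")
    expect_equal(abundances(att)[taxonIds(at), sampleIds(at)],
                 abundances(at))
})

test_that("trailing taxonomy columns and duplicate lineages are handled", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("#OTU ID\ts1\ts2\ttaxonomy",
                 "otu1\t3\t1\tk__B; g__Dorea",
                 "otu2\t4\t2\tk__B;g__Dorea",
                 "otu3\t1\t1\tk__B; g__Roseburia"), tmp)
    at <- readAbundanceTable(tmp)
    ## the two Dorea rows differ only in lineage spacing: summed element-wise
    expect_equal(nrow(at), 2L)
    expect_equal(unname(abundances(at)["k__B;g__Dorea", ]),
                 c(3 + 4, 1 + 2))
    expect_equal(metadata(at)$parseReport$rowsMerged, 1L)
})

test_that("malformed abundance input fails with a location", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("#OTU ID\ts1\ts2", "g__A\t1\tx"), tmp)
    expect_error(readAbundanceTable(tmp), "g__A.*s2")
    dup <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("#OTU ID\ts1\ts1", "g__A\t1\t2"), dup)
    expect_error(readAbundanceTable(dup), "duplicate sample")
})

test_that("rank collapse sums lineage prefixes and conserves totals", {
    m <- matrix(c(3, 1, 4, 1, 2, 2), 3, 2, byrow = TRUE,
                dimnames = list(
                    c("k__B;p__F;c__C;o__O;f__L;g__Dorea;s__a",
                      "k__B;p__F;c__C;o__O;f__L;g__Dorea;s__b",
                      "k__B;p__F;c__C;o__O;f__L;g__Roseburia;s__c"),
                    c("s1", "s2")))
    at <- AbundanceTable(m)
    gen <- collapseToRank(at, "genus")
    expect_equal(unname(abundances(gen)["k__B;p__F;c__C;o__O;f__L;g__Dorea", ]),
                 c(3 + 4, 1 + 1))
    phy <- collapseToRank(at, "phylum")
    expect_equal(nrow(phy), 1L)
    expect_equal(unname(abundances(phy)[1, ]), unname(colSums(m)))

    big <- makeCountTable(nTaxa = 50, n = 8, seed = 3)
    col <- collapseToRank(big, "family")
    expect_identical(colSums(abundances(col)), colSums(abundances(big)))
})

test_that("lineages shallower than the requested rank go to a bucket", {
    m <- matrix(1:4, 2, 2,
                dimnames = list(c("k__B;p__F", "k__B;p__F;c__C;o__O;f__L;g__G"),
                                c("s1", "s2")))
    expect_warning(res <- collapseToRank(AbundanceTable(m), "genus"),
                   "unclassified")
    expect_equal(nrow(res), 2L)
    expect_identical(colSums(abundances(res)), colSums(m))
})

test_that("relative abundance normalizes, rejects empty samples, idempotent", {
    m <- matrix(c(2, 2, 0, 7), 2, 2,
                dimnames = list(c("g__A", "g__B"), c("s1", "s2")))
    at <- relativeAbundance(AbundanceTable(m))
    expect_equal(unname(abundances(at)[, "s1"]), c(0.5, 0.5))
    expect_equal(unname(abundances(at)[, "s2"]), c(0, 1))
    expect_true(all(abundances(at) >= 0))
    expect_equal(unname(colSums(abundances(at))), c(1, 1), tolerance = 1e-12)
    again <- relativeAbundance(at)
    expect_equal(abundances(again), abundances(at), tolerance = 1e-12)

    z <- matrix(c(1, 2, 0, 0), 2, 2,
                dimnames = list(c("g__A", "g__B"), c("ok", "empty")))
    expect_error(relativeAbundance(AbundanceTable(z)), "empty")
})

test_that("mutation records read, classify and report skipped rows", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample\tgene\tensembl\teffect",
                 "t1\tAPC\tENSG1\tstop_gained",
                 "t1\tKRAS\tENSG2\tsynonymous_variant",
                 "t2\t\tENSG3\tmissense_variant",
                 "t2\tTP53\tENSG4\tweird_annotation"), tmp)
    rec <- readMutations(tmp)
    expect_equal(nrow(rec), 3L)
    expect_equal(rec$effect_class,
                 c("lof", "synonymous", "other"))
    rep <- attr(rec, "parseReport")
    expect_equal(rep$rowsSkipped, 1L)
    expect_equal(rep$unknownEffects, 1L)
})

test_that("pathway maps filter by database tag and invert to gene sets", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("G1\tPID\tWntA", "G2\tPID\tWntA", "G1\tKEGG\tK1",
                 "G2\tPID\tNotch"), tmp)
    pid <- readPathwayMap(tmp, "PID")
    expect_setequal(pid$WntA, c("G1", "G2"))
    expect_equal(pid$Notch, "G2")       # one gene, several pathways
    kegg <- readPathwayMap(tmp, "KEGG")
    expect_equal(kegg, list(K1 = "G1"))
    empty <- withr::local_tempfile(fileext = ".tsv")
    writeLines("G1\tREACTOME\tR1", empty)
    expect_error(readPathwayMap(empty, "PID"), "PID")
})

test_that("sample metadata validates stage and patient pairing", {
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample\tpatient\ttissue\tstage\tage\tsex",
                 "t1\tp1\ttumor\t2\t61\tM",
                 "n1\tp1\tnormal\t2\t61\tM",
                 "t2\tp2\ttumor\tNA\t70\tF"), tmp)
    md <- readSampleMetadata(tmp)
    expect_equal(md$stage, c(2L, 2L, NA))
    bad <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample\tpatient\ttissue\tstage",
                 "t1\tp1\ttumor\t7"), bad)
    expect_error(readSampleMetadata(bad), "stage")
})
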