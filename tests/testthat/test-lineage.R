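test_that("transmission channels follow the sex-by-lineage logic", {
    grid <- expand.grid(sex = sexLevels(), lineage = lineageLevels(),
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
        for (incY in c(FALSE, TRUE)) {
            ch <- openChannels(grid$sex[i], grid$lineage[i], includeY = incY)
            expect_true("autosomal_22" %in% ch)
            expect_gt(length(ch), 0)
        }
    }
    # X channel closed only for male probands with paternal lineage
    expect_setequal(openChannels("female", "paternal"),
                    c("autosomal_22", "x_chromosome"))
    expect_setequal(openChannels("female", "maternal"),
                    c("autosomal_22", "x_chromosome"))
    expect_setequal(openChannels("male", "maternal"),
                    c("autosomal_22", "x_chromosome"))
    expect_identical(openChannels("male", "paternal"), "autosomal_22")
    # father-to-son Y transmission appears only when asked for
    expect_setequal(openChannels("male", "paternal", includeY = TRUE),
                    c("autosomal_22", "y_chromosome"))
    expect_false("y_chromosome" %in%
                 openChannels("male", "maternal", includeY = TRUE))
    expect_false("y_chromosome" %in%
                 openChannels("female", "paternal", includeY = TRUE))
})

test_that("tabulateLineage counts affected records per cell", {
    rec <- probandRecord(
        sex = rep(c("female", "female", "male", "male"),
                  times = c(37, 67, 25, 46)),
        lineage = rep(c("paternal", "maternal", "paternal", "maternal"),
                      times = c(37, 67, 25, 46)),
        affected = TRUE)
    tab <- tabulateLineage(rec, label = "second-degree")
    expect_equal(unname(lineageCounts(tab)), c(37, 67, 25, 46))
    expect_equal(totalProbands(tab), 175)
    expect_equal(tableLabel(tab), "second-degree")

    empty <- probandRecord(character(), character(), logical())
    expect_equal(unname(lineageCounts(tabulateLineage(empty))),
                 c(0, 0, 0, 0))

    unaff <- probandRecord(rep("male", 10), rep("maternal", 10),
                           rep(FALSE, 10))
    expect_equal(totalProbands(tabulateLineage(unaff)), 0)
})

test_that("tabulation is permutation-invariant and additive", {
    set.seed(41)
    for (i in 1:5) {
        n <- sample(20:80, 1)
        rec <- probandRecord(sample(sexLevels(), n, TRUE),
                             sample(lineageLevels(), n, TRUE),
                             sample(c(TRUE, FALSE), n, TRUE))
        shuffled <- rec[sample(n), ]
        expect_identical(lineageCounts(tabulateLineage(rec)),
                         lineageCounts(tabulateLineage(shuffled)))
        cut <- sample(n - 1, 1)
        expect_identical(
            lineageCounts(tabulateLineage(rec)),
            lineageCounts(tabulateLineage(rec[seq_len(cut), ])) +
                lineageCounts(tabulateLineage(rec[(cut + 1):n, ])))
    }
})

test_that("CSV round trip is lossless for valid tables", {
    set.seed(42)
    for (i in 1:10) {
        tab <- randomCountTable()
        tf <- withr::local_tempfile(fileext = ".csv")
        writeCountTable(tab, tf)
        back <- readCountTable(tf, label = "random")
        expect_identical(lineageCounts(back), lineageCounts(tab))
    }
})

test_that("both CSV dialects are read and validated", {
    long <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sex,lineage,count",
                 "female,paternal,629", "female,maternal,582",
                 "male,paternal,343", "male,maternal,296"), long)
    tab <- readCountTable(long)
    expect_equal(totalProbands(tab), 1850)
    expect_equal(unname(lineageCounts(tab)), c(629, 582, 343, 296))

    wide <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sex,paternal,maternal",
                 "male,25,46", "female,37,67"), wide)
    expect_equal(unname(lineageCounts(readCountTable(wide))),
                 c(37, 67, 25, 46))

    dup <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sex,lineage,count",
                 "female,paternal,10", "female,paternal,5",
                 "female,maternal,1", "male,paternal,2",
                 "male,maternal,3"), dup)
    expect_equal(lineageCounts(readCountTable(dup))[["a"]], 15)

    bad <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sex,lineage,count", "female,paternal,-3"), bad)
    expect_error(readCountTable(bad), "non-negative integer")

    both <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sex,lineage,count", "female,both,3"), both)
    expect_error(readCountTable(both), "unilateral")

    hdr <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("x,y,z", "1,2,3"), hdr)
    expect_error(readCountTable(hdr), "header")
    expect_error(readCountTable("does-not-exist.csv"), "no such file")
})

test_that("count tables serialize to JSON with their total", {
    tab <- LineageCountTable(1, 2, 3, 4, label = "demo")
    parsed <- jsonlite::fromJSON(reportJSON(tab))
    expect_equal(parsed$total, 10)
    expect_equal(parsed$counts$a, 1)
    expect_equal(parsed$label, "demo")
})

test_that("invalid tables are rejected by the validity method", {
    expect_error(LineageCountTable(-1, 2, 3, 4))
    expect_error(LineageCountTable(1.5, 2, 3, 4))
    expect_error(probandRecord("female", "both", TRUE))
})
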